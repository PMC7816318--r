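## Readers/writers for the standard formats at the package boundary.
## GFF3 is 1-based closed on disk and converted here, exactly once, to the
## internal 0-based half-open convention.

#' Controlled vocabulary for predicted subcellular localization
#' @export
LOCALIZATION_LEVELS <- c("cytoplasm", "nucleus", "mitochondrion",
                         "extracellular", "cell_membrane",
                         "endoplasmic_reticulum", "other", "unknown")

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by the first whitespace-free
#'   token of each header.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read transcript models from GFF3
#'
#' Collects `CDS` features grouped by their `Parent` attribute (falling back
#' to `ID`, then `gene_id`) into one [transcript_models] set. Minus-strand
#' segments are reordered 5' to 3' in transcript space. Records whose total
#' CDS length is not a multiple of 3 are rejected with a warning; a gene id
#' appearing on more than one chromosome or strand is a hard error.
#'
#' @param path GFF3 file.
#' @return a `transcript_models` object.
#' @export
read_transcript_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  mc <- S4Vectors::mcols(cds)
  id <- rep(NA_character_, length(cds))
  if (!is.null(mc$Parent)) {
    parent <- vapply(as.list(mc$Parent),
                     function(p) if (length(p)) p[[1L]] else NA_character_,
                     character(1L))
    id <- parent
  }
  if (anyNA(id) && !is.null(mc$ID)) id[is.na(id)] <- mc$ID[is.na(id)]
  if (anyNA(id) && !is.null(mc$gene_id)) id[is.na(id)] <- mc$gene_id[is.na(id)]
  if (anyNA(id)) stop("CDS features without Parent/ID/gene_id in ", path)
  id <- sub("^(mRNA|transcript|gene):", "", id)

  models <- list()
  for (g in unique(id)) {
    rows <- cds[id == g]
    chrom <- unique(as.character(GenomicRanges::seqnames(rows)))
    strand <- unique(as.character(GenomicRanges::strand(rows)))
    if (length(chrom) > 1L || length(strand) > 1L)
      stop("duplicate gene_id '", g, "': CDS features on multiple chromosomes or strands")
    seg <- cbind(start = GenomicRanges::start(rows) - 1L,
                 end = GenomicRanges::end(rows))
    total <- sum(seg[, "end"] - seg[, "start"])
    if (total %% 3L != 0L) {
      warning("rejecting gene '", g, "': CDS length ", total,
              " nt is not a multiple of 3", call. = FALSE)
      next
    }
    models[[g]] <- new_transcript_model(g, chrom, strand, seg)
  }
  if (!length(models)) stop("no usable transcript models in ", path)
  transcript_models(models)
}

#' Write transcript models to GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` rows in GFF3's 1-based closed convention;
#' [read_transcript_models()] on the output reproduces the input coordinates
#' exactly.
#'
#' @param transcripts a `transcript_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcript_models <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in transcripts) {
    lo <- min(m$segments[, "start"]) + 1L
    hi <- max(m$segments[, "end"])
    writeLines(sprintf("%s\triboalloc\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
                       m$chromosome, lo, hi, m$strand, m$gene_id), con)
    writeLines(sprintf("%s\triboalloc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s",
                       m$chromosome, lo, hi, m$strand, m$gene_id, m$gene_id), con)
    phase <- cumsum(c(0L, m$segments[, "end"] - m$segments[, "start"])) %% 3L
    for (i in seq_len(nrow(m$segments))) {
      writeLines(sprintf("%s\triboalloc\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s",
                         m$chromosome, m$segments[i, "start"] + 1L,
                         m$segments[i, "end"], m$strand,
                         (3L - phase[i]) %% 3L, m$gene_id, m$gene_id), con)
    }
  }
  invisible(path)
}

#' Read ribosome footprints
#'
#' Footprints are represented by their 3'-most aligned genomic base (`end3`,
#' 0-based; for minus-strand alignments this is the leftmost base), length
#' and mapping quality. The plain TSV is the canonical representation; BAM is
#' an adapter over it.
#'
#' @param path footprint TSV (columns `chromosome`, `strand`, `end3`,
#'   `length`, `mapq`; header line; `#` comments) or an indexed BAM file.
#' @param format `"auto"` (by extension), `"tsv"` or `"bam"`.
#' @return data.frame with columns `chromosome`, `strand`, `end3`, `length`,
#'   `mapq`; one row per aligned read.
#' @export
read_footprints <- function(path, format = c("auto", "tsv", "bam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "tsv"
  if (format == "tsv") {
    fp <- tryCatch(
      utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
      error = function(e) stop("cannot read footprint table '", path, "': ",
                               conditionMessage(e)))
    need <- c("chromosome", "strand", "end3", "length", "mapq")
    missing <- setdiff(need, names(fp))
    if (length(missing))
      stop("footprint table '", path, "' lacks column(s): ",
           paste(missing, collapse = ", "))
    fp <- fp[need]
  } else {
    aln <- tryCatch(
      GenomicAlignments::readGAlignments(
        path, param = Rsamtools::ScanBamParam(what = "mapq")),
      error = function(e) stop("cannot read BAM '", path, "': ",
                               conditionMessage(e)))
    strand <- as.character(GenomicAlignments::strand(aln))
    fp <- data.frame(
      chromosome = as.character(GenomicAlignments::seqnames(aln)),
      strand = strand,
      end3 = ifelse(strand == "+",
                    GenomicAlignments::end(aln) - 1L,
                    GenomicAlignments::start(aln) - 1L),
      length = GenomicAlignments::qwidth(aln),
      mapq = S4Vectors::mcols(aln)$mapq,
      stringsAsFactors = FALSE)
    fp$mapq[is.na(fp$mapq)] <- 0L
  }
  stopifnot(all(fp$strand %in% c("+", "-")), all(fp$length > 0L),
            all(fp$mapq >= 0L))
  fp$end3 <- as.integer(fp$end3)
  fp$length <- as.integer(fp$length)
  fp$mapq <- as.integer(fp$mapq)
  fp
}

#' Write a footprint table
#' @param footprints data.frame as returned by [read_footprints()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_footprints <- function(footprints, path) {
  utils::write.table(footprints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the per-gene feature table
#'
#' The table carries predictor outputs (signal peptide, TMD count, GPI
#' anchor, predicted localization, COG category) consumed by the
#' classification stage; the predictors themselves are upstream of this
#' package.
#'
#' @param path TSV with header `gene_id`, `has_signal_peptide`, `tmd_count`,
#'   `has_gpi`, `localization`, `cog_category`.
#' @param transcripts optional `transcript_models`; feature rows for genes
#'   absent from the annotation are kept with a warning (classification-only
#'   genes).
#' @return data.frame, one row per gene.
#' @export
read_feature_table <- function(path, transcripts = NULL) {
  ft <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "has_signal_peptide", "tmd_count", "has_gpi",
            "localization", "cog_category")
  missing <- setdiff(need, names(ft))
  if (length(missing))
    stop("feature table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  ft <- ft[need]
  ft$has_signal_peptide <- as.logical(ft$has_signal_peptide)
  ft$has_gpi <- as.logical(ft$has_gpi)
  ft$tmd_count <- as.integer(ft$tmd_count)
  if (any(!is.finite(ft$tmd_count)) || any(ft$tmd_count < 0L))
    stop("tmd_count must be a finite non-negative integer")
  bad <- setdiff(unique(ft$localization), LOCALIZATION_LEVELS)
  if (length(bad))
    stop("unknown localization value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(LOCALIZATION_LEVELS, collapse = ", "))
  if (anyDuplicated(ft$gene_id))
    stop("duplicate gene_id in feature table")
  if (!is.null(transcripts)) {
    orphan <- setdiff(ft$gene_id, gene_ids(transcripts))
    if (length(orphan))
      warning(length(orphan), " feature row(s) for genes absent from the ",
              "annotation (kept for classification only): ",
              paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  ft
}

#' Write the per-gene feature table
#' @param features data.frame as returned by [read_feature_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
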