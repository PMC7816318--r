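## Transcript models: stranded CDS geometry in 0-based half-open coordinates.
## All conversion to/from GFF3's 1-based closed convention happens in
## annotation_io.R; everything downstream assumes this convention.

#' Construct a single transcript model
#'
#' A transcript model is a gene's CDS geometry: an ordered set of genomic
#' segments (0-based, half-open, in translation order, i.e. the first segment
#' contains the start codon) plus the derived codon count `L`.
#'
#' @param gene_id character scalar, unique gene/transcript identifier.
#' @param chromosome character scalar.
#' @param strand `"+"` or `"-"`.
#' @param segments integer matrix with columns `start`, `end` (0-based,
#'   half-open), one row per CDS segment, ordered 5' to 3' in transcript
#'   space (for `"-"` strand the rightmost genomic segment comes first).
#' @return an object of class `transcript_model`.
#' @export
new_transcript_model <- function(gene_id, chromosome, strand, segments) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  widths <- segments[, "end"] - segments[, "start"]
  if (any(widths <= 0L))
    stop("empty or inverted CDS segment in gene ", gene_id)
  total <- sum(widths)
  if (total %% 3L != 0L)
    stop("CDS length of gene ", gene_id, " (", total, " nt) is not a multiple of 3")
  ## translation order: genomic starts increase on "+", decrease on "-"
  ord <- order(segments[, "start"], decreasing = (strand == "-"))
  segments <- segments[ord, , drop = FALSE]
  if (nrow(segments) > 1L) {
    sorted <- segments[order(segments[, "start"]), , drop = FALSE]
    if (any(sorted[-1L, "start"] < sorted[-nrow(sorted), "end"]))
      stop("overlapping CDS segments in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 segments = segments, L = total %/% 3L),
            class = "transcript_model")
}

#' Bundle transcript models into a set
#'
#' @param models list of `transcript_model` objects.
#' @return an object of class `transcript_models`, a named list keyed by
#'   `gene_id`.
#' @export
transcript_models <- function(models) {
  ids <- vapply(models, `[[`, character(1L), "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids
  class(models) <- "transcript_models"
  models
}

#' @export
print.transcript_models <- function(x, ...) {
  L <- codon_lengths(x)
  cat("transcript_models:", length(x), "genes;",
      "codon length range", paste(range(L), collapse = "-"), "\n")
  invisible(x)
}

#' @export
`[.transcript_models` <- function(x, i) {
  transcript_models(unclass(x)[i])
}

#' Gene identifiers of a transcript model set
#' @param transcripts a `transcript_models` object.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(transcripts) names(transcripts)

#' Codon counts (L) per gene
#' @param transcripts a `transcript_models` object.
#' @return named integer vector of ORF lengths in codons.
#' @export
codon_lengths <- function(transcripts) {
  vapply(transcripts, `[[`, integer(1L), "L")
}

## GRanges index of all CDS segments, used for vectorized footprint
## assignment. mcols: gene_id, cum_start = transcript-space nt offset of the
## segment's first translated base.
cds_granges <- function(transcripts) {
  n_seg <- vapply(transcripts, function(m) nrow(m$segments), integer(1L))
  starts <- ends <- integer(sum(n_seg))
  chrom <- strand <- gid <- character(sum(n_seg))
  cum <- integer(sum(n_seg))
  at <- 1L
  for (m in transcripts) {
    k <- nrow(m$segments)
    idx <- at:(at + k - 1L)
    starts[idx] <- m$segments[, "start"]
    ends[idx] <- m$segments[, "end"]
    chrom[idx] <- m$chromosome
    strand[idx] <- m$strand
    gid[idx] <- m$gene_id
    w <- m$segments[, "end"] - m$segments[, "start"]
    cum[idx] <- cumsum(c(0L, w))[seq_len(k)]
    at <- at + k
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = starts + 1L, end = ends),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gid
  S4Vectors::mcols(gr)$cum_start <- cum
  gr
}

## Map genomic 0-based positions (with chrom/strand) to (gene, tx_nt).
## Positions outside every CDS get gene NA. Positions hitting CDS of more
## than one gene get gene NA and multi = TRUE.
genomic_to_tx <- function(transcripts, chromosome, strand, pos, index = NULL) {
  if (is.null(index)) index <- cds_granges(transcripts)
  q <- GenomicRanges::GRanges(chromosome,
                              IRanges::IRanges(start = pos + 1L, width = 1L),
                              strand = strand)
  hits <- GenomicRanges::findOverlaps(q, index, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n <- length(pos)
  gene <- rep(NA_character_, n)
  tx <- rep(NA_integer_, n)
  multi <- logical(n)
  if (length(qh)) {
    dup <- qh %in% qh[duplicated(qh)]
    multi[unique(qh[dup])] <- TRUE
    keep <- !dup
    qh <- qh[keep]; sh <- sh[keep]
    seg_start0 <- GenomicRanges::start(index)[sh] - 1L
    seg_end0 <- GenomicRanges::end(index)[sh]
    cum <- S4Vectors::mcols(index)$cum_start[sh]
    plus <- as.character(GenomicRanges::strand(index))[sh] == "+"
    tx[qh] <- ifelse(plus,
                     cum + (pos[qh] - seg_start0),
                     cum + (seg_end0 - 1L - pos[qh]))
    gene[qh] <- S4Vectors::mcols(index)$gene_id[sh]
  }
  data.frame(gene_id = gene, tx_nt = tx, multi = multi)
}

## Map transcript-space nt positions of one gene to genomic 0-based
## coordinates. Positions past the CDS 3' end run into the segment's
## downstream flank (used by the simulator for reads whose 3' ends overhang
## the stop codon).
tx_to_genomic <- function(model, tx_nt) {
  w <- model$segments[, "end"] - model$segments[, "start"]
  cum <- cumsum(c(0L, w))
  seg <- findInterval(tx_nt, cum, rightmost.closed = FALSE)
  seg[seg > nrow(model$segments)] <- nrow(model$segments)
  seg[seg < 1L] <- 1L
  off <- tx_nt - cum[seg]
  if (model$strand == "+") {
    model$segments[seg, "start"] + off
  } else {
    model$segments[seg, "end"] - 1L - off
  }
}

## Spliced CDS sequence (5'->3' in transcript space) as a character scalar.
cds_sequence <- function(model, genome) {
  chr <- genome[[model$chromosome]]
  parts <- lapply(seq_len(nrow(model$segments)), function(i) {
    s <- Biostrings::subseq(chr, start = model$segments[i, "start"] + 1L,
                            end = model$segments[i, "end"])
    if (model$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  paste0(unlist(parts), collapse = "")
}

## Genomic coordinate of the first base of the start codon.
cds_start_position <- function(model) {
  if (model$strand == "+") model$segments[1L, "start"]
  else model$segments[1L, "end"] - 1L
}
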