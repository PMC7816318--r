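## Ambiguity masking: footprint-length fragments whose exact sequence (or
## reverse complement) occurs more than once in the genome cannot be mapped
## uniquely, so the codons they would be assigned to are excluded from
## quantification. Terminal trimming removes the first and last five codons
## of every ORF. The remainder is the gene's pseudo length.

#' Empty mask set for an annotation
#'
#' @param transcripts a `transcript_models` object.
#' @return object of class `mask_set` with per-gene logical vectors
#'   `ambiguity` and `terminal` (all `FALSE`) and the codon lengths `L`.
#' @export
new_mask_set <- function(transcripts) {
  L <- codon_lengths(transcripts)
  structure(list(ambiguity = lapply(L, logical),
                 terminal = lapply(L, logical),
                 L = L, n_terminal = 0L),
            class = "mask_set")
}

#' Combined mask of one gene
#' @param masks a `mask_set`.
#' @param gene_id gene identifier.
#' @return logical vector of length `L`; `TRUE` = masked.
#' @export
gene_mask <- function(masks, gene_id) {
  masks$ambiguity[[gene_id]] | masks$terminal[[gene_id]]
}

#' Pseudo gene lengths
#'
#' ORF length in codons minus the number of masked codons; the cTPM length
#' normalizer.
#'
#' @param masks a `mask_set`.
#' @return named integer vector.
#' @export
pseudo_lengths <- function(masks) {
  mapply(function(a, t) sum(!(a | t)), masks$ambiguity, masks$terminal)
}

#' Genes excluded from quantification (fully masked)
#' @param masks a `mask_set`.
#' @return character vector of gene ids with pseudo length 0.
#' @export
excluded_genes <- function(masks) names(which(pseudo_lengths(masks) == 0L))

#' @export
print.mask_set <- function(x, ...) {
  pl <- pseudo_lengths(x)
  cat("mask_set:", length(x$L), "genes;",
      sum(vapply(x$ambiguity, sum, integer(1L))), "ambiguity-masked codons;",
      sum(vapply(x$terminal, sum, integer(1L))), "terminal-masked codons;",
      sum(pl == 0L), "genes fully masked\n")
  invisible(x)
}

#' Enumerate all footprint-length fragments of the coding sequences
#'
#' One fragment per k-nt window of each spliced CDS; the `codon_index` of a
#' fragment is the codon its P-site would receive under the canonical
#' offset for a k-nt footprint, so the mask lives in the same coordinate
#' system as real reads. Genes with CDS shorter than `k` contribute no
#' fragments (warned once).
#'
#' @param transcripts a `transcript_models` object.
#' @param genome a [Biostrings::DNAStringSet].
#' @param k fragment length in nt (default 28, the approximate footprint
#'   size).
#' @return data.frame with columns `gene_id`, `codon_index` (0-based),
#'   `sequence`.
#' @export
enumerate_fragments <- function(transcripts, genome, k = 28L) {
  offset <- default_psite_offset(k)
  out <- vector("list", length(transcripts))
  short <- character(0L)
  for (i in seq_along(transcripts)) {
    m <- transcripts[[i]]
    s <- cds_sequence(m, genome)
    n <- nchar(s)
    if (n < k) {
      short <- c(short, m$gene_id)
      next
    }
    starts <- seq_len(n - k + 1L)                       # 1-based window starts
    p_nt <- (starts - 1L) + (k - 1L) - offset           # shifted 3'-end, 0-based
    out[[i]] <- data.frame(gene_id = m$gene_id,
                           codon_index = p_nt %/% 3L,
                           sequence = substring(s, starts, starts + k - 1L),
                           stringsAsFactors = FALSE)
  }
  if (length(short))
    warning(length(short), " gene(s) with CDS shorter than ", k,
            " nt contribute no fragments: ",
            paste(utils::head(short, 5L), collapse = ", "), call. = FALSE)
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

## Occurrence count of each query k-mer over all k-windows of the genome and
## its reverse complement, with a window and its reverse complement collapsed
## to one site (canonical k-mer), so a palindromic fragment occurring once
## counts once.
genome_kmer_index <- function(genome, k) {
  seqs <- as.character(genome)
  windows <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0L))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }), use.names = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(windows)))
  canon <- pmin(windows, rc)
  canon <- sort(canon, method = "radix")
  r <- rle(canon)
  list(kmer = r$values, count = r$lengths)
}

#' Build the ambiguity part of the mask
#'
#' A fragment is ambiguous iff its exact sequence or reverse complement
#' occurs at more than one location in the genome; every codon assigned an
#' ambiguous fragment is masked.
#'
#' @inheritParams enumerate_fragments
#' @return a `mask_set` with the `ambiguity` component filled.
#' @export
build_ambiguity_mask <- function(transcripts, genome, k = 28L) {
  masks <- new_mask_set(transcripts)
  frags <- enumerate_fragments(transcripts, genome, k)
  if (is.null(frags) || !nrow(frags)) return(masks)
  idx <- genome_kmer_index(genome, k)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(frags$sequence)))
  canon <- pmin(frags$sequence, rc)
  occ <- idx$count[match(canon, idx$kmer)]
  occ[is.na(occ)] <- 0L   # junction-spanning spliced fragments may be absent
  ambiguous <- occ > 1L
  if (any(ambiguous)) {
    hit <- frags[ambiguous, c("gene_id", "codon_index")]
    for (g in unique(hit$gene_id))
      masks$ambiguity[[g]][unique(hit$codon_index[hit$gene_id == g]) + 1L] <- TRUE
  }
  masks
}

#' Apply the terminal mask
#'
#' Masks the first and last `n_terminal` codons of every ORF (read quality
#' at ORF termini is systematically distorted in Ribo-seq), taking the union
#' with any ambiguity mask already present. Genes with `L <= 2 * n_terminal`
#' become fully masked and are excluded from quantification (warned).
#'
#' @param masks a `mask_set`.
#' @param n_terminal codons trimmed at each terminus (default 5).
#' @return the updated `mask_set`.
#' @export
apply_terminal_mask <- function(masks, n_terminal = 5L) {
  n_terminal <- as.integer(n_terminal)
  for (g in names(masks$L)) {
    L <- masks$L[[g]]
    term <- logical(L)
    n <- min(n_terminal, L)
    if (n > 0L) {
      term[seq_len(n)] <- TRUE
      term[seq.int(max(L - n_terminal + 1L, 1L), L)] <- TRUE
    }
    masks$terminal[[g]] <- term
  }
  masks$n_terminal <- n_terminal
  gone <- excluded_genes(masks)
  if (length(gone))
    warning(length(gone), " gene(s) fully masked and excluded from ",
            "quantification: ", paste(utils::head(gone, 5L), collapse = ", "),
            call. = FALSE)
  masks
}

#' Build the complete mask (ambiguity + terminal)
#'
#' @inheritParams enumerate_fragments
#' @param n_terminal codons trimmed at each ORF terminus.
#' @return a `mask_set`.
#' @export
build_mask <- function(transcripts, genome, k = 28L, n_terminal = 5L) {
  apply_terminal_mask(build_ambiguity_mask(transcripts, genome, k), n_terminal)
}

#' Write a mask set as a BED-like TSV
#'
#' One row per masked codon: `gene_id`, `codon_index` (0-based),
#' `provenance` (`ambiguity`, `terminal`, or `ambiguity+terminal`).
#'
#' @param masks a `mask_set`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_mask <- function(masks, path) {
  rows <- lapply(names(masks$L), function(g) {
    a <- masks$ambiguity[[g]]; t <- masks$terminal[[g]]
    i <- which(a | t)
    if (!length(i)) return(NULL)
    prov <- ifelse(a[i] & t[i], "ambiguity+terminal",
                   ifelse(a[i], "ambiguity", "terminal"))
    data.frame(gene_id = g, codon_index = i - 1L, provenance = prov)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(gene_id = character(), codon_index = integer(),
                      provenance = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
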