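## P-site assignment: 3'-end offset calibration against annotated start
## codons, and assembly of the reads-per-codon-per-gene (RPCPG) table.

## Canonical P-site geometry: the P-site codon's first base sits 12 nt
## downstream of a footprint's 5' end, i.e. (length - 13) nt upstream of its
## 3'-end base. Used as the default for ambiguity-mask fragments and as the
## simulator's planted truth.
default_psite_offset <- function(length) as.integer(length) - 13L

#' Estimate per-read-length P-site offsets from 3' ends
#'
#' For each footprint length, candidate offsets (nt, counted from the 3'-end
#' base toward 5') are scored by how many shifted reads land exactly on the
#' first base of an annotated start codon, restricted to reads whose 3' end
#' lies within +/- one footprint length of a start. The maximizing offset
#' wins; ties go to the smaller offset. Lengths supported by fewer than
#' `min_reads` calibrating reads are dropped.
#'
#' @param footprints data.frame from [read_footprints()].
#' @param transcripts a `transcript_models` object.
#' @param lengths integer vector of footprint lengths to calibrate.
#' @param mapq_min minimum mapping quality of calibrating reads.
#' @param min_reads minimum number of calibrating reads per length.
#' @return named integer vector (names = footprint lengths) of offsets,
#'   class `offset_table`.
#' @export
estimate_offsets <- function(footprints, transcripts, lengths = 25:31,
                             mapq_min = 60L, min_reads = 50L) {
  stopifnot(length(lengths) > 0L)
  fp <- footprints[footprints$mapq >= mapq_min & footprints$length %in% lengths, ,
                   drop = FALSE]
  max_len <- max(lengths)
  starts <- vapply(transcripts, cds_start_position, integer(1L))
  chrom <- vapply(transcripts, `[[`, character(1L), "chromosome")
  strand <- vapply(transcripts, `[[`, character(1L), "strand")
  win <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = pmax(starts + 1L - max_len, 1L),
                     end = starts + 1L + max_len),
    strand = strand)
  q <- GenomicRanges::GRanges(fp$chromosome,
                              IRanges::IRanges(start = fp$end3 + 1L, width = 1L),
                              strand = fp$strand)
  hits <- GenomicRanges::findOverlaps(q, win, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ## signed distance from start-codon first base toward 3'
  d <- ifelse(strand[sh] == "+",
              fp$end3[qh] - starts[sh],
              starts[sh] - fp$end3[qh])
  len <- fp$length[qh]
  keep <- abs(d) <= len
  d <- d[keep]; len <- len[keep]

  offsets <- integer(0L)
  for (l in sort(unique(as.integer(lengths)))) {
    dl <- d[len == l]
    cal <- dl[dl >= 0L & dl < l]
    if (length(cal) < min_reads) next
    counts <- tabulate(cal + 1L, nbins = l)
    offsets[[as.character(l)]] <- which.max(counts) - 1L  # ties -> smaller
  }
  if (!length(offsets))
    stop("no footprint length could be calibrated against start codons; ",
         "supply offsets manually via read_offset_table()")
  structure(offsets, class = "offset_table")
}

#' Read / write a P-site offset table
#'
#' TSV with columns `length`, `offset`; offsets count from the 3'-end base
#' toward 5' and must satisfy `0 <= offset < length`.
#'
#' @param path TSV file.
#' @return named integer vector of class `offset_table`.
#' @export
read_offset_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("length", "offset") %in% names(tab)))
  if (any(tab$offset < 0L) || any(tab$offset >= tab$length))
    stop("offsets must satisfy 0 <= offset < length")
  offsets <- as.integer(tab$offset)
  names(offsets) <- as.character(as.integer(tab$length))
  structure(offsets, class = "offset_table")
}

#' @rdname read_offset_table
#' @param offsets an `offset_table`.
#' @export
write_offset_table <- function(offsets, path) {
  utils::write.table(
    data.frame(length = as.integer(names(offsets)),
               offset = as.integer(offsets)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Shared assignment core: filters by mapq and calibrated length, maps each
## surviving 3' end into transcript space and shifts by the per-length
## offset. Returns assigned reads plus a tally of every drop reason.
assign_psites <- function(footprints, offsets, transcripts, mapq_min = 60L,
                          index = NULL) {
  n0 <- nrow(footprints)
  ok_mapq <- footprints$mapq >= mapq_min
  fp <- footprints[ok_mapq, , drop = FALSE]
  ok_len <- as.character(fp$length) %in% names(offsets)
  fp <- fp[ok_len, , drop = FALSE]
  tally <- c(low_mapq = n0 - sum(ok_mapq),
             uncalibrated_length = sum(!ok_len))

  loc <- genomic_to_tx(transcripts, fp$chromosome, fp$strand, fp$end3,
                       index = index)
  multi <- loc$multi
  inside <- !is.na(loc$gene_id) & !multi
  p_nt <- rep(NA_integer_, nrow(fp))
  off <- unclass(offsets)[as.character(fp$length)]
  p_nt[inside] <- loc$tx_nt[inside] - off[inside]
  L3 <- 3L * codon_lengths(transcripts)
  in_cds <- inside & !is.na(p_nt) & p_nt >= 0L &
    p_nt < L3[loc$gene_id]
  in_cds[is.na(in_cds)] <- FALSE
  tally <- c(tally,
             outside_cds = sum(!multi & !in_cds),
             ambiguous_gene = sum(multi))
  data.frame(gene_id = loc$gene_id[in_cds],
             p_nt = p_nt[in_cds],
             length = fp$length[in_cds],
             stringsAsFactors = FALSE) -> assigned
  list(assigned = assigned, tally = tally,
       n_retained = nrow(fp))  # reads surviving mapq/length filters
}

#' Build the reads-per-codon-per-gene table
#'
#' Each footprint passing the mapping-quality threshold and carrying a
#' calibrated length contributes exactly one count to exactly one codon of
#' at most one gene: its 3' end is shifted by the per-length offset in
#' transcript space and the containing codon receives the count. Reads whose
#' shifted position falls outside any CDS, or whose 3' end lies in
#' overlapping CDS of several genes, are dropped and tallied.
#'
#' @param footprints data.frame from [read_footprints()].
#' @param offsets an `offset_table`.
#' @param transcripts a `transcript_models` object.
#' @param mapq_min minimum mapping quality (default 60).
#' @param sample sample label stored with the table.
#' @return object of class `codon_counts`: list with `counts` (named list of
#'   integer vectors, one per gene, length `L`), `sample`, and `dropped`
#'   (named tally of drop reasons).
#' @export
build_codon_counts <- function(footprints, offsets, transcripts,
                               mapq_min = 60L, sample = "sample") {
  res <- assign_psites(footprints, offsets, transcripts, mapq_min)
  L <- codon_lengths(transcripts)
  counts <- lapply(L, function(l) integer(l))
  if (nrow(res$assigned)) {
    codon <- res$assigned$p_nt %/% 3L
    by_gene <- split(codon, res$assigned$gene_id)
    for (g in names(by_gene))
      counts[[g]] <- tabulate(by_gene[[g]] + 1L, nbins = L[[g]])
  }
  structure(list(counts = counts, sample = sample, dropped = res$tally),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts [", x$sample, "]: ", length(x$counts), " genes, ",
      sum(vapply(x$counts, sum, numeric(1L))), " assigned reads\n", sep = "")
  cat("dropped:", paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Reading-frame periodicity of shifted P-site positions
#'
#' @inheritParams build_codon_counts
#' @return matrix of per-length fractions of shifted positions in codon
#'   frames 0/1/2 (rows = footprint lengths plus an `all` row); each row
#'   sums to 1.
#' @export
frame_periodicity <- function(footprints, offsets, transcripts,
                              mapq_min = 60L) {
  res <- assign_psites(footprints, offsets, transcripts, mapq_min)
  if (!nrow(res$assigned)) stop("no assignable reads for frame periodicity")
  frame <- res$assigned$p_nt %% 3L
  lens <- sort(unique(res$assigned$length))
  out <- t(vapply(lens, function(l) {
    f <- frame[res$assigned$length == l]
    tabulate(f + 1L, nbins = 3L) / length(f)
  }, numeric(3L)))
  out <- rbind(out, all = tabulate(frame + 1L, nbins = 3L) / length(frame))
  rownames(out) <- c(as.character(lens), "all")
  colnames(out) <- c("frame0", "frame1", "frame2")
  out
}
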