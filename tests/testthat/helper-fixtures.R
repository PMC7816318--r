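# Fixtures built in code: toy genomes/annotations with known geometry, and
# a convenience wrapper running the quantification stack on simulated
# libraries.

toy_genome <- function(...) {
  g <- Biostrings::DNAStringSet(c(...))
  g
}

# One plus-strand and one minus-strand single-exon gene on a shared
# chromosome of random sequence, CDS placed at known coordinates.
toy_reference <- function(L1 = 20L, L2 = 15L, seed = 42L) {
  set.seed(seed)
  nt <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  cds1 <- paste0("ATG", paste0(sample(setdiff(riboalloc:::SENSE_CODONS, "ATG"),
                                      L1 - 2L, TRUE), collapse = ""), "TAA")
  cds2 <- paste0("ATG", paste0(sample(setdiff(riboalloc:::SENSE_CODONS, "ATG"),
                                      L2 - 2L, TRUE), collapse = ""), "TAA")
  cds2_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds2)))
  chr <- paste0(nt(100), cds1, nt(100), cds2_rc, nt(100))
  genome <- Biostrings::DNAStringSet(chr)
  names(genome) <- "chrT"
  s1 <- 100L; e1 <- s1 + 3L * L1
  s2 <- e1 + 100L; e2 <- s2 + 3L * L2
  tr <- transcript_models(list(
    new_transcript_model("tg1", "chrT", "+", cbind(start = s1, end = e1)),
    new_transcript_model("tg2", "chrT", "-", cbind(start = s2, end = e2))))
  list(genome = genome, transcripts = tr)
}

make_counts <- function(counts, sample = "s") {
  structure(list(counts = counts, sample = sample,
                 dropped = c(low_mapq = 0L, uncalibrated_length = 0L,
                             outside_cds = 0L, ambiguous_gene = 0L)),
            class = "codon_counts")
}

unit_profile <- function(n) structure(rep(1, n), class = "global_profile")

footprint_df <- function(chromosome, strand, end3, length = 28L,
                         mapq = 60L) {
  data.frame(chromosome = chromosome, strand = strand,
             end3 = as.integer(end3), length = as.integer(length),
             mapq = as.integer(mapq), stringsAsFactors = FALSE)
}

# Quantify one simulated library end to end; returns the metrics frame.
quantify_library <- function(fps, ref, masks, offsets, sample = "s") {
  cc <- build_codon_counts(fps, offsets, ref$transcripts, sample = sample)
  gene_metrics(cc, ref$transcripts, masks)
}

named_ctpm <- function(metrics) stats::setNames(metrics$ctpm, metrics$gene_id)
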