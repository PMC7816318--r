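# Ambiguity masking, terminal trimming and pseudo gene lengths.

# Brute-force oracle: occurrences of each fragment over every k-window of
# the genome and its reverse complement, counting a palindromic fragment's
# sites once (vcountPDict-based; independent of the package's k-mer index).
oracle_occurrences <- function(sequences, genome, k) {
  frag <- Biostrings::DNAStringSet(sequences)
  rc <- Biostrings::reverseComplement(frag)
  fwd <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(frag), genome))
  rev <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(rc), genome))
  ifelse(as.character(frag) == as.character(rc), fwd, fwd + rev)
}

test_that("fragment enumeration yields one window per CDS position", {
  ref <- toy_reference(L1 = 30L, L2 = 20L)   # 90 and 60 nt CDS
  fr <- enumerate_fragments(ref$transcripts, ref$genome, k = 28L)
  expect_equal(sum(fr$gene_id == "tg1"), 63L)  # 90 - 28 + 1
  expect_equal(sum(fr$gene_id == "tg2"), 33L)
  # first window of the plus-strand CDS equals the genome substring
  s1 <- ref$transcripts[["tg1"]]$segments[1, "start"]
  expect_equal(fr$sequence[fr$gene_id == "tg1"][1],
               as.character(Biostrings::subseq(ref$genome[[1]], s1 + 1L,
                                               s1 + 28L)))
  # fragment -> codon assignment uses the canonical 28-nt offset
  expect_equal(fr$codon_index[fr$gene_id == "tg1"][1], 4L)  # (0+27-15)/3
})

test_that("a CDS shorter than the fragment length contributes nothing, with a warning", {
  ref <- toy_reference(L1 = 9L, L2 = 30L)    # 27 nt CDS
  expect_warning(fr <- enumerate_fragments(ref$transcripts, ref$genome),
                 "tg1")
  expect_false("tg1" %in% fr$gene_id)
})

test_that("ambiguity mask equals the brute-force multiplicity oracle on a planted-duplication genome", {
  cfg <- sim_config(n_genes = 25L, duplication_fraction = 0.2,
                    depth = 1e3, replicates = 1L, seed = 41L)
  ref <- simulate_reference(cfg)
  expect_lt(sum(Biostrings::width(ref$genome)), 50000L)
  masks <- build_ambiguity_mask(ref$transcripts, ref$genome)
  fr <- enumerate_fragments(ref$transcripts, ref$genome)
  occ <- oracle_occurrences(fr$sequence, ref$genome, 28L)
  expect_true(all(occ >= 1L))
  hit <- fr[occ > 1L, ]
  for (g in gene_ids(ref$transcripts)) {
    expected <- logical(ref$transcripts[[g]]$L)
    expected[unique(hit$codon_index[hit$gene_id == g]) + 1L] <- TRUE
    expect_identical(masks$ambiguity[[g]], expected)
  }
  # planted duplications produce a non-empty mask in donor and recipients
  expect_gt(sum(vapply(masks$ambiguity, sum, integer(1))), 0L)
  recip <- ref$truth$gene_id[!is.na(ref$truth$dup_start)]
  expect_true(all(vapply(masks$ambiguity[recip], any, logical(1))))
})

test_that("an all-unique genome yields an empty ambiguity mask", {
  cfg <- sim_config(n_genes = 15L, duplication_fraction = 0,
                    depth = 1e3, replicates = 1L, seed = 43L)
  ref <- simulate_reference(cfg)
  masks <- build_ambiguity_mask(ref$transcripts, ref$genome)
  expect_equal(sum(vapply(masks$ambiguity, sum, integer(1))), 0L)
})

test_that("a palindromic fragment occurring once is counted once and stays unmasked", {
  # CDS carries a 28-nt reverse-complement palindrome at a known window
  half <- "ATCGGATTACCGAGTC"                 # 14 nt (codon-friendly 42-nt insert)
  pal <- paste0(substr(half, 1, 14),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(substr(half, 1, 14)))))
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pal))), pal)
  set.seed(47)
  lead <- paste0(sample(riboalloc:::SENSE_CODONS, 10, TRUE), collapse = "")
  tail <- paste0(sample(riboalloc:::SENSE_CODONS, 10, TRUE), collapse = "")
  cds <- paste0("ATG", lead, pal, "GA", tail, "TAA")  # length multiple of 3
  chr <- paste0(strrep("A", 50), cds, strrep("A", 50))
  genome <- Biostrings::DNAStringSet(chr); names(genome) <- "chrP"
  tr <- transcript_models(list(new_transcript_model(
    "pg", "chrP", "+", cbind(start = 50L, end = 50L + nchar(cds)))))
  masks <- build_ambiguity_mask(tr, genome)
  # the poly-A flanks self-match, but the palindromic window must not
  fr <- enumerate_fragments(tr, genome)
  pal_rows <- which(fr$sequence == pal)
  expect_length(pal_rows, 1L)
  expect_false(masks$ambiguity[["pg"]][fr$codon_index[pal_rows] + 1L])
})

test_that("adding a duplicated segment never unmasks a codon", {
  cfg <- sim_config(n_genes = 12L, duplication_fraction = 0.1,
                    depth = 1e3, replicates = 1L, seed = 53L)
  ref <- simulate_reference(cfg)
  before <- build_ambiguity_mask(ref$transcripts, ref$genome)
  # append an extra contig carrying a copy of a CDS stretch of gene 1
  m1 <- ref$transcripts[[1]]
  copy <- Biostrings::subseq(ref$genome[[m1$chromosome]],
                             m1$segments[1, "start"] + 10L,
                             m1$segments[1, "start"] + 130L)
  genome2 <- c(ref$genome, Biostrings::DNAStringSet(as.character(copy)))
  names(genome2) <- c(names(ref$genome), "extra")
  after <- build_ambiguity_mask(ref$transcripts, genome2)
  for (g in gene_ids(ref$transcripts))
    expect_true(all(after$ambiguity[[g]] >= before$ambiguity[[g]]))
  expect_gt(sum(after$ambiguity[[gene_ids(ref$transcripts)[1]]]), 0L)
})

test_that("terminal masking trims exactly five codons per terminus and pseudo lengths are exact", {
  ref <- toy_reference(L1 = 100L, L2 = 40L)
  masks <- apply_terminal_mask(new_mask_set(ref$transcripts), n_terminal = 5L)
  expect_equal(sum(masks$terminal[["tg1"]]), 10L)
  expect_true(all(which(masks$terminal[["tg1"]]) %in% c(1:5, 96:100)))
  expect_equal(unname(pseudo_lengths(masks)["tg1"]), 90L)
  # union with an existing ambiguity mask is idempotent
  masks$ambiguity[["tg1"]][3L] <- TRUE
  expect_equal(sum(gene_mask(masks, "tg1")), 10L)
  # pseudo_length + masked = L for every gene, exactly
  for (g in gene_ids(ref$transcripts))
    expect_identical(unname(pseudo_lengths(masks)[g]) +
                       sum(gene_mask(masks, g)),
                     ref$transcripts[[g]]$L)
})

test_that("an ORF of at most ten codons becomes fully masked and is excluded", {
  ref <- toy_reference(L1 = 10L, L2 = 40L)
  expect_warning(masks <- apply_terminal_mask(new_mask_set(ref$transcripts)),
                 "fully masked")
  expect_equal(excluded_genes(masks), "tg1")
  expect_equal(unname(pseudo_lengths(masks)["tg1"]), 0L)
})

test_that("mask files list every masked codon with its provenance", {
  ref <- toy_reference(L1 = 30L, L2 = 40L)
  masks <- apply_terminal_mask(new_mask_set(ref$transcripts))
  masks$ambiguity[["tg1"]][c(3L, 15L)] <- TRUE
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mask(masks, tmp)
  tab <- read.delim(tmp)
  expect_equal(sum(tab$gene_id == "tg1"), 11L)  # 10 terminal + 1 interior
  expect_equal(tab$provenance[tab$gene_id == "tg1" & tab$codon_index == 2L],
               "ambiguity+terminal")
  expect_equal(tab$provenance[tab$gene_id == "tg1" & tab$codon_index == 14L],
               "ambiguity")
})
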