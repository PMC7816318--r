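## Ground-truth simulator: genomes, annotations, feature tables and
## fractionated footprint libraries emulating the statistical structure of a
## fungal Ribo-seq experiment — a 5'-biased global density ramp, per-gene
## initiation rates, duplicated CDS stretches that create ambiguous 28-nt
## fragments, and class-dependent membrane-association fractions.

#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the test
#' suite: 150 genes with log-normal ORF lengths (median 350 codons), a
#' linear 5' density ramp of amplitude 3 decaying to 1 over 200 codons with
#' a 3x start-codon occupancy peak, 10% of genes carrying a verbatim 60-nt
#' duplication, log-normal initiation rates (sdlog 1), membrane fractions
#' 0.9 for cotranslationally translocated classes versus 0.1 otherwise,
#' footprint lengths 27-29 nt with 90% frame fidelity, and one million
#' reads per library.
#'
#' @param n_genes number of genes.
#' @param length_meanlog,length_sdlog log-normal ORF length distribution
#'   (codons).
#' @param length_codons optional explicit ORF lengths (codons), recycled to
#'   `n_genes`; overrides the log-normal draw.
#' @param min_codons minimum ORF length (codons).
#' @param duplication_fraction fraction of genes receiving a planted
#'   verbatim copy of a donor CDS segment.
#' @param duplication_nt planted segment length (nt, multiple of 3).
#' @param bias_amplitude,bias_width global ramp g*(p): density
#'   `bias_amplitude` at the start codon decaying linearly to 1 over
#'   `bias_width` codons.
#' @param start_peak occupancy multiplier at codon 0 (initiation pause);
#'   falls inside the terminal mask, so it affects only offset calibration.
#' @param class_probs named probabilities over gene classes
#'   `cotranslational_ER`, `posttranslational_ER`, `mitochondrial`,
#'   `cytosolic`.
#' @param membrane_fraction named per-class probability that a read from
#'   the gene is recovered in the membrane fraction.
#' @param sp_length_slope length-dependence of membrane attachment for
#'   signal-peptide genes: logit(f) gains `sp_length_slope * log2(L /
#'   sp_length_ref)`. 0 disables.
#' @param sp_length_ref reference ORF length (codons) for the slope.
#' @param init_meanlog,init_sdlog log-normal initiation-rate distribution.
#' @param depth reads per library (the total fraction; membrane + soluble
#'   partition the same reads).
#' @param replicates number of replicates per fraction.
#' @param read_lengths,length_probs footprint length distribution (nt).
#' @param frame_fidelity probability that a read's 3' end is exactly at the
#'   planted offset (otherwise jittered +/- 1 nt).
#' @param low_mapq_fraction fraction of reads emitted with mapq 10 instead
#'   of 60.
#' @param utr untranslated flank per gene (nt).
#' @param gap intergenic spacer (nt).
#' @param seed integer seed recorded in the config and used by the
#'   generators.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 150L,
                       length_meanlog = log(350), length_sdlog = 0.6,
                       length_codons = NULL,
                       min_codons = 60L,
                       duplication_fraction = 0.1, duplication_nt = 60L,
                       bias_amplitude = 3, bias_width = 200L,
                       start_peak = 3,
                       class_probs = c(cotranslational_ER = 0.15,
                                       posttranslational_ER = 0.10,
                                       mitochondrial = 0.10,
                                       cytosolic = 0.65),
                       membrane_fraction = c(cotranslational_ER = 0.9,
                                             posttranslational_ER = 0.1,
                                             mitochondrial = 0.9,
                                             cytosolic = 0.1),
                       sp_length_slope = 0, sp_length_ref = 300L,
                       init_meanlog = 0, init_sdlog = 1,
                       depth = 1e6, replicates = 2L,
                       read_lengths = c(27L, 28L, 29L),
                       length_probs = c(0.15, 0.70, 0.15),
                       frame_fidelity = 0.9,
                       low_mapq_fraction = 0,
                       utr = 50L, gap = 30L,
                       seed = 1L) {
  stopifnot(duplication_nt %% 3L == 0L,
            abs(sum(class_probs) - 1) < 1e-8,
            all(membrane_fraction >= 0 & membrane_fraction <= 1),
            frame_fidelity >= 0 && frame_fidelity <= 1,
            depth > 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Global bias profile used by the simulator
#'
#' Linear ramp from `amplitude` at the start codon to 1 at `width` codons,
#' flat beyond; optionally with the start-codon occupancy peak applied.
#'
#' @param p 0-based codon positions.
#' @param amplitude,width ramp parameters.
#' @param start_peak multiplier applied at `p == 0` (default 1 = none).
#' @return numeric vector of relative densities.
#' @export
sim_bias_profile <- function(p, amplitude = 3, width = 200L,
                             start_peak = 1) {
  g <- amplitude - (amplitude - 1) * pmin(p, width) / width
  g * ifelse(p == 0L, start_peak, 1)
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_nt <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference: genome, annotation, features and ground truth
#'
#' Generates random single-exon CDSs (start codon, sense codons, stop
#' codon) packed with fixed UTR flanks and intergenic spacers onto one
#' chromosome, on random strands. A `duplication_fraction` of genes receive
#' a verbatim in-frame copy of one donor gene's CDS segment, creating
#' ambiguous footprint-length fragments. The feature table is consistent
#' with each gene's planted class.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_reference`: `genome` (DNAStringSet),
#'   `transcripts`, `features`, `truth` (per gene: class, features, true
#'   initiation rate, membrane fraction, ribosome load, planted duplication
#'   coordinates), `config`.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%03d", seq_len(n))
  L <- if (!is.null(config$length_codons)) {
    as.integer(rep_len(config$length_codons, n))
  } else {
    pmax(config$min_codons,
         as.integer(round(stats::rlnorm(n, config$length_meanlog,
                                        config$length_sdlog))))
  }
  ## planted class composition is exact (largest-remainder rounding),
  ## mirroring the exact-count semantics of planted duplications
  n_per <- floor(n * config$class_probs)
  short <- n - sum(n_per)
  if (short > 0L) {
    frac <- n * config$class_probs - n_per
    bump <- order(frac, decreasing = TRUE)[seq_len(short)]
    n_per[bump] <- n_per[bump] + 1L
  }
  cls <- sample(rep(names(config$class_probs), n_per))

  ## feature table consistent with the planted class
  sp <- tmd <- gpi <- loc <- character(0L)
  feat <- data.frame(gene_id = ids, has_signal_peptide = FALSE,
                     tmd_count = 0L, has_gpi = FALSE,
                     localization = "cytoplasm", cog_category = "S",
                     stringsAsFactors = FALSE)
  cogs <- c("J", "O", "C", "G", "U", "P", "I", "M", "S", "unknown")
  feat$cog_category <- sample(cogs, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (cls[i] == "cotranslational_ER") {
      if (stats::runif(1) < 0.5) {            # polytopic membrane protein
        feat$tmd_count[i] <- sample(2:10, 1L)
        feat$localization[i] <- "cell_membrane"
      } else {                                # secreted / lumenal / GPI
        feat$has_signal_peptide[i] <- TRUE
        feat$tmd_count[i] <- sample(0:1, 1L, prob = c(0.7, 0.3))
        feat$has_gpi[i] <- stats::runif(1) < 0.5
        feat$localization[i] <- sample(c("extracellular",
                                         "endoplasmic_reticulum"), 1L)
      }
    } else if (cls[i] == "posttranslational_ER") {
      feat$has_signal_peptide[i] <- TRUE
      feat$tmd_count[i] <- sample(0:1, 1L, prob = c(0.8, 0.2))
      feat$has_gpi[i] <- stats::runif(1) < 0.6
      feat$localization[i] <- "extracellular"
    } else if (cls[i] == "mitochondrial") {
      feat$localization[i] <- "mitochondrion"
      feat$tmd_count[i] <- sample(0:1, 1L, prob = c(0.7, 0.3))
    } else {
      feat$localization[i] <- sample(c("cytoplasm", "nucleus"), 1L,
                                     prob = c(0.8, 0.2))
    }
  }

  ## CDS sequences: ATG + sense codons + TAA
  cds <- vapply(L, function(l) {
    paste0("ATG", paste0(sample(SENSE_CODONS, l - 2L, replace = TRUE),
                         collapse = ""), "TAA")
  }, character(1L))

  ## planted duplications: verbatim in-frame copy of a donor segment
  dupc <- config$duplication_nt %/% 3L
  n_dup <- round(config$duplication_fraction * n)
  dup_start <- rep(NA_integer_, n)
  donor <- NA_integer_
  donor_start <- NA_integer_
  if (n_dup > 0L) {
    eligible <- which(L >= dupc + 20L)
    donor <- eligible[which.max(L[eligible])]
    donor_start <- 10L
    segment <- substr(cds[donor], 3L * donor_start + 1L,
                      3L * (donor_start + dupc))
    recipients <- sample(setdiff(eligible, donor),
                         min(n_dup, length(eligible) - 1L))
    for (r in recipients) {
      rs <- sample(6:(L[r] - 6L - dupc), 1L)
      substr(cds[r], 3L * rs + 1L, 3L * (rs + dupc)) <- segment
      dup_start[r] <- rs
    }
  }

  ## pack onto one chromosome with UTR flanks, spacers and random strands
  strand <- sample(c("+", "-"), n, replace = TRUE)
  pieces <- character(2L * n + 1L)
  pieces[1L] <- random_nt(config$gap)
  cds_start <- cds_end <- integer(n)
  at <- config$gap
  for (i in seq_len(n)) {
    unit <- paste0(random_nt(config$utr), cds[i], random_nt(config$utr))
    if (strand[i] == "-")
      unit <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(unit)))
    if (strand[i] == "+") {
      cds_start[i] <- at + config$utr
    } else {
      cds_start[i] <- at + config$utr  # leftmost CDS base either way
    }
    cds_end[i] <- cds_start[i] + 3L * L[i]
    pieces[2L * i] <- unit
    pieces[2L * i + 1L] <- random_nt(config$gap)
    at <- at + 2L * config$utr + 3L * L[i] + config$gap
  }
  genome <- Biostrings::DNAStringSet(paste0(pieces, collapse = ""))
  names(genome) <- "chr1"

  transcripts <- transcript_models(lapply(seq_len(n), function(i) {
    new_transcript_model(ids[i], "chr1", strand[i],
                         cbind(start = cds_start[i], end = cds_end[i]))
  }))

  ## ground truth
  rate <- stats::rlnorm(n, config$init_meanlog, config$init_sdlog)
  mf <- unname(config$membrane_fraction[cls])
  if (config$sp_length_slope != 0) {
    adj <- feat$has_signal_peptide
    mf[adj] <- stats::plogis(stats::qlogis(mf[adj]) +
                               config$sp_length_slope *
                               log2(L[adj] / config$sp_length_ref))
  }
  load <- vapply(seq_len(n), function(i) {
    rate[i] * sum(sim_bias_profile(0:(L[i] - 1L), config$bias_amplitude,
                                   config$bias_width, config$start_peak))
  }, numeric(1L))
  truth <- data.frame(gene_id = ids, class = cls, L = L,
                      init_rate = rate, membrane_fraction = mf,
                      load = load, dup_start = dup_start,
                      dup_len_codons = ifelse(is.na(dup_start), NA_integer_,
                                              dupc),
                      stringsAsFactors = FALSE)
  attr(truth, "donor") <- if (is.na(donor)) NULL else
    list(gene_id = ids[donor], start = donor_start, len_codons = dupc)

  structure(list(genome = genome, transcripts = transcripts,
                 features = feat, truth = truth, config = config),
            class = "sim_reference")
}

#' Simulate fractionated footprint libraries
#'
#' Reads are drawn per (gene, codon) with probability proportional to the
#' gene's initiation rate times the planted bias profile, then assigned to
#' the membrane versus soluble fraction by the gene's membrane fraction;
#' the total library is the union of both. 3'-end coordinates are
#' back-computed from the P-site codon via per-length canonical offsets,
#' with `1 - frame_fidelity` of reads jittered +/- 1 nt.
#'
#' @param reference a `sim_reference`.
#' @param config optional [sim_config()]; defaults to the one inside
#'   `reference`.
#' @return named list of footprint data.frames
#'   (`total_rep1`, `soluble_rep1`, `membrane_rep1`, ...), each with the
#'   canonical columns plus `true_gene` and `true_codon`.
#' @export
simulate_footprints <- function(reference, config = reference$config) {
  tr <- reference$transcripts
  truth <- reference$truth
  L <- truth$L
  n <- nrow(truth)
  gene_of <- rep.int(seq_len(n), L)
  codon_of <- unlist(lapply(L, function(l) 0:(l - 1L)), use.names = FALSE)
  w <- truth$init_rate[gene_of] *
    sim_bias_profile(codon_of, config$bias_amplitude, config$bias_width,
                     config$start_peak)
  gstart <- vapply(tr, function(m) m$segments[1L, "start"], integer(1L))
  gend <- vapply(tr, function(m) m$segments[1L, "end"], integer(1L))
  strand <- vapply(tr, `[[`, character(1L), "strand")

  out <- list()
  for (rep_i in seq_len(config$replicates)) {
    set.seed((config$seed + 104729L * rep_i) %% .Machine$integer.max)
    depth <- as.integer(config$depth)
    idx <- sample.int(length(w), depth, replace = TRUE, prob = w)
    gi <- gene_of[idx]
    p <- codon_of[idx]
    len <- sample(config$read_lengths, depth, replace = TRUE,
                  prob = config$length_probs)
    offset <- default_psite_offset(len)
    u <- stats::runif(depth)
    delta <- ifelse(u < config$frame_fidelity, 0L,
                    ifelse(u < config$frame_fidelity +
                             (1 - config$frame_fidelity) / 2, -1L, 1L))
    tx_end3 <- 3L * p + offset + delta
    end3 <- ifelse(strand[gi] == "+",
                   gstart[gi] + tx_end3,
                   gend[gi] - 1L - tx_end3)
    mapq <- rep(60L, depth)
    if (config$low_mapq_fraction > 0)
      mapq[stats::runif(depth) < config$low_mapq_fraction] <- 10L
    fp <- data.frame(chromosome = "chr1",
                     strand = strand[gi],
                     end3 = as.integer(end3),
                     length = as.integer(len),
                     mapq = mapq,
                     true_gene = truth$gene_id[gi],
                     true_codon = p,
                     stringsAsFactors = FALSE)
    membrane <- stats::runif(depth) < truth$membrane_fraction[gi]
    out[[paste0("total_rep", rep_i)]] <- fp
    out[[paste0("membrane_rep", rep_i)]] <- fp[membrane, , drop = FALSE]
    out[[paste0("soluble_rep", rep_i)]] <- fp[!membrane, , drop = FALSE]
  }
  out
}

#' Write a simulated reference to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `features.tsv`, `truth.tsv` and a
#' YAML echo of the configuration (`sim_config.yaml`) into `dir`.
#'
#' @param reference a `sim_reference`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(reference$genome, file.path(dir, "genome.fa"))
  write_transcript_models(reference$transcripts,
                          file.path(dir, "annotation.gff3"))
  write_feature_table(reference$features, file.path(dir, "features.tsv"))
  utils::write.table(reference$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- reference$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
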