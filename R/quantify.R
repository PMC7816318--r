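## Per-gene expression metrics. cTPM estimates nascent-chain production
## (rate-like: corrected reads per unmasked codon); cRPM estimates ribosome
## sequestration (load-like: mask-compensated read counts). TPM/RPM are the
## uncorrected analogues, reported for comparison.

#' Uncorrected TPM and RPM
#'
#' Standard transcripts-per-million over ORF codon length, and reads per
#' million, computed from raw (unmasked, uncorrected) codon counts.
#'
#' @param counts a `codon_counts` object.
#' @return data.frame with columns `gene_id`, `raw_reads`, `tpm`, `rpm`.
#' @export
compute_tpm_rpm <- function(counts) {
  raw <- vapply(counts$counts, sum, numeric(1L))
  L <- lengths(counts$counts)
  rate <- raw / L
  data.frame(gene_id = names(raw),
             raw_reads = as.integer(raw),
             tpm = 1e6 * rate / sum(rate),
             rpm = 1e6 * raw / sum(raw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Corrected transcripts per million (cTPM)
#'
#' Per gene, the mean profile-corrected read count over unmasked codons
#' (total corrected reads divided by the pseudo gene length), scaled to one
#' million across the quantified gene universe. Genes with pseudo length 0
#' are excluded from the denominator and reported as `NA`.
#'
#' @param corrected a `corrected_counts` object.
#' @param masks a `mask_set`.
#' @return named numeric vector of cTPM values.
#' @export
compute_ctpm <- function(corrected, masks) {
  pl <- pseudo_lengths(masks)[names(corrected$corrected)]
  rate <- vapply(names(corrected$corrected), function(g) {
    if (pl[[g]] == 0L) return(NA_real_)
    sum(corrected$corrected[[g]], na.rm = TRUE) / pl[[g]]
  }, numeric(1L))
  1e6 * rate / sum(rate, na.rm = TRUE)
}

#' Per-gene ribosome scaling factor
#'
#' The reciprocal of the fraction of ribosomes expected to remain observable
#' when the gene's mask is applied to the global profile:
#' `sum(g[1..L]) / sum(g[unmasked])`. Exactly 1 for an empty mask, > 1
#' otherwise; `NA` for fully masked genes.
#'
#' @param transcripts a `transcript_models` object.
#' @param profile a `global_profile`.
#' @param masks a `mask_set`.
#' @return named numeric vector of scaling factors.
#' @export
compute_ribosome_scaling_factor <- function(transcripts, profile, masks) {
  g <- unclass(profile)
  vapply(gene_ids(transcripts), function(gene) {
    L <- transcripts[[gene]]$L
    mask <- gene_mask(masks, gene)
    gv <- g[seq_len(L)]
    denom <- sum(gv[!mask])
    if (denom == 0) return(NA_real_)
    sum(gv) / denom
  }, numeric(1L))
}

#' Corrected ribosomes per million (cRPM)
#'
#' Unmasked raw read counts multiplied by the gene's ribosome scaling factor
#' and scaled to one million across the quantified universe.
#'
#' @param counts a `codon_counts` object.
#' @param masks a `mask_set`.
#' @param scaling_factors named vector from
#'   [compute_ribosome_scaling_factor()].
#' @return named numeric vector of cRPM values.
#' @export
compute_crpm <- function(counts, masks, scaling_factors) {
  load <- vapply(names(counts$counts), function(g) {
    f <- scaling_factors[[g]]
    if (is.na(f)) return(NA_real_)
    sum(counts$counts[[g]][!gene_mask(masks, g)]) * f
  }, numeric(1L))
  1e6 * load / sum(load, na.rm = TRUE)
}

#' Assemble per-gene metrics for one sample
#'
#' Runs the full quantification for one library: raw TPM/RPM, metagene
#' profile, corrected counts, cTPM, ribosome scaling factors and cRPM.
#' Genes excluded from quantification (fully masked) carry `NA` metrics so
#' they do not distort per-million denominators.
#'
#' @param counts a `codon_counts` object.
#' @param transcripts a `transcript_models` object.
#' @param masks a `mask_set`.
#' @param profile optional precomputed `global_profile`; built from this
#'   sample's counts when `NULL`.
#' @param min_mean_reads,aggregate passed to [build_global_profile()].
#' @return data.frame (one row per gene) with columns `gene_id`, `sample`,
#'   `raw_reads`, `tpm`, `ctpm`, `rpm`, `crpm`, `scaling_factor`,
#'   `pseudo_length`; the profile used is attached as attribute `profile`.
#' @export
gene_metrics <- function(counts, transcripts, masks, profile = NULL,
                         min_mean_reads = 1, aggregate = "mean") {
  if (is.null(profile))
    profile <- build_global_profile(counts, masks,
                                    min_mean_reads = min_mean_reads,
                                    aggregate = aggregate)
  corrected <- correct_counts(counts, profile, masks)
  base <- compute_tpm_rpm(counts)
  ctpm <- compute_ctpm(corrected, masks)
  rsf <- compute_ribosome_scaling_factor(transcripts, profile, masks)
  crpm <- compute_crpm(counts, masks, rsf)
  out <- data.frame(gene_id = base$gene_id,
                    sample = counts$sample,
                    raw_reads = base$raw_reads,
                    tpm = base$tpm,
                    ctpm = as.numeric(ctpm[base$gene_id]),
                    rpm = base$rpm,
                    crpm = as.numeric(crpm[base$gene_id]),
                    scaling_factor = as.numeric(rsf[base$gene_id]),
                    pseudo_length = as.integer(pseudo_lengths(masks)[base$gene_id]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "profile") <- profile
  out
}

#' Write a gene-metrics table
#' @param metrics data.frame from [gene_metrics()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
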