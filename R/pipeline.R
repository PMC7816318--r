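## End-to-end orchestration over files: offsets -> mask -> per-sample
## quantification -> enrichment -> classification -> ontology summaries,
## with a YAML run manifest for provenance.

#' Run the full quantification and classification pipeline
#'
#' Sample names must follow `<fraction>_rep<i>` with fraction one of
#' `total`, `soluble`, `membrane`. The metagene profile is built per
#' sample; P-site offsets are calibrated once on all reads pooled (or taken
#' from `offsets`).
#'
#' @param genome_path genome FASTA.
#' @param gff3_path transcript models (GFF3).
#' @param feature_path per-gene feature TSV.
#' @param footprint_paths named character vector of footprint TSV/BAM paths
#'   (names = sample labels, e.g. `membrane_rep1`).
#' @param out_dir output directory.
#' @param offsets optional `offset_table` or path to an offset TSV;
#'   estimated from the data when `NULL`.
#' @param mapq_min,k,n_terminal,lengths,min_mean_reads,aggregate,pseudocount,threshold
#'   stage parameters (defaults: mapping quality 60, 28-nt fragments, 5
#'   terminal codons, calibration lengths 25-31, expression filter 1
#'   read/codon, mean aggregation, pseudocount 0.5, threshold 2).
#' @param contrast `"membrane_vs_soluble"` (default) or
#'   `"total_vs_soluble"`.
#' @return invisibly, a list with `metrics` (per-sample data.frames),
#'   `enrichment` (combined per-gene table), `summary_all`, `summary_er`,
#'   and `manifest` (path).
#' @export
run_pipeline <- function(genome_path, gff3_path, feature_path,
                         footprint_paths, out_dir,
                         offsets = NULL, mapq_min = 60L, k = 28L,
                         n_terminal = 5L, lengths = 25:31,
                         min_mean_reads = 1, aggregate = "mean",
                         pseudocount = 0.5, threshold = 2.0,
                         contrast = c("membrane_vs_soluble",
                                      "total_vs_soluble")) {
  contrast <- match.arg(contrast)
  stage <- function(name, expr) {
    message(format(Sys.time(), "%H:%M:%S"), " [", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- stage("read", read_genome(genome_path))
  transcripts <- stage("read", read_transcript_models(gff3_path))
  features <- stage("read", read_feature_table(feature_path, transcripts))
  fps <- stage("read", lapply(footprint_paths, read_footprints))

  if (is.null(offsets)) {
    pooled <- do.call(rbind, fps)
    offsets <- stage("psite", estimate_offsets(pooled, transcripts,
                                               lengths = lengths,
                                               mapq_min = mapq_min))
  } else if (is.character(offsets)) {
    offsets <- read_offset_table(offsets)
  }
  write_offset_table(offsets, file.path(out_dir, "offsets.tsv"))

  masks <- stage("mask", build_mask(transcripts, genome, k = k,
                                    n_terminal = n_terminal))
  write_mask(masks, file.path(out_dir, "mask.tsv"))

  metrics <- list()
  for (s in names(fps)) {
    counts <- stage("quantify", build_codon_counts(fps[[s]], offsets,
                                                   transcripts,
                                                   mapq_min = mapq_min,
                                                   sample = s))
    m <- stage("quantify", gene_metrics(counts, transcripts, masks,
                                        min_mean_reads = min_mean_reads,
                                        aggregate = aggregate))
    write_metrics(m, file.path(out_dir, paste0("metrics_", s, ".tsv")))
    write_profile(attr(m, "profile"),
                  file.path(out_dir, paste0("profile_", s, ".tsv")))
    metrics[[s]] <- m
  }

  num_frac <- if (contrast == "membrane_vs_soluble") "membrane" else "total"
  reps <- sub(paste0("^", num_frac, "_"), "",
              grep(paste0("^", num_frac, "_rep"), names(metrics),
                   value = TRUE))
  reps <- reps[paste0("soluble_", reps) %in% names(metrics)]
  if (!length(reps))
    stop("contrast ", contrast, " requires matching '", num_frac,
         "_rep<i>' and 'soluble_rep<i>' samples; available: ",
         paste(names(metrics), collapse = ", "))
  ctpm_of <- function(m) stats::setNames(m$ctpm, m$gene_id)
  mean_ctpm <- function(fraction) {
    ms <- metrics[paste0(fraction, "_", reps)]
    Reduce(`+`, lapply(ms, ctpm_of)) / length(ms)
  }
  scores <- stage("enrich",
                  membrane_enrichment(mean_ctpm(num_frac),
                                      mean_ctpm("soluble"), pseudocount))
  enrichment <- stage("classify",
                      enrichment_table(scores, features, contrast,
                                       threshold))
  utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  base_sample <- if (any(grepl("^total_rep", names(metrics))))
    grep("^total_rep", names(metrics), value = TRUE)[1L] else names(metrics)[1L]
  routes <- stats::setNames(enrichment$route, enrichment$gene_id)
  summary_all <- stage("summarize",
                       aggregate_by_category(metrics[[base_sample]], routes,
                                             features,
                                             group = "destination",
                                             universe = "all"))
  summary_er <- stage("summarize",
                      aggregate_by_category(metrics[[base_sample]], routes,
                                            features, group = "route",
                                            universe = "er"))
  utils::write.table(summary_all, file.path(out_dir, "summary_all.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_er, file.path(out_dir, "summary_er.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = as.character(utils::packageVersion("riboalloc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(mapq_min = mapq_min, k = k, n_terminal = n_terminal,
                      lengths = as.integer(lengths),
                      min_mean_reads = min_mean_reads,
                      aggregate = aggregate, pseudocount = pseudocount,
                      threshold = threshold, contrast = contrast,
                      offsets = as.list(stats::setNames(
                        as.integer(offsets), names(offsets)))),
    inputs = as.list(tools::md5sum(c(genome = genome_path,
                                     gff3 = gff3_path,
                                     features = feature_path,
                                     footprint_paths))),
    samples = names(fps))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(metrics = metrics, enrichment = enrichment,
                 summary_all = summary_all, summary_er = summary_er,
                 manifest = manifest_path))
}
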