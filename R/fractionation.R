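## Membrane-enrichment scoring from subcellular fractionation and rule-based
## classification of translocation routes and protein destinations.

ROUTE_LEVELS <- c("cotranslational_ER", "cotranslational_mito",
                  "posttranslational_ER", "cytosolic_or_other",
                  "undetermined")
DESTINATION_LEVELS <- c("secreted_lumenal_gpi", "membrane_protein",
                        "mitochondrial", "other")

#' Membrane-enrichment score
#'
#' Per gene, `log2((ctpm_numerator + pseudocount) / (ctpm_soluble +
#' pseudocount))`, computed over the genes present in both samples. The
#' numerator is the membrane (default contrast) or total fraction. Genes
#' absent from either sample, or with `NA` cTPM in either, are dropped and
#' tallied in attribute `dropped`.
#'
#' @param ctpm_numerator named numeric vector of cTPM (membrane or total).
#' @param ctpm_soluble named numeric vector of cTPM (soluble fraction).
#' @param pseudocount added to both cTPM values before the ratio
#'   (default 0.5 cTPM units; bounds scores for genes undetected in one
#'   fraction without distorting well-expressed genes).
#' @return named numeric vector of log2 scores.
#' @export
membrane_enrichment <- function(ctpm_numerator, ctpm_soluble,
                                pseudocount = 0.5) {
  shared <- intersect(names(ctpm_numerator), names(ctpm_soluble))
  num <- ctpm_numerator[shared]
  sol <- ctpm_soluble[shared]
  ok <- !is.na(num) & !is.na(sol)
  score <- log2((num[ok] + pseudocount) / (sol[ok] + pseudocount))
  attr(score, "dropped") <-
    c(absent = length(union(names(ctpm_numerator), names(ctpm_soluble))) -
        length(shared),
      not_quantified = sum(!ok))
  score
}

#' Classify translocation routes
#'
#' Genes with enrichment scores strictly greater than `threshold` are
#' cotranslationally translocated, into the mitochondrial surface when the
#' predicted localization is mitochondrion and into the ER otherwise. Genes
#' at or below the threshold with a predicted signal peptide enter the ER
#' posttranslationally; the remainder are cytosolic or other. Genes with a
#' score but no feature row are `undetermined` (tallied in attribute
#' `n_undetermined`).
#'
#' @param scores named numeric vector from [membrane_enrichment()].
#' @param features feature data.frame ([read_feature_table()]).
#' @param threshold classification threshold in log2 score units
#'   (default 2).
#' @return named character vector of routes.
#' @export
classify_route <- function(scores, features, threshold = 2.0) {
  f <- features[match(names(scores), features$gene_id), ]
  route <- rep("undetermined", length(scores))
  known <- !is.na(f$gene_id)
  mito <- known & f$localization == "mitochondrion"
  sp <- known & f$has_signal_peptide
  hi <- scores > threshold
  route[known & hi & mito] <- "cotranslational_mito"
  route[known & hi & !mito] <- "cotranslational_ER"
  route[known & !hi & sp] <- "posttranslational_ER"
  route[known & !hi & !sp] <- "cytosolic_or_other"
  names(route) <- names(scores)
  attr(route, "n_undetermined") <- sum(!known)
  route
}

#' Classify protein destinations from sequence features
#'
#' Secreted/lumenal/GPI-anchored proteins carry an N-terminal signal
#' peptide, are not predicted mitochondrial, and have at most one
#' transmembrane domain (frequently the GPI anchor). Membrane proteins
#' either lack a signal peptide but have at least one TMD, or have two or
#' more TMDs regardless of signal peptide. Remaining mitochondrially
#' localized genes are mitochondrial; everything else is other.
#'
#' @param features feature data.frame ([read_feature_table()]).
#' @return named character vector of destinations, keyed by gene id.
#' @export
classify_destination <- function(features) {
  mito <- features$localization == "mitochondrion"
  sp <- features$has_signal_peptide
  tmd <- features$tmd_count
  dest <- rep("other", nrow(features))
  dest[mito] <- "mitochondrial"
  dest[(!sp & tmd >= 1L) | tmd >= 2L] <- "membrane_protein"
  dest[sp & !mito & tmd <= 1L] <- "secreted_lumenal_gpi"
  names(dest) <- features$gene_id
  dest
}

#' Aggregate resource demands by ontology
#'
#' Summarizes, per COG category crossed with route (or destination), the
#' percentage of total cTPM (nascent chains) and total cRPM (ribosomes)
#' plus gene counts, within a stated gene universe: all quantified genes,
#' or the ER-destined subset (cotranslational ER plus posttranslational ER
#' routes).
#'
#' @param metrics data.frame from [gene_metrics()].
#' @param routes named character vector from [classify_route()].
#' @param features feature data.frame (for COG categories).
#' @param group `"route"` or `"destination"` — the classification crossed
#'   with COG.
#' @param universe `"all"` or `"er"`; percentages are relative to summed
#'   cTPM/cRPM within this universe.
#' @return data.frame with columns `cog_category`, `class`, `n_genes`,
#'   `pct_ctpm`, `pct_crpm`.
#' @export
aggregate_by_category <- function(metrics, routes, features,
                                  group = c("route", "destination"),
                                  universe = c("all", "er")) {
  group <- match.arg(group)
  universe <- match.arg(universe)
  cls <- if (group == "route") routes else classify_destination(features)
  m <- metrics[metrics$gene_id %in% names(cls) &
                 !is.na(metrics$ctpm) & !is.na(metrics$crpm), ]
  m$class <- as.character(cls[m$gene_id])
  m$cog <- features$cog_category[match(m$gene_id, features$gene_id)]
  m$cog[is.na(m$cog)] <- "unknown"
  if (universe == "er") {
    er <- names(routes)[routes %in% c("cotranslational_ER",
                                      "posttranslational_ER")]
    m <- m[m$gene_id %in% er, ]
  }
  if (!nrow(m))
    return(data.frame(cog_category = character(), class = character(),
                      n_genes = integer(), pct_ctpm = numeric(),
                      pct_crpm = numeric()))
  tot_ctpm <- sum(m$ctpm)
  tot_crpm <- sum(m$crpm)
  agg <- do.call(rbind, lapply(split(m, list(m$cog, m$class), drop = TRUE),
    function(d) data.frame(cog_category = d$cog[1L], class = d$class[1L],
                           n_genes = nrow(d),
                           pct_ctpm = 100 * sum(d$ctpm) / tot_ctpm,
                           pct_crpm = 100 * sum(d$crpm) / tot_crpm)))
  agg <- agg[order(-agg$pct_ctpm), ]
  rownames(agg) <- NULL
  agg
}

#' Correlation of enrichment scores between replicates or species
#'
#' Pearson correlation of two score vectors over their shared genes,
#' optionally restricted to a subset (e.g. one destination class).
#'
#' @param scoresA,scoresB named numeric score vectors.
#' @param subset optional character vector of gene ids to restrict to.
#' @return Pearson r (scalar).
#' @export
replicate_correlation <- function(scoresA, scoresB, subset = NULL) {
  shared <- intersect(names(scoresA), names(scoresB))
  if (!is.null(subset)) shared <- intersect(shared, subset)
  if (length(shared) < 3L)
    stop("fewer than 3 shared genes (", length(shared),
         "); cannot compute correlation")
  stats::cor(scoresA[shared], scoresB[shared], method = "pearson")
}

#' Assemble the per-gene enrichment/classification table
#'
#' @param scores named numeric vector from [membrane_enrichment()].
#' @param features feature data.frame.
#' @param contrast label, `"membrane_vs_soluble"` or `"total_vs_soluble"`.
#' @param threshold route-classification threshold (log2 units).
#' @return data.frame with columns `gene_id`, `contrast`, `score`, `route`,
#'   `destination`.
#' @export
enrichment_table <- function(scores, features,
                             contrast = c("membrane_vs_soluble",
                                          "total_vs_soluble"),
                             threshold = 2.0) {
  contrast <- match.arg(contrast)
  route <- classify_route(scores, features, threshold)
  dest <- classify_destination(features)
  data.frame(gene_id = names(scores),
             contrast = contrast,
             score = as.numeric(scores),
             route = as.character(route),
             destination = as.character(dest[names(scores)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
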