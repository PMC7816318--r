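# Membrane-enrichment scoring, route/destination rules, summaries.

toy_features <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], has_signal_peptide = r[[2]],
               tmd_count = r[[3]], has_gpi = r[[4]], localization = r[[5]],
               cog_category = r[[6]], stringsAsFactors = FALSE)))
}

test_that("enrichment scores are log2 ratios with pseudocount handling", {
  num <- c(a = 800, b = 100, c = 50)
  sol <- c(a = 100, b = 100, d = 10)
  sc <- membrane_enrichment(num, sol, pseudocount = 0)
  expect_equal(unname(sc["a"]), 3)          # log2(8)
  expect_equal(unname(sc["b"]), 0)
  expect_false("c" %in% names(sc))          # absent from soluble
  expect_equal(unname(attr(sc, "dropped")["absent"]), 2L)
  # pseudocount bounds the score of a gene absent from one fraction
  sc2 <- membrane_enrichment(c(a = 100, z = 0), c(a = 100, z = 100),
                             pseudocount = 0.5)
  expect_true(is.finite(sc2[["z"]]))
})

test_that("route rules: threshold is strict, mitochondria are filtered, signal rescues", {
  ft <- toy_features(
    list("hi_ext",  FALSE, 0L, FALSE, "extracellular", "U"),
    list("hi_mito", FALSE, 0L, FALSE, "mitochondrion", "C"),
    list("lo_sp",   TRUE,  0L, TRUE,  "extracellular", "S"),
    list("lo_cyt",  FALSE, 0L, FALSE, "cytoplasm",     "J"),
    list("border",  FALSE, 0L, FALSE, "extracellular", "U"))
  sc <- c(hi_ext = 3.0, hi_mito = 3.0, lo_sp = 0.5, lo_cyt = 0.5,
          border = 2.0, ghost = 4.0)
  route <- classify_route(sc, ft, threshold = 2.0)
  expect_equal(unname(route["hi_ext"]), "cotranslational_ER")
  expect_equal(unname(route["hi_mito"]), "cotranslational_mito")
  expect_equal(unname(route["lo_sp"]), "posttranslational_ER")
  expect_equal(unname(route["lo_cyt"]), "cytosolic_or_other")
  expect_equal(unname(route["border"]), "cytosolic_or_other")  # strict >
  expect_equal(unname(route["ghost"]), "undetermined")
  expect_equal(attr(route, "n_undetermined"), 1L)
})

test_that("destination rules follow signal/TMD/localization precedence", {
  ft <- toy_features(
    list("sec_gpi", TRUE,  1L, TRUE,  "extracellular", "S"),
    list("poly_tm", FALSE, 7L, FALSE, "cell_membrane", "P"),
    list("sp_3tmd", TRUE,  3L, FALSE, "cell_membrane", "P"),
    list("single",  FALSE, 1L, FALSE, "cytoplasm",     "S"),
    list("mito",    FALSE, 0L, FALSE, "mitochondrion", "C"),
    list("plain",   FALSE, 0L, FALSE, "cytoplasm",     "J"))
  dest <- classify_destination(ft)
  expect_equal(unname(dest["sec_gpi"]), "secreted_lumenal_gpi")
  expect_equal(unname(dest["poly_tm"]), "membrane_protein")
  expect_equal(unname(dest["sp_3tmd"]), "membrane_protein")  # >= 2 TMD wins
  expect_equal(unname(dest["single"]), "membrane_protein")   # no signal, 1 TMD
  expect_equal(unname(dest["mito"]), "mitochondrial")
  expect_equal(unname(dest["plain"]), "other")
})

test_that("ontology aggregation reports per-universe percentages and counts", {
  ft <- toy_features(
    list("a1", TRUE, 0L, FALSE, "extracellular", "S"),
    list("a2", TRUE, 0L, FALSE, "extracellular", "S"),
    list("b1", FALSE, 0L, FALSE, "cytoplasm", "J"))
  metrics <- data.frame(gene_id = c("a1", "a2", "b1"), sample = "s",
                        raw_reads = 1L, tpm = 1,
                        ctpm = c(2e5, 1e5, 7e5), rpm = 1,
                        crpm = c(1e5, 1e5, 8e5), scaling_factor = 1,
                        pseudo_length = 100L)
  routes <- c(a1 = "cotranslational_ER", a2 = "posttranslational_ER",
              b1 = "cytosolic_or_other")
  tab <- aggregate_by_category(metrics, routes, ft, group = "route",
                               universe = "all")
  expect_equal(sum(tab$pct_ctpm), 100)
  expect_equal(sum(tab$pct_crpm), 100)
  expect_equal(tab$pct_ctpm[tab$class == "cytosolic_or_other"], 70)
  expect_equal(sum(tab$n_genes), 3L)
  # ER-destined universe drops the cytosolic gene and renormalizes
  er <- aggregate_by_category(metrics, routes, ft, group = "route",
                              universe = "er")
  expect_equal(sum(er$pct_ctpm), 100)
  expect_equal(er$pct_ctpm[er$class == "cotranslational_ER"], 100 * 2 / 3)
  expect_equal(sum(er$n_genes), 2L)
})

test_that("replicate correlation handles exact, degenerate and error cases", {
  a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  expect_equal(replicate_correlation(a, a), 1)
  expect_equal(replicate_correlation(a, -a), -1)
  expect_error(replicate_correlation(a[1:2], a[1:2]), "fewer than 3")
  expect_equal(replicate_correlation(a, a, subset = c("g1", "g2", "g3")), 1)
})

test_that("independent replicates of the same truth give highly correlated scores", {
  cfg <- sim_config(n_genes = 60L, depth = 4e5, replicates = 2L, seed = 71L)
  ref <- simulate_reference(cfg)
  fps <- simulate_footprints(ref)
  masks <- build_mask(ref$transcripts, ref$genome)
  offsets <- structure(c(`27` = 14L, `28` = 15L, `29` = 16L),
                       class = "offset_table")
  score_rep <- function(i) {
    mm <- quantify_library(fps[[paste0("membrane_rep", i)]], ref, masks,
                           offsets, sample = "m")
    ms <- quantify_library(fps[[paste0("soluble_rep", i)]], ref, masks,
                           offsets, sample = "s")
    membrane_enrichment(named_ctpm(mm), named_ctpm(ms))
  }
  r <- replicate_correlation(score_rep(1), score_rep(2))
  expect_gte(r, 0.95)
})

test_that("length-limited membrane attachment yields scores increasing with ORF length", {
  # signal-peptide genes whose attachment probability grows with L
  cfg <- sim_config(n_genes = 500L, sp_length_slope = 1,
                    class_probs = c(cotranslational_ER = 0,
                                    posttranslational_ER = 1,
                                    mitochondrial = 0, cytosolic = 0),
                    membrane_fraction = c(cotranslational_ER = 0.9,
                                          posttranslational_ER = 0.5,
                                          mitochondrial = 0.9,
                                          cytosolic = 0.1),
                    duplication_fraction = 0, depth = 5e5, replicates = 1L,
                    seed = 73L)
  ref <- simulate_reference(cfg)
  fps <- simulate_footprints(ref)
  masks <- build_mask(ref$transcripts, ref$genome)
  offsets <- structure(c(`27` = 14L, `28` = 15L, `29` = 16L),
                       class = "offset_table")
  mm <- quantify_library(fps$membrane_rep1, ref, masks, offsets, "m")
  ms <- quantify_library(fps$soluble_rep1, ref, masks, offsets, "s")
  sc <- membrane_enrichment(named_ctpm(mm), named_ctpm(ms))
  ct <- suppressWarnings(
    stats::cor.test(sc[ref$truth$gene_id], ref$truth$L,
                    method = "spearman", exact = FALSE))
  expect_gt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("enrichment tables combine scores, routes and destinations per gene", {
  ft <- toy_features(list("a", TRUE, 0L, FALSE, "extracellular", "S"),
                     list("b", FALSE, 7L, FALSE, "cell_membrane", "P"))
  sc <- c(a = 2.5, b = 3.5)
  tab <- enrichment_table(sc, ft, contrast = "membrane_vs_soluble")
  expect_equal(tab$route, c("cotranslational_ER", "cotranslational_ER"))
  expect_equal(tab$destination, c("secreted_lumenal_gpi", "membrane_protein"))
  expect_equal(tab$contrast, rep("membrane_vs_soluble", 2L))
})
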