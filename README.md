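# riboalloc

Codon-resolution quantification of translational resource allocation from
ribosome profiling (Ribo-seq), with classification of cotranslational and
posttranslational ER translocation from subcellular fractionation.

Ribo-seq reads mark the positions of translating ribosomes, but two biases
break TPM-style quantification at footprint scale: short fragments from
homologous CDS stretches cannot be mapped uniquely, and ribosome density
is systematically elevated toward the 5' end of ORFs, inflating short
genes relative to long ones. `riboalloc` addresses both and derives, per
gene and library:

* **cTPM** — corrected transcripts per million. Reads are assigned to
  P-site codons (per-length 3'-end offsets calibrated on start codons),
  codons hidden by a k-mer **ambiguity mask** (default k = 28, both
  strands, exact multiplicity) plus a 5-codon terminal trim are excluded,
  counts are divided by an empirical **metagene profile** g(p) of the
  shared positional bias, summed, and normalized by the *pseudo length*
  L − masked: an estimate of the relative rate of nascent-chain
  production.
* **cRPM** — corrected ribosomes per million. Unmasked read counts are
  multiplied by the gene's **ribosome scaling factor**
  Σ<sub>p&lt;L</sub> g(p) / Σ<sub>p unmasked</sub> g(p) ≥ 1, which
  restores the ribosomes expected to be hidden under the mask: an
  estimate of each gene's share of sequestered ribosomes.
* **Membrane enrichment** — log2((cTPM<sub>membrane</sub> + c) /
  (cTPM<sub>soluble</sub> + c)) from fractionated libraries. Scores above
  a threshold (default 2, log2 units) mark cotranslational translocation
  (ER, or mitochondrial surface by predicted localization); at or below
  it, a predicted signal peptide marks posttranslational ER entry.
  Destinations (secreted/lumenal/GPI, membrane protein, mitochondrial)
  follow signal-peptide/TMD/localization rules, and ontology summaries
  report each category's share of nascent chains (cTPM) and ribosomes
  (cRPM).

Inputs are standard files: genome FASTA, CDS models in GFF3, footprint
alignments as BAM or a plain 5-column TSV (chromosome, strand, 3'-end
coordinate, length, mapq), and a per-gene feature table carrying
predictor outputs (signal peptide, TMD count, GPI, localization, COG).
A ground-truth synthetic generator (`simulate_reference()`,
`simulate_footprints()`) emulates the 5' density ramp, duplicated CDS
stretches, per-gene initiation rates and class-dependent membrane
fractions, so the whole pipeline is testable without sequencing data.

## Worked example

Simulate a 40-gene reference with fractionated libraries, quantify, and
classify:

```r
library(riboalloc)

cfg <- sim_config(n_genes = 40L, depth = 2e5, replicates = 1L, seed = 7L)
ref <- simulate_reference(cfg)
fps <- simulate_footprints(ref)

masks   <- build_mask(ref$transcripts, ref$genome)     # ambiguity + terminal
offsets <- estimate_offsets(fps$total_rep1, ref$transcripts)
offsets
#> 27 28 29
#> 14 15 16

counts <- build_codon_counts(fps$total_rep1, offsets, ref$transcripts,
                             sample = "total_rep1")
counts
#> codon_counts [total_rep1]: 40 genes, 198358 assigned reads
#> dropped: low_mapq=0, uncalibrated_length=0, outside_cds=1642, ambiguous_gene=0

metrics <- gene_metrics(counts, ref$transcripts, masks)
head(metrics[order(-metrics$ctpm), -2], 5)
#>    gene_id raw_reads   tpm   ctpm    rpm   crpm scaling_factor pseudo_length
#> 22    g022     25277 95740 112611 127431 127287          1.028           524
#> 17    g017      8637 85215  70700  43542  43758          1.054           195
#> 28    g028     12309 49892  57440  62054  61819          1.030           489
#> 24    g024      5581 74264  54764  28136  28322          1.071           142
#> 29    g029      6433 67069  53230  32431  32430          1.056           184
```

The planted offsets (length − 13 nt from the 3' end) are recovered
exactly. Gene `g022` is long and highly initiated: correction raises its
cTPM above its plain TPM (the 5' ramp had deflated it), while its cRPM
stays close to RPM because little of it is masked; the scaling factors
sit just above 1, compensating each gene's masked codons. Each metric
column sums to 10^6 over the quantified genes.

Enrichment and route classification from the membrane/soluble contrast:

```r
ctpm_of <- function(m) setNames(m$ctpm, m$gene_id)
mem <- gene_metrics(build_codon_counts(fps$membrane_rep1, offsets,
                    ref$transcripts, sample = "m"), ref$transcripts, masks)
sol <- gene_metrics(build_codon_counts(fps$soluble_rep1, offsets,
                    ref$transcripts, sample = "s"), ref$transcripts, masks)
scores <- membrane_enrichment(ctpm_of(mem), ctpm_of(sol))
tab <- enrichment_table(scores, ref$features)
table(tab$route)
#>   cotranslational_ER cotranslational_mito   cytosolic_or_other
#>                    6                    4                   26
#> posttranslational_ER
#>                    4

head(tab[order(-tab$score), ], 3)
#>    gene_id            contrast score                route          destination
#> 21    g021 membrane_vs_soluble  4.60 cotranslational_mito     membrane_protein
#> 16    g016 membrane_vs_soluble  4.60   cotranslational_ER secreted_lumenal_gpi
#> 17    g017 membrane_vs_soluble  4.52   cotranslational_ER     membrane_protein
```

All 40 planted routes are recovered at this depth. For file-driven runs,
`run_pipeline()` orchestrates every stage (offsets → mask → metagene →
quantification per sample → enrichment → classification → ontology
summaries) and writes per-sample metrics tables, the enrichment table,
Table-style summaries and a YAML manifest of parameters and input
checksums. `aggregate_by_category()` produces the ontology shares, and
`replicate_correlation()` the cross-replicate or cross-species score
agreement. The scientific background, estimator details and all tunable
parameters are documented in `vignettes/riboalloc-methods.Rmd`.

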