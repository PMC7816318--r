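---
title: "Quantifying translational resource allocation from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translational resource allocation from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboalloc)
```

## The problem

Ribosome profiling (Ribo-seq) sequences the ~18–34 nt mRNA fragments
protected by translating ribosomes, so each read marks one ribosome's
position at codon resolution. Two questions about cellular resource
allocation follow naturally: how many nascent polypeptide chains does each
gene produce per unit time, and how many ribosomes does each gene hold
sequestered while doing so? In organisms engineered for protein secretion
(methylotrophic yeasts and other fungal hosts), a third question matters as
much: which of those nascent chains enter the endoplasmic reticulum, and
through which route — cotranslationally, with the ribosome docked at the
Sec translocon, or posttranslationally, after release into the cytosol?

Plain TPM-style metrics answer none of these well at footprint scale, for
two reasons this package addresses explicitly:

1. **Ambiguity.** Footprints are short; homologous CDS stretches make some
   fragments impossible to place uniquely, and both discarding and random
   assignment distort counts in opposite directions.
2. **Positional bias.** Ribosome density is systematically higher toward
   the 5' end of ORFs, so short ORFs — which sample only the ribosome-rich
   region — look inflated relative to long ones.

## The pipeline

### P-site assignment

Reads are collapsed to their 3'-end genomic base (`end3`; the leftmost
aligned base for minus-strand alignments). For each footprint length, a
P-site offset is calibrated by counting, over candidate offsets `0 ≤ o <
length`, the shifted reads landing exactly on annotated start codons,
restricted to reads whose 3' end lies within one footprint length of a
start; the arg-max wins, with ties broken toward the smaller offset, and
lengths with fewer than `min_reads` (default 50) calibrating reads are
dropped rather than guessed. Reads are then assigned to the codon
containing the shifted position; reads below the mapping-quality threshold
(default 60), with uncalibrated lengths, shifted outside any CDS, or whose
3' end lies in overlapping CDS of several genes are dropped and tallied,
so that counts plus tallies reconcile exactly with the input.

The calibration needs a landmark at the start codon. Real metagene profiles
show a strong initiation peak there, which is what makes the arg-max
identifiable; the synthetic generator therefore plants a start-codon
occupancy multiplier (default 3×). Because the first five codons are
terminally masked, that peak never reaches quantification — it exists only
for the calibrator to find.

### Ambiguity mask and terminal trimming

Every k-nt window (default k = 28, the canonical footprint length) of every
spliced CDS is tested for multiplicity: a fragment is ambiguous if its
exact sequence or reverse complement occurs at more than one genomic
location (a reverse-complement palindrome occurring once counts once).
Each ambiguous fragment masks the codon its P-site would receive under the
canonical 28-nt offset, so the mask lives in the same coordinate system as
real reads. Exact k-mer multiplicity replaces aligner-based remapping at
two MAPQ cutoffs: it is deterministic, aligner-free, and captures the same
notion of a multi-mapping position; the cost is that mismatch-tolerant
near-duplicates are not caught. The first and last five codons of every
ORF are additionally masked (`n_terminal = 5`), absorbing the
initiation/termination artifacts of the protocol. An ORF of ≤ 2·n_terminal
codons becomes fully masked and is excluded from quantification with `NA`
metrics — reporting zeros instead would silently distort the per-million
denominators of downstream re-analyses. The unmasked remainder is the
gene's *pseudo length*.

### Metagene profile and correction

The shared positional bias is estimated as a global profile `g[p]` over
0-based codon positions. Each qualifying ORF (mean unmasked reads/codon ≥
`min_mean_reads`, default 1) contributes its unmasked counts divided by a
per-ORF expression scale; the per-position mean (or median) across ORFs
long enough to reach `p` is the raw profile. The naive choice of scale —
the ORF's own mean count — leaves a length-composition bias: the profile
then estimates `g*(p) · h(p)` with `h(p) = mean(1/c_g | L > p)`, and in
the deterministic limit equal-initiation genes of 300 versus 3000 codons
end up with cTPM ratios of 1.2–1.3 rather than 1. Since removing exactly
this length bias is the point of the correction, the estimator iterates
the same two steps to their fixed point: scale = mean profile-corrected
count, profile = positional aggregate of rescaled counts (default 20
iterations, early exit when scales change by < 1e-8; `iterations = 1`
reproduces the plain one-pass composite). The iteration is an alternating
fit of the rank-1 model `counts[g, p] ≈ rate_g · g(p)` under the
triangular missingness induced by gene lengths, and converges
geometrically.

The converged series is smoothed piecewise — centered rolling mean with
window 10 for positions 1–100, window 100 for positions 100–1000, centered
rolling median with window 1000 beyond, windows truncated at the series
boundaries and segments concatenated without blending. The window-100
regime biases the estimate near the ramp kink by at most `slope·W/8`
(12.5% for the simulator's default ramp), which is the tolerance the
recovery tests use. Positions with no observations (beyond the longest
qualifying ORF, e.g. in a shallow fraction library) take the nearest
observed value: the profile is flat at depth, so plateau extension is the
unbiased completion, and it prevents a handful of deep reads from being
divided by the numerical floor (`epsilon = 1e-6`, retained purely as
division safety). Masked codons are invisible throughout: they enter
neither the per-ORF scale nor the positional aggregate, and they carry no
corrected value.

### cTPM, the ribosome scaling factor, and cRPM

For each library:

* **cTPM** (corrected transcripts per million) — per gene, the sum of
  profile-corrected counts over unmasked codons divided by the pseudo
  length, scaled to 10^6 across the quantified universe. It estimates the
  relative rate of nascent-chain production.
* **Ribosome scaling factor** — `sum(g[1..L]) / sum(g[unmasked])`: the
  reciprocal of the fraction of ribosomes expected to remain visible once
  the gene's mask hides part of the profile. Exactly 1 for an empty mask,
  strictly greater otherwise. The "smoothed reads with the mask applied"
  denominator is read as the metagene values over unmasked positions — the
  only reading that makes the factor exactly 1 for an empty mask.
* **cRPM** (corrected ribosomes per million) — unmasked raw counts times
  the scaling factor, scaled to 10^6. It estimates each gene's share of
  sequestered ribosomes. With no masks anywhere, cRPM is identical to
  plain RPM, and with a flat profile cTPM is identical to plain TPM; both
  limits are asserted in the tests.

Uncorrected TPM and RPM are always reported alongside for comparison. All
four metrics conserve their 10^6 total to numerical precision; genes
excluded from quantification are `NA`, never zero.

### Membrane enrichment and translocation classification

Subcellular fractionation splits libraries into total, soluble, and
membrane fractions. The membrane-enrichment score is
`log2((cTPM_mem + c) / (cTPM_sol + c))` (or total versus soluble by
configuration), with pseudocount `c = 0.5` cTPM units — large enough to
bound scores for genes undetected in one fraction, three to four orders of
magnitude below typical expressed-gene cTPM so it does not distort them.
Routes follow the rule set: score strictly greater than the threshold
(default 2, in log2 units — "twofold" in the figure-caption sense is
deliberately not the default reading, and the threshold is configurable)
means cotranslational translocation, split into mitochondrial surface
versus ER by predicted localization; at or below the threshold, a
predicted signal peptide indicates posttranslational ER entry; everything
else is cytosolic/other. Destinations come from sequence features alone:
signal peptide, non-mitochondrial, ≤ 1 TMD → secreted/lumenal/GPI; no
signal but ≥ 1 TMD, or ≥ 2 TMDs regardless → membrane protein;
mitochondrial localization otherwise → mitochondrial; else other. The
feature table (SignalP/TOPCONS/predGPI/DeepLoc/EggNOG-style predictor
outputs) is consumed as input; the predictors are out of scope.

Ontology summaries report, per COG category crossed with route or
destination, the percentage of summed cTPM (nascent chains) and cRPM
(ribosomes) within a stated universe — all quantified genes, or the
ER-destined subset. Replicate and cross-dataset agreement is measured as
Pearson correlation of score vectors over shared genes, optionally within
one destination class.

Note that the absolute scale of enrichment scores carries a global offset
set by fractionation efficiency (the log-ratio of the two libraries'
per-million denominators); no recentering is applied. Classification is
robust to moderate offsets because the planted separations are large.

## The synthetic generator

`simulate_reference()` and `simulate_footprints()` generate the entire
input side with known truth: random single-exon CDSs (log-normal lengths,
median 350 codons) packed on one chromosome with 50-nt UTR flanks on
random strands; a planted fraction of genes (exact count, default 10%)
carrying a verbatim in-frame 60-nt copy of a donor segment to create
genuine mapping ambiguity; log-normal initiation rates (sdlog 1); the
linear 5' ramp `g*(p) = a − (a−1)·min(p, w)/w` with defaults a = 3,
w = 200 plus the start-codon peak; per-class membrane fractions (0.9
cotranslational ER/mito, 0.1 posttranslational/cytosolic — the planted
0.9/0.1 recovery condition), optionally made length-dependent on the logit
scale for signal-peptide genes (`sp_length_slope`, default 0) to emulate
the kinetic competition that limits enrichment of short signal-peptide
ORFs; footprint lengths 27–29 nt at 0.15/0.70/0.15 with the canonical
`length − 13` offsets and 90% frame fidelity; one million reads per
library, with membrane and soluble fractions partitioning the total
exactly. Gene classes use exact planted composition (largest-remainder
rounding of the class probabilities) so that planted contrasts are
conditions rather than random variables.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: realistic codon usage and nucleotide
composition (ambiguity rates on real genomes are much higher than the
~0.3% the random-sequence default produces), rRNA and other contaminating
reads, nuclease footprint-length conformations beyond the length
distribution, splicing (simulated genes are single-exon, though the
pipeline handles multi-exon models), expression–length correlation, and
mismatch-tolerant multi-mapping.

## Numerical choices and test conditions

* Internal coordinates are 0-based half-open everywhere; GFF3's 1-based
  closed convention is converted exactly once at the I/O boundary.
* Offset ties break toward the smaller offset; uncalibrated lengths are
  dropped and tallied, never guessed.
* Profile flatness (the fixed-point property of the correction) is
  measured as the coefficient of variation of the window-10 rolling mean
  of each corrected profile — the same window the profile's early segment
  uses — because per-codon Poisson noise does not vanish at fixed depth
  and would otherwise dominate the systematic signal being tested.
* The planted eight-fold enrichment check uses a balanced two-class design
  (half the genes at membrane fraction 8/9, half at 1/9, equal initiation
  rates) so the fractionation-efficiency offset cancels and the score's
  arithmetic is isolated.
* Test problem sizes: the deep study-condition runs use the default 150
  genes at 10^6 reads per library; metagene recovery uses 40 equal-rate
  400-codon genes at 10^6 reads; oracle equivalence for the ambiguity mask
  runs on a < 50-kb genome against a `vcountPDict` brute force; unit tests
  run at 10^3–10^5 reads.

## Limitations

Metrics are relative (per-million); no absolute chains-per-minute
calibration is attempted. Footprints are assigned by their 3' end within a
single CDS segment; junction-spanning footprints of multi-exon genes are
dropped and tallied rather than split-mapped, and spliced fragments
spanning junctions are searched against the genome only, where they may
have no match and hence count as unambiguous. Ambiguity is exact-match
only. The route classifier inherits whatever systematic offset
fractionation efficiency imposes on scores; with poorly matched library
depths the fixed threshold of 2 should be revisited against the bimodal
score distribution before use.
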