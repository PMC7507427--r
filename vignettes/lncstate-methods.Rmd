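---
title: "Methods: chromatin-state and co-expression analysis of lncRNA regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state and co-expression analysis of lncRNA regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncstate)
```

## Scope and model

`lncstate` studies how the transcription of long non-coding RNAs (lncRNAs)
is controlled during myoblast differentiation by integrating four layers of
evidence around each lncRNA transcription start site (TSS): differential
expression between a proliferation (GM) and a differentiation (DM)
condition, chromatin accessibility (ATAC peaks and signal), promoter- and
enhancer-associated histone marks (H3K4me3, H3K4me1), and transcription
factor (TF) binding. Two further stages relate the resulting lncRNA sets to
co-expression structure (a weighted correlation network intersected with
Pearson edge tests) and to developmental expression dynamics of muscle stem
cells (pre-ranked gene-set enrichment across stage contrasts W2–W12),
with a known-motif enrichment step over the open-chromatin regions.

All interval arithmetic uses a single 0-based half-open convention
(BED-native); GTF input is converted once at the parsing boundary. Interval
operations are backed by `GenomicRanges`.

## Differential expression

The DE engine is intentionally a small, fully specified negative-binomial
(NB) Wald test rather than a full GLM framework; the package's contribution
is the integration, and every stage downstream only needs per-feature
`log2FC`, `p`, and an up/down/not-DE status.

* Normalization: counts per million (CPM), `counts / library_size * 1e6`.
* Fold-change: `log2((mean_cpm_B + 1) / (mean_cpm_A + 1))`. The 1-CPM
  pseudocount bounds fold-changes for features with zero counts.
* Dispersion: per-feature method of moments, `max(0, (s^2 - m) / m^2)`
  pooled across conditions by residual degrees of freedom. Raw per-feature
  moment estimates are unusably noisy at 3 replicates, so `de_test`
  squeezes them toward the global mean with a prior weight of 10 degrees of
  freedom (an empirical-Bayes moderation in the spirit of the established
  NB DE engines) and refers the Wald statistic to a t distribution whose
  degrees of freedom include the prior. On NB null simulations
  (mu = 100, phi = 0.1, 3 vs 3) this combination holds the type-I error
  near the nominal 5% (measured 3–5% in the test suite); a plain residual-df
  t is conservative by an order of magnitude and a normal reference is
  anti-conservative.
* Calling: a feature is DE when `|log2FC| >= 1` **and** `p < 0.05` (both
  are flags; `fdr = TRUE` switches the threshold to Benjamini–Hochberg
  adjusted p-values and is off by default, matching the raw-p convention
  the rest of the pipeline assumes). Direction is the sign of `log2FC`.
* `filter_low_expression` drops features with mean CPM below 1 in both
  contrasted conditions before chromatin-state annotation.

## TSS chromatin state

Each DE lncRNA (and an equal-sized random control sampled from non-DE
lncRNAs under a caller-supplied seed) receives a strand-aware TSS window of
2.5 kb upstream and 1.5 kb downstream of its 5′-most base. "Upstream"
follows the direction of transcription; the window for a minus-strand TSS
`t` is `[t - 1499, t + 2501)`.

* **Open chromatin**: the union of both conditions' ATAC peaks is merged
  (`bedtools merge` semantics: bookended intervals join at gap 0) and a
  window is open iff it shares at least one base with a merged peak. The
  half-open convention makes abutting intervals non-overlapping.
* **Categories**: merged ATAC peaks are extended by 1 kb on both sides and
  re-merged; the extended regions overlapping a window are tested against
  histone-mark peaks, giving `ATAC_H3K4me3`, `ATAC_H3K4me1` (H3K4me3 takes
  precedence when both marks are present, making the categories exclusive),
  `ATAC_only`, or `closed`. Mark co-occurrence is deliberately tested
  against the extended ATAC region rather than the raw window, because
  histone-mark peaks flank rather than coincide with accessibility summits.
* **Signal**: per-region mean per-base coverage (uncovered bases count 0)
  is computed per condition over the extended regions, quantile-normalized
  across the two condition columns, averaged over each window's overlapping
  regions, and summarized as `log2((B + 1) / (A + 1))`. Quantile
  normalization is the classic sorted-column/row-means algorithm; ties
  receive the mean of their tied reference values, which makes the
  transform deterministic and idempotent.
* **Groups**: ATAC signal fold-changes of up-regulated, down-regulated and
  control lncRNAs are compared pairwise with two-sided Mann–Whitney U
  tests (normal approximation with tie correction); with the default
  simulated gain of 4 the medians order up > control > down with very
  small p-values.
* **TF binding**: a TF is associated with a window when one of its peaks
  overlaps the window's extended ATAC regions; MyoD/MyoG co-localization is
  the ratio of windows bound by both to windows bound by either.

## Co-expression network

Expression input is `log2(CPM + 1)` of the DE features. Both network
branches run on the same matrix:

* **Weighted network**: unsigned adjacency `|r|^beta` with `beta` chosen as
  the smallest candidate power whose signed scale-free fit R² reaches 0.8
  (else the argmax); topological overlap
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`; average-linkage
  clustering on `1 - TOM` with a static cut. The static cut replaces
  dynamic tree cutting to keep module detection deterministic and
  dependency-free; its default height is 0.99 of the dendrogram's top
  merge, because absolute TOM dissimilarities vary strongly with `beta`
  while genuinely distinct modules only fuse in the final merges. Clusters
  below 20 members are left unassigned (`grey`); labels are colour-style
  strings in descending size order.
* **Pearson branch**: all pairwise correlations with the closed-form
  two-sided p from `t = r sqrt((n-2)/(1-r^2))`.
* **Intersection**: the exported TF–lncRNA network keeps Pearson edges
  between a TF and a lncRNA with network weight above 0.05 and p below
  0.01. The weight is the TOM entry by default (`weight_type =
  "adjacency"` switches to `|r|^beta`), since the module network is what
  assigns a topological weight to a pair.

## Pre-ranked GSEA

Features are ranked by `log2((mean_cpm_B + 1)/(mean_cpm_A + 1))`,
descending, ties broken lexicographically so ranking is deterministic. The
enrichment score is the signed extremum of the weighted Kolmogorov–Smirnov
running sum (hits weighted by `|metric|^p`, default `p = 1`; `p = 0`
recovers the classical KS statistic). Because the input is a pre-ranked
list rather than per-sample phenotypes, the null resamples gene sets of the
same size ("gene-set permutation"); the nominal p is
`(1 + worse) / (1 + same_sign)` among same-sign permutation scores and NES
divides by the mean same-sign null magnitude. Both are reproducible under a
caller seed.

## Motif enrichment

Known-motif enrichment replaces de novo discovery: sequences of
foreground/background regions are scanned on both strands with log-odds PWM
scores in bits (windows containing `N` are skipped), a region counts as hit
when any window reaches 60% of the motif's maximal score, and the 2×2
foreground/background table is tested with a one-sided Fisher exact test
(Haldane-corrected odds ratio when a cell is zero). The bundled PWM library
is synthetic — consensus-derived matrices for MyoD, MyoG, CTCF, Runx, AP-1
and ATF3 with 97:1 column counts — and is meant for testing and
demonstration; substitute a curated JASPAR download for real analyses. The
60% threshold together with the sharp matrices makes a hit essentially an
exact consensus match, keeping the background hit rate of a 400 bp region
low (≈0.1–0.2) while planted instances are always found.

## The synthetic study

`simulate_study()` generates every input with known ground truth. Defaults
(all overridable through `sim_config()`):

* 2 chromosomes × 5 Mb of uniform random sequence; 300 lncRNAs and 1500
  protein-coding genes (12 designated TFs, named for the myogenic
  regulators) on evenly spaced slots, so no TSS window is clamped and
  neighbouring promoter regions cannot cross-talk.
* Counts: NB with dispersion 0.1; baseline `log2` means uniform on (3, 9);
  conditions GM, DM and six stages W2–W12 with 3 replicates each. 30% of
  features are DE at `|log2FC| = 2`; the effect is split symmetrically
  across GM and DM so that with balanced up/down calls the expected library
  sizes match and CPM fold-changes carry no composition bias (plain CPM has
  no TMM-style correction to absorb one).
* Chromatin: category proportions 26/27/11/36% (H3K4me1/H3K4me3/ATAC-only/
  closed), mirroring the reported composition of open-chromatin-associated
  lncRNA promoters (~64% open, of which ~83% marked); 400 bp ATAC peaks on
  the TSS with a 4-fold DM signal gain (loss) for up- (down-) regulated
  lncRNAs; TF peaks placed in extended ATAC regions of marked promoters at
  rate 0.5, MyoD/MyoG jointly at co-localization rate 0.8.
* Modules: five 50-member modules drawn from the DE features, each seeded
  with TF hubs. A per-module latent factor acts across the W2–W12 samples
  only — co-expression in this design lives in the developmental series,
  which keeps the GM/DM contrast cleanly NB — with loadings calibrated
  from each feature's NB noise so within-module log-CPM correlation hits
  0.8 (across-series measurements land at 0.77–0.83). The pipeline
  correspondingly measures co-expression across the satellite conditions.
* Satellite dynamics: the up-regulated lncRNA set follows a planted
  rise-then-fall `log2` profile (0, 0.75, 1, 0.5, 0, −0.75 over W2–W12;
  mirrored for the down set), so its enrichment score is positive in the
  W6-vs-W2 contrast and negative in W12-vs-W2. The amplitude is kept at 1
  so the profile does not compete with module structure in clustering.
* Motifs: MyoD/MyoG consensus instances written into foreground (open DE)
  regions at rate 0.5 per motif and background (open non-DE) regions at
  0.1.

Determinism: one master seed; each stage derives a private stream, and
`with_seed` restores the caller's RNG state, so identical configs produce
byte-identical files. `validate_truth()` re-derives open status, categories
and TF binding from the generated files and checks them against the truth
table; it runs in the test suite on every generated study.

What the generator does **not** emulate: read-level noise (counts are drawn
directly), GC and mappability biases, replicate-specific library
composition effects, peak-calling uncertainty (peaks are placed, not
called), correlated histone-mark spreading, or realistic genome sequence
composition. Passing recovery tests therefore demonstrates correctness of
the implementations under the stated statistical model, not performance on
real sequencing data.

## Problem sizes and numerical choices

The default study (1800 features × 24 samples, 10 Mb genome) runs the full
pipeline in well under a minute; the test suite adds brute-force oracles
(per-base bitmaps for interval algebra, O(n³) topological overlap, direct
running-sum recomputation for enrichment scores, exact Mann–Whitney
enumeration) at sizes where exactness is checkable (n ≤ 30 nodes, ≤ 400 bp
toy chromosomes, ≤ 8-element groups). Degenerate inputs are defined rather
than left to chance: zero-variance features are excluded from correlation
with a warning, an all-zero hit weight vector in GSEA falls back to equal
hit increments, undefined co-localization (no bound windows) returns `NA`,
and an empty chromosome intersection between windows and peaks is an error
because it almost always indicates a naming-convention mismatch.

## Known limitations

* The DE test is a moderated Wald approximation, not an exact NB test;
  very low counts with few replicates are better served by edgeR/DESeq2.
* Static tree cutting has one global height; nested or close modules that
  merge below the cut are not split further.
* The network weight threshold (0.05) is interpreted on TOM values, whose
  scale depends on the soft power; comparisons across runs should fix
  `beta`.
* Signal quantification assumes disjoint bedGraph steps and equal
  weighting per base; it does not reproduce deeptools' binning exactly.
* The bundled PWMs are consensus-derived stand-ins, adequate for
  planted-motif recovery but not for real motif annotation.
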