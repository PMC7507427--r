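# lncstate

Integrative analysis of long non-coding RNA (lncRNA) transcriptional
regulation during myoblast differentiation, for epigenomics groups working
with matched RNA-seq, ATAC-seq and ChIP-seq. The package asks, for each
differentially expressed lncRNA, *why* it changes: is the chromatin around
its transcription start site (TSS) open, which histone mark decorates the
open region, which transcription factors (TFs) bind there, how does the
accessibility signal move between conditions, which TFs does the lncRNA
co-express with, and how does it behave across muscle stem-cell
development.

The pipeline has six stages, each usable on its own:

1. **Differential expression** (`de_test`) — moderated negative-binomial
   Wald test on CPM; a feature is DE when |log₂FC| ≥ 1 and p < .05.
2. **TSS chromatin state** (`annotate_chromatin_state`) — strand-aware TSS
   windows (−2.5 kb / +1.5 kb), overlap with merged ATAC peaks, categories
   `ATAC_H3K4me3` / `ATAC_H3K4me1` / `ATAC_only` / `closed` against 1 kb
   -extended open regions, quantile-normalized signal
   log₂FC = log₂((B+1)/(A+1)), TF association, and Mann–Whitney comparisons
   of up / down / non-DE control groups.
3. **Co-expression network** (`coexpression_network`) — unsigned weighted
   network (soft power by the scale-free criterion, topological overlap
   TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij), average-linkage
   modules) intersected with closed-form Pearson edge tests; TF–lncRNA
   edges kept at weight > 0.05 and p < .01.
4. **Pre-ranked GSEA** (`gsea_preranked`) — weighted Kolmogorov–Smirnov
   enrichment score with a seeded gene-set permutation null, applied to
   the up-/down-regulated lncRNA sets across developmental contrasts.
5. **Motif enrichment** (`motif_enrichment`) — both-strand log-odds PWM
   scanning and one-sided Fisher tests of foreground vs background
   open-chromatin regions.
6. **Synthetic study** (`simulate_study`) — deterministic generator with
   planted ground truth (DE calls, chromatin categories, TF binding,
   co-expression modules, motif insertions) exercising every stage with no
   external data.

`run_all(validate_config(...))` chains the stages and writes TSV outputs
plus an MD5 run manifest. File formats: GTF, BED3/6, bedGraph, TSV counts,
GMT, JASPAR-style PWM text, FASTA — all 0-based half-open internally. A
thin CLI lives at `inst/scripts/lncstate.R`.

## Worked example

```r
library(lncstate)

study <- simulate_study(sim_config(seed = 1))
study
#> sim_study: seed 1 - 1800 features on 2 chromosomes
#>                 de
#> biotype          down not_de   up
#>   lncRNA           45    208   47
#>   protein_coding  226   1043  231

de <- filter_low_expression(de_test(study$cm, "GM", "DM"))

ann <- annotate_chromatin_state(
  de, study$transcripts, study$chromatin$atac_peaks,
  study$chromatin$atac_signal, study$chromatin$k4me1_peaks,
  study$chromatin$k4me3_peaks, mark_signal = study$chromatin$mark_signal,
  tf_peaks = study$chromatin$tf_peaks,
  chrom_lengths = study$chrom_lengths, seed = 1)
ann
#> chromstate_annotation: 194 lncRNAs ( 97 DE + 97 controls )
#>   open chromatin among DE: 63/97 (64.9%)
#> category
#> ATAC_H3K4me1 ATAC_H3K4me3    ATAC_only       closed
#>           24           26           13           34

gsea_preranked(study$cm, "W2", "W6", study$sets, n_perm = 1000, seed = 1)[,
  c("set", "size", "es", "nes", "p_value")]
#>            set size         es       nes     p_value
#> 1   up_lncRNAs   47  0.8729760  2.947595 0.001727116
#> 2 down_lncRNAs   45 -0.7621551 -2.726324 0.002421308
```

Reading the output: the generator planted 92 DE lncRNAs of which 97 are
called after CPM filtering (5 false positives at the raw-p threshold);
64.9% of the called DE lncRNAs have an ATAC peak within their TSS window,
and among those open promoters most carry H3K4me1 or H3K4me3. The
up-regulated lncRNA set is strongly enriched at the top of the W6-vs-W2
developmental ranking (ES 0.87, p ≈ 0.002) — the same set flips to a
negative score in the W12-vs-W2 contrast, reproducing the planted
rise-then-fall dynamic.

The methods vignette (`vignettes/lncstate-methods.Rmd`) documents the
statistical choices, generator design and limitations.

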