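# wharv — window-based HERV alignment scoring for single-cell cohorts

`wharv` scores the transcription of autonomous human endogenous retrovirus
(HERV) loci — proviruses whose long terminal repeats can drive transcription
when chromatin is epigenetically remodeled — in one annotated cell
population (typically monocytes) of single-cell RNA-seq samples, and
compares those calls across patient cohorts. It is aimed at researchers
studying innate-immune activation (acute infection, sepsis, vaccination,
post-acute sequelae) who want locus-resolved, per-individual HERV calls
rather than aggregate transposable-element counts.

## The method

Reads carrying the barcodes of the target cell type are aligned to a
catalog of HERV loci and nearby host genes. Each region is tiled into
sequential, non-overlapping windows of L nt (default L = 100; the terminal
remainder window is kept). For sample *s* and region *r*, with *d\_w* the
mean per-base coverage of window *w* by retained reads:

* reads pass an identity filter (identity strictly > 99%) and the barcode
  filter;
* a window is **usable** when *d\_w* ≥ 3;
* the **window-similarity score (WSS)** is the percentage of covered
  windows in which every retained read matches the reference perfectly;
* the locus is called **positive** in the sample iff it has ≥ 9 usable
  windows, locus depth (mean *d\_w* over usable windows) ≥ 3, and
  WSS = 100 under the strict gate; otherwise **negative**.

Per-sample calls form a samples × loci presence matrix. A **pangenome
filter** keeps loci negative in every healthy control and positive in at
least one patient; set arithmetic reports loci unique to or shared between
cohorts; usable-window counts and depth are compared between cohorts with
Welch t-tests, and host-gene signals across groups with one-way ANOVA plus
Tukey's HSD. A synthetic-cohort generator (reference, barcoded SAMs,
ground-truth manifest) makes the whole pipeline testable without any
sequencing data; see `vignette("wha-methods")` for the model, parameter
defaults and their rationale.

## Worked example

Simulate a small cohort (4 controls, 4 acute, 4 PASC samples, 32 HERV
loci + 5 host genes), score it, filter against the controls and compare
cohorts:

```r
library(wharv)
run <- file.path(tempdir(), "wha-demo")
wha_simulate(run, seed = 42, n_controls = 4, n_acute = 4, n_pasc = 4,
             n_loci = 32)
calls <- wha_score(run)
#> C01: 1627 reads, 997 after barcode filter (0 unknown), 997 after identity filter
#> ...
#> P04: 11430 reads, 10825 after barcode filter (0 unknown), 10825 after identity filter
retained <- wha_filter(run)
#> 30 loci retained by pangenome filter
pm <- presence_matrix(calls, read.delim(file.path(run, "samples.tsv")))
intersect(retained, shared_loci(pm, sprintf("P%02d", 1:4)))[1:3]
#> [1] "HERV001" "HERV002" "HERV003"
res <- wha_compare(run)   # PASC vs acute
head(subset(res$comparisons, metric == "n_usable_windows" & significant),
     3)[, c("region_id", "statistic", "p_value", "mean_a", "mean_b")]
#>   region_id statistic      p_value mean_a   mean_b
#> 1   HERV001  3.862699 2.356988e-02  26.25 15.66667
#> 2   HERV002  5.937608 2.063129e-03  24.75 15.66667
#> 3   HERV003 16.203254 6.328187e-05  26.00 13.33333
```

The per-sample lines show reads surviving each filter: the drop at the
barcode filter is the decoy (non-monocyte) reads the generator plants to
make that filter consequential. The host genes are expressed in controls
too, so they never pass the pangenome filter; HERV001–003 are positive in
every PASC sample, and the significant rows show their amplification —
about 25 usable windows in PASC (`mean_a`) versus about 15 in acute
samples (`mean_b`). `wha_report(run)` writes the presence matrix and a
heatmap-ready long table; a thin command-line front end over the same
functions is in `inst/cli/wha.R`.

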