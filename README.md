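# ploidyscreen

Expression-dosage screening for whole-chromosome aneuploidy in
mixed-ploidy bulk RNA-seq designs, plus a variance-weighted
principal-component distance ("transcriptomic shift") between matched
diploid/triploid samples.

## Who this is for

Triploid oysters (and other farmed polyploids) are prone to
whole-chromosome losses and gains during their error-prone cell
divisions, a suspected contributor to episodic triploid mortality. If
paired diploid and triploid animals from the same site, hatchery cohort,
and dam have been RNA-sequenced, their transcriptomes can be screened for
aneuploidy without karyotyping: after counts-per-million (CPM)
normalization the whole-genome 3:2 dosage of triploidy cancels exactly,
so any *chromosome-restricted* shift in transcript output is a
copy-number signal.

## The statistics

For each matched pair and each chromosome *k*, over that chromosome's
genes (log2 CPM, diploid = x, triploid = y):

- **slope** — OLS fit of y on x with intercept, the conventionally
  tabulated quantity. A uniform dosage change moves the *intercept* of
  this fit, not the slope, so the slope is reported for comparability but
  not used for calls.
- **median log-ratio** — `m_k = median(y - x)`, re-centered at the
  cross-chromosome median (the within-pair baseline). For a chromosome at
  copy number *c* in a triploid the expected deviation is `log2(c/3)`
  (−0.585 for a 2-of-3 loss), independent of the chromosome's expression
  share.
- **robust z** — `(m_k − median(m)) / (1.4826 · MAD(m))`. A chromosome is
  flagged when `|z| ≥ 3` and the deviation is at least `log2(1.15)`; a
  pair with zero flags is called euploid.

A gene-centered PCA of the same matrix gives per-sample scores; the
transcriptomic shift of a pair is the Euclidean distance between its two
samples after multiplying each PC coordinate by that component's variance
fraction (PC1 and PC2 by default).

A negative-binomial simulator (`simulate_dataset()`) reproduces the
two-site × two-cohort × three-dam crossing design with planted
copy-number events and returns the true karyotype, so the whole pipeline
is testable end to end; `power_analysis()` estimates the screen's
sensitivity and false-positive rate by simulation.

## Worked example

Simulate the study layout at reduced depth (2 animals per ploidy per
cross), plant a single monosomy (chromosome 6 at copy 2) in one triploid,
and screen:

```r
library(ploidyscreen)

cfg <- simulation_config(
  n_genes = 5000,
  design = default_design(n_per_ploidy = 2),
  dispersion = Inf, lib_size_cv = 0,
  aneuploidy_events = data.frame(
    sample_id = "LUMCON_LSU_VB_3n_01", chromosome_id = "chr6",
    copy_number = 2L),
  seed = 42)
sim   <- simulate_dataset(cfg)
lc    <- log_cpm(filter_low_expression(sim$counts))
pairs <- match_pairs(sim$samples)        # 24 pairs, matched on site+cohort+dam
screen <- screen_all_pairs(lc, sim$genemap, pairs)
subset(screen, flagged)
#>     pair_id chromosome_id n_genes slope intercept slope_se median_log_ratio robust_z flagged
#> 227 pair023          chr6     455 0.985    -0.431  0.00835           -0.524    -40.5    TRUE
```

Exactly one of the 240 pair × chromosome records is flagged — the planted
monosomy (`median_log_ratio` −0.52, near the theoretical log2(2/3) =
−0.585), found in pair023 = `LUMCON_LSU_VB_2n_01` vs
`LUMCON_LSU_VB_3n_01`. Its slope (0.985) is indistinguishable from the
other chromosomes': dosage lives in the ratio, not the slope. The other
23 pairs are called euploid.

The same pair tops the transcriptomic shift ranking, since a
chromosome-wide dosage change is also a large global perturbation:

```r
pc <- expression_pca(lc, 2)
sh <- transcriptomic_shift(pc, pairs)    # weights = PC variance fractions
head(sh[order(-sh$distance), c("pair_id", "site", "cohort", "dam", "distance")], 3)
#>    pair_id      site cohort dam distance
#> 23 pair023    LUMCON    LSU  VB    0.647
#> 7  pair007 GrandIsle    LSU  CL    0.173
#> 5  pair005 GrandIsle     AU  VB    0.137
```

`run_pipeline()` chains simulate/read → filter → normalize → pair →
screen → shift, writing TSV outputs and a checksummed JSON manifest;
`exec/ploidyscreen` exposes the same stages as shell subcommands
(`simulate`, `filter`, `normalize`, `pairs`, `aneuploidy`, `shift`,
`power`, `run`).

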