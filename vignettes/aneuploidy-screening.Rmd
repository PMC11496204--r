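---
title: "Expression-dosage screening for aneuploidy in mixed-ploidy RNA-seq designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-dosage screening for aneuploidy in mixed-ploidy RNA-seq designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyscreen)
```

## The problem

Triploid oysters are widely farmed because they grow fast, but they suffer
episodic summer mortality, and one suspected contributor is aneuploidy:
polyploid cell division is error-prone, and losing (or gaining) a whole
chromosome disrupts expression genome-wide. Karyotyping field samples is
expensive; bulk RNA-seq of the same animals is often already in hand. This
package implements an expression-based screen that asks, for each
covariate-matched diploid/triploid pair of animals, whether any single
chromosome's transcript output deviates from the dosage expected under a
euploid karyotype — together with a complementary whole-transcriptome
distance ("transcriptomic shift") that quantifies how far a triploid's
global expression state sits from its matched diploid.

## The dosage logic

Let $x_{g}$ and $y_{g}$ be the $\log_2$ counts-per-million (CPM) of gene
$g$ in the diploid and triploid member of a pair. CPM normalization
rescales every library to $10^6$, so a *uniform* dosage change — the
whole-genome 3:2 ratio that defines triploidy — cancels exactly: after
normalization a perfectly euploid triploid is indistinguishable from its
diploid partner, chromosome by chromosome. Only a *chromosome-restricted*
copy-number change survives normalization. If a triploid carries
chromosome $k$ at copy number $c$ while the rest of the genome is at 3,
and chromosome $k$ contributes a fraction $f$ of per-copy expression, the
expected CPM ratio (3n/2n) is

$$
\frac{c}{3 - (3-c)f} \;\text{ (on chromosome } k\text{)}, \qquad
\frac{3}{3 - (3-c)f} \;\text{ (elsewhere)};
\quad\text{for } c = 2:\; \frac{2}{3-f} \text{ and } \frac{3}{3-f},
$$

so the difference of the two, on the $\log_2$ scale, is $\log_2(c/3)$ —
independent of $f$. This is the quantity the screen estimates: the
per-chromosome **median log-ratio** $m_k = \mathrm{median}_{g \in k}(y_g -
x_g)$, re-centered at the cross-chromosome median (the within-pair
baseline, which absorbs any residual global offset), is compared against
$\log_2(c/3)$: $-0.585$ for a 2-of-3 loss, $+0.415$ for a 4-of-3 gain.

Two statistics are reported per pair and chromosome:

* the **OLS slope** (with intercept) of $y$ on $x$ over the chromosome's
  genes, the quantity conventionally tabulated in such screens. Note that
  a uniform dosage shift adds a constant to $y$ and therefore moves the
  *intercept*, not the slope, of an intercept-including fit — the slope is
  reported for comparability, but it is the wrong axis to detect pure
  dosage on;
* the **robust z** of the median log-ratio:
  $z_k = (m_k - \tilde m) / (1.4826 \cdot \mathrm{MAD})$, with $\tilde m$
  the median of the $m_k$ and the MAD taken across chromosomes. A
  chromosome is flagged when $|z_k| \ge 3$ **and** $|m_k - \tilde m| \ge
  \log_2(1.15)$. Flags are therefore based on the statistic that the
  dosage logic actually predicts, not on the slope.

The effect floor matters: with only ten chromosomes the MAD is itself
noisy, and in a quiet pair it can be tiny; requiring at least a 15%
dosage-equivalent deviation prevents flagging measurement noise. The
conventional $|z| \ge 3$ cutoff controls the rate in the opposite regime.
A pair is called euploid when no chromosome is flagged. The baseline
median needs a majority of chromosomes to be trustworthy, so calls
require at least 5 chromosomes with defined statistics; a chromosome with
fewer than `min_genes = 20` usable genes (or a degenerate regressor)
yields an explicit undefined record rather than a silent omission.

## Normalization and filtering

Counts are CPM-normalized and $\log_2(\mathrm{CPM}+1)$-transformed. The
pseudocount of 1 keeps zero counts at exactly 0 on the log scale. Before
any analysis, genes are filtered with the keep-if-expressed rule: a gene
is retained iff its CPM is at least 5 in at least 80% of samples
(boundary inclusive on both margins; the phrasing "fewer than five CPM in
80% of samples" is ambiguous between remove-if-low and keep-if-high
readings, and this package adopts and documents keep-if-high). Filtering
is applied before the screen by default — the same gene set then underlies
every pair, keeping statistics comparable across pairs — and the filter is
exposed separately for users who prefer otherwise. Log-CPM is used both
for the screen and for the PCA; a variance-stabilizing transformation
from a fitted dispersion model is a deliberate non-goal, and the small
discrepancy this introduces for the PCA is accepted and documented here.

## Pairing

Pairs are matched exactly on site, cohort (hatchery of origin), and dam
(maternal broodstock). Within each (site, cohort, dam) cell, diploids and
triploids are paired one-to-one up to `min(n_2n, n_3n)`; the default
`ordered` strategy pairs lexicographically by sample id, which makes runs
deterministic, and a seeded `random` strategy supports sensitivity
analysis of the within-cell assignment (which is not identifiable from
the design). Exhaustive one-to-one pairing maximizes usable pairs.
Unmatched samples are reported, and a cell missing one ploidy warns
rather than errors, so partial designs degrade gracefully.

## The transcriptomic shift

Samples are projected by gene-centered PCA (singular value decomposition
of the filtered log-CPM matrix, samples as observations). For each
matched pair the shift is

$$ d = \sqrt{\textstyle\sum_{i \le k} \big(w_i\,(s_i^{3n} -
s_i^{2n})\big)^2}, \qquad w_i = \text{variance fraction of PC}_i, $$

with $k = 2$ (PC1 and PC2) by default. "Weighting by the percent of
variation explained" admits two arithmetic readings — multiplying the
coordinates (used here as the default) or weighting the squared terms
(equivalent to `weighting = "sqrt"`); both are implemented, `"none"`
gives the plain Euclidean distance, and the choice is recorded in the
output's metadata. Each component's loading vector is oriented so its
largest-magnitude entry is positive, which fixes the SVD sign
indeterminacy; distances are unaffected either way. Distances are
summarized per site x cohort by median and interquartile range, the
grouping in which site-dependent ploidy stress shows up.

## The simulator

`simulate_dataset()` draws counts from a negative binomial whose mean is
library size times renormalized relative expression
$c_{k(g),s}^{\gamma}\, e_g\, m_{gs}$: copy-number dosage (exponent
$\gamma = 1$, fully proportional by default, with $\gamma$ exposed so
partial dosage compensation can be probed), a log-normal gene baseline,
and multiplicative covariate effects shared within each site, cohort and
ploidy level. The renormalization makes whole-genome ploidy cancel in the
simulation for the same reason it cancels in the data. Defaults emulate
the motivating study's layout: 10 chromosomes, a 2-site x 2-cohort x
3-dam crossing design with 8 individuals per ploidy per cell (192
samples, 96 pairs), and per-sample chromosome copy-number events planted
through an explicit event table whose ground truth is returned alongside
the counts.

Parameter defaults, chosen once as typical of bulk RNA-seq and kept fixed:

| parameter | default | meaning |
|---|---|---|
| `baseline_log_mean`, `baseline_log_sd` | 3, 1.5 | natural-log gene baseline; expression spans ~4 orders of magnitude |
| `dispersion` | 10 | NB size (larger = less overdispersed; `Inf` = Poisson) |
| `lib_size_mean`, `lib_size_cv` | 1e6, 0.2 | log-normal library sizes |
| `covariate_effect_sd` | 0 (off) | log-scale sd of site/cohort/ploidy effects |
| `frac_affected_genes` | 0.1 | genes carrying covariate effects |
| `ploidy_site_interaction_sd` | 0 (off) | extra triploid effect at one site |

Genes are apportioned to chromosomes deterministically
(largest-remainder on `chromosome_weights`), so a test can fix a
chromosome's expression share exactly. The `ploidy_site_interaction_sd`
knob gives triploids at one site an extra gene-wise effect; it exists so
the qualitative site ordering of the shift metric is reproducible in
simulation. What the simulator does **not** emulate: gene-length and GC
effects, correlated co-expression modules, isoform structure,
within-chromosome positional effects, batch effects, and mosaic (partial
or subclonal) aneuploidy. Tests passing on simulated data therefore
demonstrate the statistical machinery under the stated generative model,
not robustness to these real-data features.

## Numerical choices and edge cases

* OLS is computed in closed form (slope $= S_{xy}/S_{xx}$, textbook
  standard error); tests cross-check it against `lm()` and an
  independent numeric least-squares minimizer.
* `robust_z` with a zero MAD: if all deviations are zero the z is defined
  as 0 (degenerate equality, no flags); a zero MAD with nonzero
  deviations falls back to the effect floor alone, with a warning.
* Dosage statistics are exactly invariant to integer rescaling of either
  library, and the robust z is invariant to adding a constant to every
  log-CPM value of one sample.
* All randomness flows from explicit integer seeds (simulation config,
  random pairing, pipeline); reruns are byte-identical, and the pipeline
  manifest records parameters and MD5 checksums but no timestamps so it
  too reproduces exactly.
* Chromosome identifiers are opaque strings throughout; no "chr" prefix
  or ordering is assumed.

## Validation problem sizes

The shipped validation suite simulates at desk scale, chosen to keep the
Monte Carlo error well below the margins being asserted: 200 euploid
pairs of 5,000 genes (10 chromosomes x 500 genes, fixed $10^6$ libraries,
Poisson limit) for the null behaviour — across those pairs all 2,000
slopes fall within [0.95, 1.05] and no chromosome is flagged; 200
replicate pairs for the planted 2-of-3 monosomy operating point
(sensitivity 1.0, false-positive rate 0 at the default thresholds); and
10 replicates for the $\log_2(2/3)$ effect-size recovery (within 0.05
log2 units). The observed slight downward bias of euploid slopes
(~0.96-0.99 rather than exactly 1) is classical regression attenuation
from per-gene count noise in the diploid coordinate; it shrinks as
library size grows and is another reason calls are not based on slopes.

## Limitations

The screen detects whole-chromosome events large enough to shift the
chromosome-wide median; segmental events, low-fraction mosaicism, and
dosage-compensated chromosomes ($\gamma$ well below 1, effect below the
15% floor) are out of reach by design. With ten chromosomes the MAD
baseline tolerates at most a few simultaneous aneuploidies per pair
before the baseline itself moves. The shift metric inherits PCA's
sensitivity to whatever dominates global variance; it measures divergence
along the leading axes, not any specific biological pathway.
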