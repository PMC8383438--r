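---
title: "Models and methods behind atacdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atacdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atacdiff` packages the statistical pipeline of a sorted-nuclei ATAC-seq
case-control study: quality filtering, TMM normalization, iterative
covariate selection against count principal components, negative-binomial
quasi-likelihood differential testing, genomic annotation, and permutation
enrichment of differential sites in GWAS tag-SNP windows. This vignette is
the package's own account of the modelling choices — what is assumed, which
knobs matter, and where the design was genuinely open.

## The count model

Accessibility counts are treated as negative binomial:
$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_i)$ with
$\log \mu_{ij} = \log(N_j f_j) + x_j^\top \beta_i$, where $N_j$ is the
library size and $f_j$ the TMM factor; the product is used as a GLM offset.
The NB assumption captures the donor-to-donor biological variation that a
Poisson model would understate; $\sqrt{\phi}$ is the biological coefficient
of variation, and values around 0.2 are typical of human cohort ATAC-seq —
the generator's default.

Fitting is Fisher-scoring IRLS, vectorized across peaks against the shared
design matrix (the per-iteration normal equations are assembled with two
matrix products and solved in closed form for up to three coefficients,
peak-by-peak Cholesky otherwise). Convergence is declared at a relative
deviance change below `1e-8` or 50 iterations; non-converging peaks are
flagged and reported with p = 1 rather than aborting a run.

### Dispersion estimation

* **Common**: maximizes the Cox–Reid adjusted profile likelihood (sum of
  per-peak NB log-likelihoods minus half the log-determinant of the Fisher
  information) over a 25-point log-spaced grid on $[10^{-4}, 4]$, refined
  by quadratic interpolation around the grid maximum.
* **Trended**: per-peak adjusted profile likelihoods are averaged in a
  moving window (10% of peaks) along mean log-CPM; the trend value is the
  per-peak maximizer of the smoothed likelihood.
* **Tagwise**: maximizer of the per-peak likelihood plus
  `prior_df / df_residual` times the trend likelihood. `prior_df = 10` by
  default — enough shrinkage to stabilize 10-to-20-sample comparisons
  without erasing genuine heterogeneity; `prior_df = Inf` returns the
  trend exactly.

Testing uses trended dispersions in the GLM fits. The quasi-likelihood
F-test then absorbs residual over/under-dispersion: per-peak quasi-dispersions
(deviance over residual df) are squeezed toward their common value by
empirical Bayes (limma's `squeezeVar`), and
$F = (\Delta\mathrm{deviance}/\Delta\mathrm{df}) / s^2_{post}$ is referred
to $F_{\Delta df,\; df_{prior} + df_{res}}$. This scheme is compatible
with, but not numerically identical to, the established count-model
frameworks; calibration is demonstrated by simulation instead (global-null
type-I fraction 0.03–0.07 at nominal 0.05 over 20 seeds of 2,000 peaks,
10 vs 10, dispersion 0.2 — the sizes used in the test suite and acceptance
script, chosen so the whole calibration study runs in about a minute).

### Multiplicity and direction

Adjusted p-values are Benjamini–Hochberg (`stats::p.adjust`); "adjusted p"
and "FDR q" are used interchangeably. Direction labels follow the
case-vs-control log2 fold change: positive means more accessible in cases.
Peaks with total count below 10 across the comparison's samples are
removed before testing — the abundance filter is our declared choice, not
inherited from the study, and is configurable.

## Normalization

TMM factors are computed by the standard edgeR implementation behind the
`tmm_factors()` surface, with the original method's trim fractions (30% on
log-ratios, 5% on absolute intensity), automatic reference selection by
upper-quartile proximity to the mean, and rescaling to geometric mean 1.
The test suite checks the factors against an independent brute-force
evaluation of the trimmed inverse-variance-weighted mean formula.
`cpm_log()` (log2 counts per million on effective library sizes, prior
count 0.5) is the input surface for PCA-based stages.

## Quality control

* **Complexity metrics**: NRF = distinct/total read positions;
  PBC1 = single-read positions over distinct positions; PBC2 = single-read
  over two-read positions (`Inf` when nothing is seen twice). These are
  computed from position multisets; alignment-derived metrics are accepted
  as inputs.
* **Sample filter**: "normalized peak calls" is interpreted as peak calls
  at FDR q < 0.01 per million uniquely mapped reads, thresholded at 100.
  Where a donor/fraction has replicate datasets, the one with the higher
  normalized peak calls is kept — the only quantitative proxy for
  "signal-to-noise" the QC table supports; both the unit and the proxy are
  documented choices.
* **Outlier removal**: PCA scores (top 10 PCs) are clustered with classic
  Ward linkage on squared Euclidean distances (the `ward.D`-on-squared-
  distances variant; two Ward variants exist, so the choice is recorded).
  Any cluster below 5% of samples (minimum 1) is flagged. The 5% rule
  generalizes the one-outlier-in-90 removal it emulates.

## Covariate selection

Candidates are regressed against the first 10 PCs of the (normalized,
log-scale) peak matrix; categorical candidates use one-way ANOVA.
"Bonferroni significant" is implemented as
$p < \alpha / (n_{cand} \times n_{PC})$ with $\alpha = 0.05$ — the stricter
family-wise reading, since the procedure names Bonferroni explicitly.
Among significant candidates the pick is: technical (assay-related)
variables first; then the largest variance-weighted evidence score
$\sum_{PC} -\log_{10} p \times \mathrm{varshare}$ — our concrete rendering
of "explaining one of the largest proportions of variance"; then fewer
parameters; then name. The formula is documented and swappable.

Each iteration regresses the selected variable out of the **residual**
matrix and recomputes the PCA ("independent of the selected variables"
reads as cumulative residualization; refitting from raw each round is the
alternative we did not take). Selected variables leave the candidate pool,
so the loop terminates in at most `n_candidates` iterations. Missing
covariate values are imputed by median (continuous) or mode (categorical)
with per-cell flags — a deliberately simple, documented replacement for
chained-equation imputation.

PCA uses centering only, no unit-variance scaling: log-CPM values share a
scale, and rescaling would inflate low-variance peaks. Sort dates are
unordered factors.

## GWAS windows and permutation enrichment

Windows are tag-SNP position ±100 kb on the printed coordinate scale,
clamped at zero; no 0/1-based correction is applied to window arithmetic
(every printed window in the bundled examples reproduces exactly as
pos ± 100,000), while BED export converts to 0-based half-open with the
shift documented. A differential site counts if it intersects a window by
at least 1 bp; full containment and a minimum-overlap threshold are
options (on the published examples the readings agree — every listed peak
lies fully inside its window).

The permutation null draws the same number of sites uniformly **without
replacement** from the comparison's peak universe (sites are distinct
peaks), 10,000 times by default, and reports the add-one empirical
p-value $(1 + \#\{perm \ge obs\}) / (1 + n_{perm})$, which can never be
zero. Draws are not matched on width or GC; matched sampling is a
possible extension, not the stated procedure. The test suite checks the
machinery against a 4-peak universe whose null is exhaustively enumerable.

## The synthetic cohort

The generator emulates the study's statistical structure, not its
sequences:

* **Design**: 40 donors with paired neuronal/non-neuronal samples
  (controls 11 F / 10 M; cases 11 F / 8 M, matching the sex-stratified
  comparison sizes) plus 9 unpaired female non-neuronal samples (3
  control, 6 mild). The printed cohort tables are internally inconsistent
  about the male case count and the supplemented female comparison size;
  presets record the printed nominal sizes and warn (not error) when
  realized sizes differ.
* **Counts**: NB with log-linear effects; per-peak baselines uniform on
  [-2.5, 2.5] (natural log), dispersion `phi0 + decay/mean` with
  `phi0 = 0.2` default; column sums target log-normal library sizes
  (default 1e5 for desk-scale runs; deep cohorts would use 2e7, and the
  parameter is a config field, not a constant).
* **Effect structure**: cell-type effects on 15% of peaks (|log2FC| 1–3);
  disease effects on 2% of peaks in neuronal samples of both sexes and 4%
  in non-neuronal samples — full strength in females, attenuated by 0.3 in
  males, implemented as an interaction switch so male glia carry the same
  directional trends below detection at cohort size. Disease magnitudes
  (|log2FC| in [0.5, 2]) are a choice, not an inference: the study does
  not report accessibility effect sizes.
* **Confounding**: one latent factor per sample feeds both the technical
  covariates (loading × latent + noise, then scaled to realistic units:
  NRF ≈ 0.82, alignment ≈ 95%, ≈ 3×10⁵ nuclei, GC ≈ 45%, ≈ 400 normalized
  peak calls, 5 sort-date batches) and a random 20% of peaks, so
  covariates genuinely associate with count PCs and the selection loop has
  something real to find.
* **Demographics**: neuronal-fraction percentages by diagnosis group
  (means 35.27 / 38.59 / 19.16, SDs 13.26 / 14.70 / 7.49, truncated to
  [0, 100]), group-specific age and PMI, two donors with missing PMI.
* **Peaks**: widths log-normal (median 500 bp, σ = 0.5 on the log scale,
  truncated to [100, 5000] bp — typical ATAC peak widths), placed
  disjointly with peak counts proportional to chromosome length, sex
  chromosomes included so the exclusion logic is exercised.
* **Reproducibility**: one seed; each component draws from its own child
  stream, so regenerating one artifact does not perturb the others.

What it does **not** emulate: read-level data (positions are abstract
integers; no fragment-size or Tn5-insertion structure), GC- or
mappability-dependent bias, correlated peaks (peaks are independent given
the latent factor), LD structure among GWAS loci, or peak-calling noise.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the stated generative model — not that the
pipeline is robust to artifacts the generator does not produce.

## Numerical and degenerate-input choices

* Dispersion grid $[10^{-4}, 4]$, 25 points, quadratic refinement;
  estimates floored at $10^{-6}$.
* IRLS linear predictors capped at 50 to prevent overflow; all-zero peak
  rows are excluded from dispersion estimation with a message.
* Separated or non-converging GLM rows are flagged, p set to 1.
* Ties in outlier clustering resolve deterministically through hclust's
  ordering; flagged ids are returned sorted.
* Constant covariates associate with p = 1 (warned, not an error);
  single-sample factor levels regress to zero residuals by construction
  (warned).
* Empty keep-sets after QC are warned, not fatal; an empty peak table
  after filtering is an error naming the stage.

## Known limitations

* No exact numerical parity with any existing NB-QLF implementation is
  claimed; agreement is demonstrated statistically (calibration, power,
  dispersion recovery against the generating values) and against
  independent brute-force oracles on small instances.
* The covariate-selection ranking formula is one reasonable rendering of a
  qualitative preference; different renderings can change the selection
  order when candidates are nearly tied.
* Surrogate-variable or latent-factor adjustment beyond the explicit
  iterative procedure is out of scope, as are LD-aware GWAS windows,
  chromatin-QTL colocalization, and TAD overlap.
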