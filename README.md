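# atacdiff

Differential chromatin accessibility analysis for sorted-nuclei ATAC-seq
cohorts.

`atacdiff` implements the full analysis ladder used in case-control studies
of brain chromatin accessibility with fluorescence-activated nuclei sorting
(FANS): neuronal (NeuN+) and non-neuronal (NeuN−) nuclei fractions from the
same donors, compared between disease cases (here, late-onset Alzheimer's
disease) and controls, overall and stratified by sex. It is aimed at
epigenomics analysts who have peak-by-sample read-count matrices and
per-sample metadata and want a reproducible, testable route from raw counts
to differential sites and GWAS-locus enrichment — plus a synthetic-data
generator that makes every stage testable without restricted human data.

## The model

Counts `y_ij` for peak *i* in sample *j* are modelled as negative binomial,

```
y_ij ~ NB(mu_ij, phi_i),    log mu_ij = log(N_j * f_j) + x_j' beta_i
```

with `N_j` the library size, `f_j` a TMM (weighted trimmed mean of
M-values) normalization factor, and `x_j` the group indicator plus
covariates. Dispersion `phi_i` is estimated by Cox–Reid adjusted profile
likelihood (common), smoothed along abundance (trended) and shrunk
empirically toward the trend (tagwise). Case-control contrasts use a
quasi-likelihood F-test on empirical-Bayes-moderated quasi-dispersions and
BH false discovery control; chrX/chrY peaks are excluded.

Covariates are chosen by the study's iterative procedure: regress every
candidate against the first 10 principal components of the log-CPM matrix,
select the strongest Bonferroni-significant candidate (technical variables
preferred), remove its effect from the matrix, recompute the PCA, and
repeat until nothing is significant.

Differential sites are annotated by genomic feature (promoter, first exon,
5'/3' UTR, intragenic, intergenic) and tested for enrichment in ±100 kb
windows around GWAS tag SNPs with a 10,000-draw permutation test over the
peak universe (add-one empirical p-value).

## Worked example

```r
library(atacdiff)

cfg   <- sim_config(n_peaks = 2000, seed = 42)   # 89-sample paired cohort
peaks <- simulate_peak_universe(cfg)
meta  <- simulate_metadata(cfg)
sim   <- simulate_counts(cfg, peaks, meta)

# female non-neuronal case-control comparison (11 vs 11)
res <- run_contrast(sim$counts, meta, "L3A")
glance(res)
#>   label contrast fraction     sex   n_peaks n_significant n_more_accessible
#> 1 L3A   disease  non_neuronal F        1646            34                17
#>   n_less_accessible dispersion_common df_prior
#>                 17             0.207    6909.

tidy(res)[1:3, c("peak_id", "log2FC", "p", "q", "direction")]
#>   peak_id                  log2FC        p             q direction
#> 1 chr1:89984305-89984959     2.22 7.48e-13 0.00000000123 more_accessible_in_case
#> 2 chr3:88217420-88217796    -3.05 7.17e-12 0.00000000590 less_accessible_in_case
#> 3 chr2:237227436-237228210   2.14 5.90e-11 0.0000000324  more_accessible_in_case
```

The generator planted disease effects on 4% of peaks in female non-neuronal
samples; the contrast recovers 34 of them at q < 0.05 (17 more and 17 less
accessible in cases), at a common dispersion of 0.21 — the biological
coefficient of variation of the simulated cohort. The same counts run under
the male preset (`"L3B"`) yield essentially no discoveries, reproducing the
female-specific structure.

The bundled worked example from the published study reproduces its overlap
table directly:

```r
ex  <- load_gwas_examples()
win <- build_gwas_windows(ex$snps, flank = 1e5)
overlap_regions(ex$peaks[ex$peaks$panel == "female_glia", ], win)
#> 9 site(s) overlapping 7 GWAS region(s)
```

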