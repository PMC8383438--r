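# Shared fixtures, all built in code at test time.

# a small flat (no-donor-structure) two-group cohort, one sample per donor
flat_design <- function(n_per_group = 10, fraction = "neuronal", sex = "F") {
  n <- 2 * n_per_group
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    donor_id = sprintf("P%02d", seq_len(n)),
    cell_fraction = fraction,
    diagnosis = rep(c("control", "mild_LOAD"), each = n_per_group),
    sex = sex
  )
}

# an effects-free, confounder-free generator configuration
null_sim_config <- function(n_peaks = 500, design = flat_design(), seed = 1,
                            phi0 = 0.2, ...) {
  sim_config(
    n_peaks = n_peaks, design = design,
    dispersion_model = list(phi0 = phi0, decay = 0),
    n_cell_type_peaks = 0, n_disease_neuronal_peaks = 0,
    n_disease_glial_female_peaks = 0,
    confounders = default_confounders(loading = 0),
    confounder_peak_fraction = 0,
    seed = seed, ...
  )
}

# design spec for a flat cohort (no paired donors to restrict to)
flat_spec <- function(...) {
  design_spec("disease", include_unpaired = TRUE, ...)
}

# brute-force membership oracle: which of `sets` cover each basepair of a
# chromosome; used against interval-arithmetic routines
bitmap_union <- function(sets, chrom_len = 10000) {
  mask <- rep(FALSE, chrom_len)
  for (s in sets) {
    for (i in seq_len(nrow(s))) {
      mask[(s$start[i] + 1):s$end[i]] <- TRUE
    }
  }
  mask
}

# independent TMM evaluation: direct trimmed weighted-mean formula
tmm_oracle <- function(y, trim_m = 0.3, trim_a = 0.05) {
  uq <- apply(sweep(y, 2, colSums(y), "/"), 2, quantile, 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(smp) {
    Nr <- sum(y[, ref]); Nk <- sum(y[, smp])
    keep <- y[, ref] > 0 & y[, smp] > 0
    yr <- y[keep, ref]; yk <- y[keep, smp]
    M <- log2((yk / Nk) / (yr / Nr))
    A <- 0.5 * log2((yk / Nk) * (yr / Nr))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    v <- (Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }
  f <- vapply(seq_len(ncol(y)), one, numeric(1))
  f / exp(mean(log(f)))
}

random_intervals <- function(n, chrom = "chr1", max_pos = 9000, seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(200, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}
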