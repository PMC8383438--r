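test_that("peak universe is disjoint, seeded, and respects the empty case", {
  expect_equal(nrow(simulate_peak_universe(null_sim_config(n_peaks = 0))), 0)

  cfg <- null_sim_config(n_peaks = 1000, seed = 42)
  pk1 <- simulate_peak_universe(cfg)
  pk2 <- simulate_peak_universe(cfg)
  expect_equal(nrow(pk1), 1000)
  expect_identical(pk1, pk2)

  # disjointness via pairwise check within chromosomes
  by_chr <- split(pk1, pk1$chrom)
  for (ch in by_chr) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1) {
      expect_true(all(ch$end[-nrow(ch)] <= ch$start[-1]))
    }
  }
  expect_equal(nrow(merge_peak_sets(pk1)), 1000)
  # universe exercises the sex chromosomes
  expect_true(any(pk1$chrom %in% c("chrX", "chrY")))
  # all peaks inside their chromosome
  expect_true(all(pk1$end <= cfg$chrom_sizes[pk1$chrom]))
})

test_that("insufficient chromosome capacity names the chromosome", {
  cfg <- null_sim_config(
    n_peaks = 2000,
    chrom_sizes = c(chr1 = 5e4, chrX = 5e4, chrY = 5e4)
  )
  expect_error(simulate_peak_universe(cfg), "chromosome chr")
})

test_that("metadata encodes the cohort design and confounder structure", {
  cfg <- null_sim_config(design = cohort_design(), seed = 2)
  md <- simulate_metadata(cfg)
  expect_equal(nrow(md), 89)
  expect_equal(sum(md$cell_fraction == "neuronal"), 40)
  # missing PMI planted for the configured number of donors
  expect_equal(length(unique(md$donor_id[is.na(md$pmi)])), 2)
  expect_true(all(md$neuronal_fraction_pct >= 0 & md$neuronal_fraction_pct <= 100))

  # duplicate (donor, fraction) rejected
  bad <- cfg
  bad$design <- rbind(cfg$design, cfg$design[1, ])
  expect_error(simulate_metadata(bad), "duplicate")
})

test_that("confounder loading controls covariate-latent coupling", {
  des <- flat_design(20)
  # loading 1, noise 0: exactly collinear with the latent factor
  conf <- default_confounders(loading = 1)
  conf$noise_sd <- 0
  cfg <- sim_config(n_peaks = 10, design = des, confounders = conf, seed = 5)
  md <- simulate_metadata(cfg)
  expect_equal(cor(md$nrf, md$latent), 1, tolerance = 1e-12)

  # zero loading: no correlation beyond the null band
  cfg0 <- sim_config(n_peaks = 10, design = des,
                     confounders = default_confounders(loading = 0), seed = 5)
  md0 <- simulate_metadata(cfg0)
  expect_lt(abs(cor(md0$nrf, md0$latent)), 2.5 / sqrt(nrow(md0)))
})

test_that("neuronal fraction group means match the cohort table at large n", {
  # many donors per diagnosis group; 2 SEM band around 35.27/38.59/19.16
  des <- tibble::tibble(
    donor_id = sprintf("D%03d", 1:600),
    diagnosis = rep(c("control", "mild_LOAD", "severe_LOAD"), each = 200),
    sex = "F", cell_fraction = "non_neuronal",
    sample_id = sprintf("S%03d", 1:600)
  )
  cfg <- null_sim_config(n_peaks = 10, design = des, seed = 9)
  md <- simulate_metadata(cfg)
  means <- tapply(md$neuronal_fraction_pct, md$diagnosis, mean)
  # truncation at 0/100 barely moves these means; allow 2 SEM + 0.5
  for (g in c("control", "mild_LOAD", "severe_LOAD")) {
    target <- c(control = 35.27, mild_LOAD = 38.59, severe_LOAD = 19.16)[g]
    sem <- c(control = 13.26, mild_LOAD = 14.70, severe_LOAD = 7.49)[g] /
      sqrt(200)
    expect_lt(abs(means[[g]] - target), 2 * sem + 0.5)
  }
})

test_that("counts are reproducible, non-negative, and recover planted logFC", {
  des <- flat_design(40)
  pkc <- sim_config(n_peaks = 60, design = des,
                    dispersion_model = list(phi0 = 0.05, decay = 0),
                    n_cell_type_peaks = 0, n_disease_neuronal_peaks = 0,
                    n_disease_glial_female_peaks = 0,
                    confounders = default_confounders(loading = 0),
                    confounder_peak_fraction = 0, seed = 11)
  pk <- simulate_peak_universe(pkc)
  md <- simulate_metadata(pkc)
  eff <- list(
    cell_type = tibble::tibble(peak_id = character(), lfc = numeric()),
    disease_neuronal = tibble::tibble(peak_id = pk$peak_id[7], lfc = 2),
    disease_glial_female = tibble::tibble(peak_id = character(),
                                          lfc = numeric())
  )
  s1 <- simulate_counts(pkc, pk, md, effects = eff)
  s2 <- simulate_counts(pkc, pk, md, effects = eff)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0))

  # direct mean-ratio oracle on the planted peak (depth-normalized)
  rate <- s1$counts[7, ] / colSums(s1$counts)
  case <- md$diagnosis != "control"
  lfc_hat <- log2(mean(rate[case]) / mean(rate[!case]))
  expect_equal(lfc_hat, 2, tolerance = 0.35)

  # unknown peak id in the effect table is an error
  eff$disease_neuronal$peak_id <- "chrZ:1-2"
  expect_error(simulate_counts(pkc, pk, md, effects = eff), "unknown peak")
})

test_that("null generator has equal group means and NB moments hold", {
  # 200 identical-condition samples: variance tracks mu + phi mu^2
  des <- flat_design(100)
  cfg <- null_sim_config(n_peaks = 80, design = des, seed = 13, phi0 = 0.3,
                         library_size = list(meanlog = log(1e5), cv = 0))
  pk <- simulate_peak_universe(cfg)
  md <- simulate_metadata(cfg)
  sim <- simulate_counts(cfg, pk, md)
  y <- sim$counts
  case <- md$diagnosis != "control"
  # null generator: per-peak group means agree within sampling error
  ratio <- log2(rowMeans(y[, case]) + 1) - log2(rowMeans(y[, !case]) + 1)
  expect_lt(median(abs(ratio)), 0.25)
  # NB moment check against the closed form, aggregated over peaks
  mu_hat <- rowMeans(y)
  v_hat <- apply(y, 1, var)
  keep <- mu_hat > 5
  phi_hat <- median((v_hat[keep] - mu_hat[keep]) / mu_hat[keep]^2)
  expect_equal(phi_hat, 0.3, tolerance = 0.1)
})

test_that("library sizes follow the configured distribution", {
  cfg <- null_sim_config(n_peaks = 200, design = flat_design(30), seed = 17,
                         library_size = list(meanlog = log(1e5), cv = 0.3))
  pk <- simulate_peak_universe(cfg)
  md <- simulate_metadata(cfg)
  sim <- simulate_counts(cfg, pk, md)
  cs <- colSums(sim$counts)
  # column sums within 3 SD of the configured log-normal
  sdlog <- sqrt(log(1 + 0.3^2))
  expect_true(all(abs(log(cs) - log(1e5)) < 3.5 * sdlog))
})

test_that("covariate/PC1 coupling is monotone in the confounder loading", {
  cors <- vapply(c(0.2, 0.5, 1.0), function(l) {
    conf <- default_confounders(loading = l)
    conf$noise_sd <- 0.3
    cfg <- sim_config(n_peaks = 300, design = flat_design(25),
                      confounders = conf, confounder_peak_fraction = 0.5,
                      confounder_peak_sd = 0.6,
                      n_cell_type_peaks = 0, n_disease_neuronal_peaks = 0,
                      n_disease_glial_female_peaks = 0, seed = 21)
    pk <- simulate_peak_universe(cfg)
    md <- simulate_metadata(cfg)
    sim <- simulate_counts(cfg, pk, md)
    pc1 <- prcomp(t(cpm_log(sim$counts)))$x[, 1]
    abs(cor(md$nrf, pc1))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("read-position multisets honour depth and duplication structure", {
  p1 <- simulate_read_positions(100, distinct_fraction = 1, seed = 3)
  expect_equal(length(p1), 100)
  expect_equal(length(unique(p1)), 100)

  p2 <- simulate_read_positions(100, duplication_profile = c(`2` = 50),
                                seed = 3)
  expect_equal(length(p2), 100)
  expect_equal(length(unique(p2)), 50)
  expect_true(all(table(p2) == 2))

  # arbitrary profile reproduced exactly
  prof <- c(`1` = 6, `2` = 2, `5` = 1)
  p3 <- simulate_read_positions(15, duplication_profile = prof, seed = 3)
  hist3 <- table(factor(table(p3), levels = c(1, 2, 5)))
  expect_equal(as.integer(hist3), c(6, 2, 1))

  expect_error(simulate_read_positions(10, duplication_profile = c(`3` = 2)),
               "infeasible")
  expect_error(simulate_read_positions(10, distinct_fraction = 0), "distinct")
})

test_that("planted GWAS regions control the observed overlap exactly", {
  des <- flat_design(10)
  base <- list(n_peaks = 400, design = des, seed = 31,
               chrom_sizes = c(chr1 = 5e8, chr2 = 5e8, chrX = 1e8, chrY = 5e7))

  mk <- function(planted_fraction, n_gwas_regions = 10) {
    do.call(sim_config, c(base, list(planted_fraction = planted_fraction,
                                     n_gwas_regions = n_gwas_regions)))
  }
  cfg <- mk(1)
  pk <- simulate_peak_universe(cfg)
  diff_ids <- pk$peak_id[seq(1, 400, by = 40)]  # 10 sparse "differential" peaks
  reg <- plant_gwas_regions(cfg, pk, diff_ids)
  ov <- overlap_regions(pk[pk$peak_id %in% diff_ids, ], reg)
  expect_equal(ov$n_sites, 10)

  # planted_fraction = 0: windows avoid every differential peak
  reg0 <- plant_gwas_regions(mk(0), pk, diff_ids)
  ov0 <- overlap_regions(pk[pk$peak_id %in% diff_ids, ], reg0)
  expect_equal(ov0$n_sites, 0)

  # intermediate fraction: observed equals the construction
  reg5 <- plant_gwas_regions(mk(0.5), pk, diff_ids)
  ov5 <- overlap_regions(pk[pk$peak_id %in% diff_ids, ], reg5)
  expect_equal(ov5$n_sites, 5)

  # infeasible: more planted peaks than windows
  expect_error(plant_gwas_regions(mk(1, n_gwas_regions = 5), pk, diff_ids),
               "windows")
})

test_that("simulation artifacts round-trip through disk", {
  cfg <- null_sim_config(n_peaks = 50, design = flat_design(4), seed = 8,
                         n_gwas_regions = 5)
  pk <- simulate_peak_universe(cfg)
  md <- simulate_metadata(cfg)
  sim <- simulate_counts(cfg, pk, md)
  reg <- plant_gwas_regions(cfg, pk, character(0))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, pk, md, reg, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_counts_tsv(paths[["counts"]]), sim$counts)
  expect_equal(read_bed(paths[["peaks"]])$start, pk$start)
})
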