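sim_bundle <- function(cfg) {
  pk <- simulate_peak_universe(cfg)
  md <- simulate_metadata(cfg)
  sim <- simulate_counts(cfg, pk, md)
  list(peaks = pk, metadata = md, counts = sim$counts, truth = sim$truth)
}

test_that("level presets encode the study's cohort arithmetic", {
  expect_equal(level_preset("L1")$nominal_n, c(40, 40))
  expect_true(level_preset("L1")$paired_by_donor)
  # sex-stratified group sizes sum to the per-fraction comparison sizes
  for (fr in list(c("L3A", "L3B"), c("L3C", "L3D"))) {
    a <- level_preset(fr[1])$nominal_n
    b <- level_preset(fr[2])$nominal_n
    expect_equal(a + b, level_preset(sub("L3.", "L2_neuronal", fr[1]))$nominal_n)
  }
  expect_equal(level_preset("L3E")$nominal_n, c(14, 13))
  expect_true(level_preset("L3E")$include_unpaired)
})

test_that("differential results exclude sex chromosomes and label direction", {
  cfg <- null_sim_config(n_peaks = 400, design = flat_design(8), seed = 3)
  b <- sim_bundle(cfg)
  expect_true(any(parse_peak_id(rownames(b$counts))$chrom %in%
                    c("chrX", "chrY")))
  res <- suppressWarnings(run_contrast(b$counts, b$metadata, flat_spec()))
  expect_false(any(res$chrom %in% c("chrX", "chrY")))
  expect_true(all(res$direction[res$log2FC > 0] == "more_accessible_in_case"))
  expect_true(all(diff(res$p) >= 0))
  # BH q is a monotone step function of ranked p
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})

test_that("contrast guards: group sizes, covariates, confounded designs", {
  cfg <- null_sim_config(n_peaks = 100, design = flat_design(4), seed = 5)
  b <- sim_bundle(cfg)
  expect_error(run_contrast(b$counts, b$metadata, flat_spec(sex = "M")),
               ">= 2 samples")
  expect_error(
    run_contrast(b$counts, b$metadata, flat_spec(), covariates = "nope"),
    "covariate not in metadata"
  )
  md2 <- b$metadata
  md2$leak <- as.numeric(md2$diagnosis != "control")
  expect_error(run_contrast(b$counts, md2, flat_spec(), covariates = "leak"),
               "confounded")
})

test_that("case/control label swap negates log2FC and keeps p", {
  cfg <- null_sim_config(n_peaks = 300, design = flat_design(8), seed = 7)
  b <- sim_bundle(cfg)
  res1 <- run_contrast(b$counts, b$metadata, flat_spec())
  md_sw <- b$metadata
  md_sw$diagnosis <- ifelse(md_sw$diagnosis == "control", "mild_LOAD",
                            "control")
  res2 <- run_contrast(b$counts, md_sw, flat_spec())
  m <- match(res1$peak_id, res2$peak_id)
  expect_equal(res1$log2FC, -res2$log2FC[m], tolerance = 1e-6)
  expect_equal(res1$p, res2$p[m], tolerance = 1e-6)
})

test_that("results are invariant to sample and peak ordering", {
  cfg <- null_sim_config(n_peaks = 200, design = flat_design(6), seed = 9)
  b <- sim_bundle(cfg)
  res1 <- run_contrast(b$counts, b$metadata, flat_spec())
  set.seed(1)
  y2 <- b$counts[sample(nrow(b$counts)), sample(ncol(b$counts))]
  md2 <- b$metadata[sample(nrow(b$metadata)), ]
  res2 <- run_contrast(y2, md2, flat_spec())
  m <- match(res1$peak_id, res2$peak_id)
  expect_equal(res1$log2FC, res2$log2FC[m], tolerance = 1e-8)
  expect_equal(res1$q, res2$q[m], tolerance = 1e-8)
})

test_that("null cohort yields no discoveries; planted effects are found", {
  # null: no q < 0.05 discoveries expected
  cfg0 <- null_sim_config(n_peaks = 800, design = flat_design(10), seed = 21)
  b0 <- sim_bundle(cfg0)
  res0 <- run_contrast(b0$counts, b0$metadata, flat_spec())
  expect_lte(sum(res0$q < 0.05), 2)

  # planted disease effects at the paired-cohort scale are recovered
  cfg1 <- sim_config(n_peaks = 800, seed = 22,
                     confounders = default_confounders(loading = 0),
                     confounder_peak_fraction = 0)
  b1 <- sim_bundle(cfg1)
  res1 <- run_contrast(b1$counts, b1$metadata, "L2_neuronal")
  sig <- res1$peak_id[res1$q < 0.05]
  truth <- b1$truth$differential$disease_neuronal
  expect_gt(length(sig), 0)
  # discoveries are dominated by planted peaks (empirical FDR controlled)
  expect_lte(mean(!(sig %in% truth)), 0.2)
})

test_that("sex-restricted glial effects surface only in the female stratum", {
  cfg <- sim_config(n_peaks = 1200, seed = 23,
                    n_cell_type_peaks = 0, n_disease_neuronal_peaks = 0,
                    n_disease_glial_female_peaks = 60,
                    disease_lfc_range = c(1.5, 2.5),
                    confounders = default_confounders(loading = 0),
                    confounder_peak_fraction = 0)
  b <- sim_bundle(cfg)
  res_f <- run_contrast(b$counts, b$metadata, "L3A")
  res_m <- run_contrast(b$counts, b$metadata, "L3B")
  n_f <- sum(res_f$q < 0.05)
  n_m <- sum(res_m$q < 0.05)
  expect_gt(n_f, 0)
  expect_lte(n_m, max(1, 0.1 * n_f))
})

test_that("donor-blocked cell-type contrast recovers planted differences", {
  # a reduced paired cohort keeps the donor-blocked design small
  donors <- tibble::tibble(
    donor_id = sprintf("D%02d", 1:12),
    diagnosis = rep(c("control", "mild_LOAD"), 6),
    sex = rep(c("F", "M"), each = 6)
  )
  des <- tidyr::crossing(donors, cell_fraction = c("neuronal", "non_neuronal"))
  des$sample_id <- paste0(des$donor_id, "_", substr(des$cell_fraction, 1, 3))
  cfg <- sim_config(n_peaks = 400, design = des, seed = 25,
                    n_cell_type_peaks = 40,
                    cell_type_lfc_range = c(2, 3),
                    n_disease_neuronal_peaks = 0,
                    n_disease_glial_female_peaks = 0,
                    confounders = default_confounders(loading = 0),
                    confounder_peak_fraction = 0)
  b <- sim_bundle(cfg)
  res <- suppressWarnings(run_contrast(b$counts, b$metadata, "L1"))
  sig <- res$peak_id[res$q < 0.05]
  truth <- b$truth$differential$cell_type
  expect_gt(mean(truth %in% sig), 0.6)
  g <- glance(res)
  expect_equal(g$label, "L1")
  expect_equal(g$n_significant, length(sig))
})
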