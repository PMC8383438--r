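# construct a samples-described matrix with known latent structure
latent_matrix <- function(n = 30, g = 200, strength = 3, seed = 1,
                          z = NULL) {
  set.seed(seed)
  if (is.null(z)) z <- rnorm(n)
  gamma <- rnorm(g, 0, strength / sqrt(g))
  mat <- outer(gamma, z) * sqrt(g) + matrix(rnorm(g * n), g, n)
  dimnames(mat) <- list(sprintf("p%03d", 1:g), sprintf("s%02d", 1:n))
  list(mat = mat, z = z)
}

md_for <- function(mat, ...) {
  tibble::tibble(sample_id = colnames(mat), ...)
}

test_that("PC association recovers planted and constructed signals", {
  lt <- latent_matrix(seed = 2)
  pc1 <- prcomp(t(lt$mat))$x[, 1]
  md <- md_for(lt$mat, copy_pc1 = pc1, noise = rnorm(ncol(lt$mat)))
  cands <- covariate_candidates(md, c("copy_pc1", "noise"))
  assoc <- suppressWarnings(pc_association(lt$mat, md, cands, n_pcs = 5))
  expect_lt(assoc$pvals["copy_pc1", 1], 1e-20)
  expect_gt(min(assoc$pvals["copy_pc1", 3:5]), 1e-4)

  # categorical split on the sign of PC2
  pc2 <- prcomp(t(lt$mat))$x[, 2]
  md2 <- md_for(lt$mat, split2 = ifelse(pc2 > 0, "a", "b"))
  cands2 <- covariate_candidates(md2, "split2")
  assoc2 <- pc_association(lt$mat, md2, cands2, n_pcs = 5)
  expect_lt(assoc2$pvals["split2", 2], 1e-6)
  expect_equal(cands2$kind, "categorical")

  # constant candidate: warned, p = 1
  md3 <- md_for(lt$mat, flat = 1)
  expect_warning(
    assoc3 <- pc_association(lt$mat, md3,
                             covariate_candidates(md3, "flat"), n_pcs = 3),
    "constant"
  )
  expect_true(all(assoc3$pvals == 1))

  expect_error(pc_association(lt$mat[, 1:4], md, cands, n_pcs = 10),
               "more samples")
})

test_that("null covariates give uniform association p-values", {
  # pooled PC1 p-values over independent replicates are U(0,1)
  ps <- vapply(1:300, function(i) {
    set.seed(1000 + i)
    mat <- matrix(rnorm(40 * 24), 40, 24,
                  dimnames = list(NULL, sprintf("s%02d", 1:24)))
    md <- tibble::tibble(sample_id = colnames(mat), v = rnorm(24))
    assoc <- pc_association(mat, md, covariate_candidates(md, "v"), n_pcs = 2)
    assoc$pvals[1, 1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("selection ranking prefers technical, high-variance, low-parameter", {
  cands <- tibble::tibble(
    name = c("bio", "tech"), kind = "continuous",
    n_levels = 1L, is_technical = c(FALSE, TRUE)
  )
  assoc <- structure(list(
    pvals = matrix(1e-10, 2, 2, dimnames = list(cands$name, c("PC1", "PC2"))),
    varshare = c(0.5, 0.3)
  ), class = "pc_association")
  expect_equal(select_next(assoc, cands), "tech")

  # nothing significant: NULL
  assoc$pvals[] <- 0.5
  expect_null(select_next(assoc, cands))

  # larger variance-share signal wins among equals
  cands2 <- tibble::tibble(name = c("v40", "v10"), kind = "continuous",
                           n_levels = 1L, is_technical = TRUE)
  pv <- matrix(1, 2, 2, dimnames = list(cands2$name, c("PC1", "PC2")))
  pv["v40", 1] <- 1e-8
  pv["v10", 2] <- 1e-8
  assoc2 <- structure(list(pvals = pv, varshare = c(0.4, 0.1)),
                      class = "pc_association")
  expect_equal(select_next(assoc2, cands2), "v40")

  # fewer parameters breaks exact ties
  cands3 <- tibble::tibble(name = c("many", "few"), kind = "categorical",
                           n_levels = c(6L, 2L), is_technical = TRUE)
  pv3 <- matrix(c(1e-8, 1e-8, 1, 1), 2, 2,
                dimnames = list(cands3$name, c("PC1", "PC2")))
  assoc3 <- structure(list(pvals = pv3, varshare = c(0.4, 0.1)),
                      class = "pc_association")
  expect_equal(select_next(assoc3, cands3), "few")
})

test_that("regressing out a covariate removes it and is idempotent", {
  set.seed(4)
  v <- rnorm(30)
  w <- rnorm(150)
  mat <- outer(w, v) + matrix(rnorm(150 * 30, sd = 0.2), 150, 30)
  colnames(mat) <- sprintf("s%02d", 1:30)
  res <- regress_out(mat, v)
  cors <- apply(res, 1, cor, v)
  expect_lt(max(abs(cors)), 1e-8)
  # peak means preserved (intercept added back)
  expect_equal(rowMeans(res), rowMeans(mat), tolerance = 1e-10)
  # idempotent
  expect_equal(regress_out(res, v), res, tolerance = 1e-10)
  # constant covariate: unchanged
  expect_equal(regress_out(mat, rep(2, 30)), mat)
  # categorical with a singleton level: warned, that sample's residual 0
  fac <- factor(c("solo", rep(c("a", "b"), length.out = 29)))
  expect_warning(r2 <- regress_out(mat, fac), "single sample")
  centered <- r2 - rowMeans(r2)
  expect_equal(unname(centered[, 1]), rep(0, 150), tolerance = 1e-10)
})

test_that("iterative selection recovers planted confounders then stops", {
  # one strong planted confounder
  lt <- latent_matrix(n = 30, g = 200, strength = 4, seed = 6)
  md <- md_for(lt$mat,
               conf = lt$z + rnorm(30, sd = 0.1),
               noise1 = rnorm(30), noise2 = rnorm(30))
  cands <- covariate_candidates(md, c("conf", "noise1", "noise2"),
                                technical = "conf")
  sel <- run_selection(lt$mat, md, cands, n_pcs = 5)
  expect_equal(sel$selected, "conf")
  expect_equal(sel$stop_reason, "no significant candidate")

  # residual matrix is clean: re-running selects nothing
  sel2 <- run_selection(sel$residual_matrix, md, cands, n_pcs = 5)
  expect_length(sel2$selected, 0)

  # null data: nothing selected
  set.seed(8)
  nullmat <- matrix(rnorm(200 * 30), 200, 30,
                    dimnames = list(NULL, sprintf("s%02d", 1:30)))
  sel3 <- run_selection(nullmat, md, cands, n_pcs = 5)
  expect_length(sel3$selected, 0)

  # broom-style accessors
  expect_equal(glance(sel)$n_selected, 1)
  expect_equal(nrow(tidy(sel)), length(sel$iterations))
})

test_that("two orthogonal confounders are recovered in variance order", {
  hits <- 0; ordered <- 0
  for (i in 1:20) {
    set.seed(200 + i)
    n <- 30; g <- 300
    z1 <- rnorm(n); z2 <- rnorm(n)
    g1 <- rnorm(g); g2 <- rnorm(g)
    mat <- 3 * outer(g1, z1) + 1.5 * outer(g2, z2) +
      matrix(rnorm(g * n), g, n)
    colnames(mat) <- sprintf("s%02d", 1:n)
    md <- tibble::tibble(sample_id = colnames(mat), c1 = z1, c2 = z2)
    sel <- run_selection(mat, md, covariate_candidates(md, c("c1", "c2")),
                         n_pcs = 5)
    if (setequal(sel$selected, c("c1", "c2"))) {
      hits <- hits + 1
      if (identical(sel$selected, c("c1", "c2"))) ordered <- ordered + 1
    }
  }
  expect_gte(hits, 18)
  expect_gte(ordered, 18)
})

test_that("recovery probability is nondecreasing in confounder loading", {
  recover <- vapply(c(0.2, 0.5, 1.0), function(load) {
    got <- 0
    for (i in 1:15) {
      set.seed(3000 + i)
      n <- 24; g <- 150
      z <- rnorm(n)
      mat <- load * 3 * outer(rnorm(g), z) + matrix(rnorm(g * n), g, n)
      colnames(mat) <- sprintf("s%02d", 1:n)
      md <- tibble::tibble(sample_id = colnames(mat), conf = z)
      sel <- run_selection(mat, md, covariate_candidates(md, "conf"),
                           n_pcs = 4)
      if (identical(sel$selected, "conf")) got <- got + 1
    }
    got
  }, numeric(1))
  expect_true(all(diff(recover) >= 0))
})

test_that("pure-noise matrices rarely select anything (family-wise control)", {
  n_sel <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    mat <- matrix(rnorm(60 * 20), 60, 20,
                  dimnames = list(NULL, sprintf("s%02d", 1:20)))
    md <- tibble::tibble(sample_id = colnames(mat),
                         a = rnorm(20), b = rnorm(20))
    length(run_selection(mat, md, covariate_candidates(md, c("a", "b")),
                         n_pcs = 3)$selected)
  }, numeric(1))
  expect_lte(mean(n_sel > 0), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("median/mode imputation flags exactly the filled cells", {
  md <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    pmi = c(4, NA, 8),
    batch = c("x", "x", NA)
  )
  # median of a 2-value set: mean convention
  out <- impute_missing(md)
  expect_equal(out$pmi[2], 6)
  expect_equal(out$batch[3], "x")
  flags <- attr(out, "imputed")
  expect_equal(which(flags[, "pmi"]), 2L)
  expect_equal(which(flags[, "batch"]), 3L)
  expect_equal(sum(flags), 2)

  # identity on complete data
  out2 <- impute_missing(out)
  expect_equal(sum(attr(out2, "imputed")), 0)

  expect_error(impute_missing(tibble::tibble(x = c(NA_real_, NA_real_))),
               "entirely missing")
})
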