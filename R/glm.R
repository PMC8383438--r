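# Negative-binomial GLM machinery for differential accessibility testing.
# All fits share one design matrix across peaks, so IRLS is vectorized over
# peaks: the per-iteration normal equations are assembled with two matrix
# products and solved peak-by-peak on tiny p x p systems.

nb_deviance <- function(y, mu, phi) {
  # rowwise NB deviance; phi ~ 0 falls back to the Poisson expression
  y <- as.matrix(y); mu <- pmax(as.matrix(mu), 1e-10)
  phim <- matrix(phi, nrow(y), ncol(y))
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(phim < 1e-10,
               y - mu,
               (y + 1 / phim) * log((1 + phim * y) / (1 + phim * mu)))
  rowSums(2 * (t1 - t2))
}

#' Fit negative-binomial log-link GLMs across peaks
#'
#' Fisher-scoring (IRLS) fit of `y ~ design` with log link, per-sample
#' offsets (log effective library sizes) and per-peak dispersion `phi`.
#' All peaks are fit simultaneously against the shared design matrix.
#' Convergence: relative deviance change below `tol` or `max_iter`
#' iterations; non-converged peaks are flagged, never fatal.
#'
# Batched solve of G symmetric p x p systems given packed row-major upper
# triangles A (G x p(p+1)/2) and right-hand sides B (G x p). Closed-form
# and fully vectorized for p <= 3; per-peak Cholesky otherwise.
solve_batch <- function(A, B, p) {
  G <- nrow(A)
  beta <- matrix(NA_real_, G, p)
  logdet <- rep(NA_real_, G)
  failed <- rep(FALSE, G)
  if (p == 1) {
    failed <- A[, 1] <= 0
    beta[, 1] <- B[, 1] / A[, 1]
    logdet <- log(A[, 1])
  } else if (p == 2) {
    a <- A[, 1]; b <- A[, 2]; d <- A[, 3]
    det <- a * d - b * b
    failed <- !(det > 0 & a > 0)
    beta[, 1] <- (d * B[, 1] - b * B[, 2]) / det
    beta[, 2] <- (a * B[, 2] - b * B[, 1]) / det
    logdet <- log(det)
  } else if (p == 3) {
    a <- A[, 1]; b <- A[, 2]; c <- A[, 3]
    d <- A[, 4]; e <- A[, 5]; f <- A[, 6]
    # inverse via cofactors of [[a,b,c],[b,d,e],[c,e,f]]
    C11 <- d * f - e * e
    C12 <- c * e - b * f
    C13 <- b * e - c * d
    C22 <- a * f - c * c
    C23 <- b * c - a * e
    C33 <- a * d - b * b
    det <- a * C11 + b * C12 + c * C13
    failed <- !(det > 0 & a > 0 & C33 > 0)
    beta[, 1] <- (C11 * B[, 1] + C12 * B[, 2] + C13 * B[, 3]) / det
    beta[, 2] <- (C12 * B[, 1] + C22 * B[, 2] + C23 * B[, 3]) / det
    beta[, 3] <- (C13 * B[, 1] + C23 * B[, 2] + C33 * B[, 3]) / det
    logdet <- log(det)
  } else {
    pair_i <- rep(seq_len(p), times = seq(p, 1))
    pair_k <- unlist(lapply(seq_len(p), function(i) i:p))
    M <- matrix(0, p, p)
    for (g in seq_len(G)) {
      M[cbind(pair_i, pair_k)] <- A[g, ]
      M[cbind(pair_k, pair_i)] <- A[g, ]
      ch <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(ch)) { failed[g] <- TRUE; next }
      beta[g, ] <- backsolve(ch, forwardsolve(t(ch), B[g, ]))
      logdet[g] <- 2 * sum(log(diag(ch)))
    }
  }
  bad <- failed | !is.finite(rowSums(beta))
  list(beta = beta, logdet = logdet, failed = bad)
}

#' @param y Count matrix (peaks x samples) or a single row.
#' @param design Numeric design matrix (samples x p), full rank.
#' @param offsets Numeric vector of per-sample offsets (default 0).
#' @param phi Per-peak dispersion (scalar recycled).
#' @param tol,max_iter Convergence controls.
#' @param beta_init Optional warm-start coefficient matrix (peaks x p).
#' @return List: `coefficients` (peaks x p), `fitted` (mu, peaks x samples),
#'   `deviance`, `converged`, `df_residual`, `logdet_info` (log-determinant
#'   of the Fisher information at the optimum, for profile adjustments).
#' @export
fit_nb_glm <- function(y, design, offsets = NULL, phi = 0.1,
                       tol = 1e-8, max_iter = 50, beta_init = NULL) {
  y <- rbind(y)
  G <- nrow(y); n <- ncol(y); p <- ncol(design)
  if (qr(design)$rank < p) abort("design matrix is not full rank")
  if (n - p < 0) abort("more coefficients than samples")
  if (is.null(offsets)) offsets <- rep(0, n)
  phi <- rep_len(phi, G)
  X <- design

  # packed row-major upper triangle of X' W X, assembled by matrix product
  pair_i <- rep(seq_len(p), times = seq(p, 1))
  pair_k <- unlist(lapply(seq_len(p), function(i) i:p))
  XX <- X[, pair_i, drop = FALSE] * X[, pair_k, drop = FALSE]  # n x p(p+1)/2

  off_m <- matrix(offsets, G, n, byrow = TRUE)
  if (is.null(beta_init)) {
    mu <- pmax(y, 0.5)
    eta <- log(mu)
  } else {
    eta <- pmin(beta_init %*% t(X) + off_m, 50)
    mu <- pmax(exp(eta), 1e-10)
  }
  beta <- matrix(0, G, p)
  dev <- rep(Inf, G)
  converged <- rep(FALSE, G)
  failed <- rep(FALSE, G)
  logdet <- rep(NA_real_, G)
  phim <- matrix(phi, G, n)

  for (iter in seq_len(max_iter)) {
    W <- mu / (1 + phim * mu)
    z <- (eta - off_m) + (y - mu) / mu
    A <- W %*% XX              # G x p(p+1)/2
    B <- (W * z) %*% X         # G x p
    sol <- solve_batch(A, B, p)
    upd <- !sol$failed & !converged
    beta[upd, ] <- sol$beta[upd, , drop = FALSE]
    logdet[upd] <- sol$logdet[upd]
    failed <- failed | (sol$failed & !converged)
    converged <- converged | failed
    eta <- pmin(beta %*% t(X) + off_m, 50)
    mu <- pmax(exp(eta), 1e-10)
    new_dev <- nb_deviance(y, mu, phi)
    done <- abs(new_dev - dev) < tol * (abs(new_dev) + 0.1)
    dev <- new_dev
    converged <- converged | done
    if (all(converged)) break
  }
  list(
    coefficients = beta,
    fitted = mu,
    deviance = dev,
    converged = converged & !failed,
    df_residual = n - p,
    logdet_info = logdet
  )
}

nb_loglik <- function(y, mu, phi) {
  # rowwise NB log-likelihood; phi scalar or per-peak
  G <- nrow(y)
  phim <- matrix(rep_len(phi, G), G, ncol(y))
  rowSums(dnbinom(y, size = 1 / phim, mu = pmax(mu, 1e-10), log = TRUE))
}

moving_average <- function(x, width) {
  # centered running mean with shrinking windows at the edges
  n <- length(x)
  if (width >= n) return(rep(mean(x), n))
  cs <- cumsum(c(0, x))
  half <- floor(width / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

grid_interp_max <- function(grid_log, value) {
  # quadratic interpolation of the maximizer on a log-dispersion grid
  j <- which.max(value)
  if (j == 1 || j == length(grid_log)) return(exp(grid_log[j]))
  y0 <- value[j - 1]; y1 <- value[j]; y2 <- value[j + 1]
  denom <- y0 - 2 * y1 + y2
  if (!is.finite(denom) || denom >= 0) return(exp(grid_log[j]))
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 1), -1)
  step <- grid_log[2] - grid_log[1]
  exp(grid_log[j] + delta * step)
}

#' Estimate NB dispersions: common, trended, tagwise
#'
#' Common dispersion maximizes the Cox-Reid adjusted profile likelihood
#' (sum over peaks of the NB log-likelihood minus half the log-determinant
#' of the Fisher information) over a log-spaced dispersion grid, refined by
#' quadratic interpolation. Trended values smooth per-peak profile
#' likelihoods along abundance; tagwise values are empirical-Bayes
#' maximizers of the per-peak likelihood plus `prior_df / df_residual`
#' times the local (trend) likelihood — as `prior_df` grows they collapse
#' onto the trend.
#'
#' @param counts Count matrix (peaks x samples); all-zero rows are excluded
#'   (with a message) and returned as NA.
#' @param design Design matrix (samples x p).
#' @param offsets Log effective library sizes (default: log column sums).
#' @param prior_df Prior degrees of freedom for tagwise shrinkage
#'   (default 10; `Inf` returns the trend).
#' @param grid_range,grid_length Dispersion grid (log-spaced).
#' @param trend_span Fraction of peaks in the moving-average trend window.
#' @return List: `common`, `trended`, `tagwise` (per input row; NA for
#'   excluded rows), `grid`, `ok` (rows used).
#' @export
estimate_dispersions <- function(counts, design, offsets = NULL,
                                 prior_df = 10,
                                 grid_range = c(1e-4, 4), grid_length = 25,
                                 trend_span = 0.1) {
  y_all <- as.matrix(counts)
  ok <- rowSums(y_all) > 0
  if (!all(ok)) {
    inform(sprintf("excluding %d all-zero peak row(s) from dispersion estimation",
                   sum(!ok)))
  }
  y <- y_all[ok, , drop = FALSE]
  G <- nrow(y); n <- ncol(y); p <- ncol(design)
  if (n - p < 1) abort("no residual degrees of freedom")
  if (is.null(offsets)) offsets <- log(colSums(y_all))

  grid_log <- seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_length)
  grid <- exp(grid_log)

  apl <- numeric(grid_length)
  L <- matrix(NA_real_, G, grid_length)
  beta_prev <- NULL
  for (k in seq_len(grid_length)) {
    fit <- fit_nb_glm(y, design, offsets, phi = grid[k],
                      beta_init = beta_prev,
                      max_iter = if (is.null(beta_prev)) 50 else 20)
    beta_prev <- fit$coefficients
    ll <- nb_loglik(y, fit$fitted, grid[k])
    cr <- 0.5 * ifelse(is.finite(fit$logdet_info), fit$logdet_info, 0)
    apl[k] <- sum(ll - cr)
    L[, k] <- ll - cr
  }
  common <- grid_interp_max(grid_log, apl)

  # abundance ordering for the trend
  ab <- rowMeans(cpm_log(y, norm = NULL))
  ord <- order(ab)
  width <- max(10, ceiling(trend_span * G))
  Ltrend <- L
  for (k in seq_len(grid_length)) {
    sm <- moving_average(L[ord, k], width)
    Ltrend[ord, k] <- sm
  }
  trended <- vapply(seq_len(G), function(g) {
    grid_interp_max(grid_log, Ltrend[g, ])
  }, numeric(1))

  prior_n <- prior_df / (n - p)
  tagwise <- if (is.infinite(prior_df)) {
    trended
  } else {
    post <- L + prior_n * Ltrend
    vapply(seq_len(G), function(g) {
      grid_interp_max(grid_log, post[g, ])
    }, numeric(1))
  }

  expand <- function(v) {
    out <- rep(NA_real_, nrow(y_all))
    out[ok] <- pmax(v, 1e-6)
    out
  }
  list(
    common = max(common, 1e-6),
    trended = expand(trended),
    tagwise = expand(tagwise),
    grid = grid,
    ok = ok
  )
}

#' Quasi-likelihood F-test between nested NB fits
#'
#' Per-peak quasi-dispersion is the full-model deviance over its residual
#' df; quasi-dispersions are moderated across peaks by empirical-Bayes
#' squeezing toward their common trend (estimated prior df), and
#' `F = (deviance difference / df difference) / moderated quasi-dispersion`
#' is referred to an F distribution on `(delta_df, df_prior + df_residual)`.
#'
#' @param fit_full,fit_reduced Results of [fit_nb_glm()] on nested designs
#'   (same peaks, same samples).
#' @return Tibble: `stat`, `p`, `df1`, `df2`, `s2_post`, plus the prior df
#'   in attribute `df_prior`. Non-converged peaks get p = 1.
#' @export
ql_f_test <- function(fit_full, fit_reduced) {
  df1 <- fit_reduced$df_residual - fit_full$df_residual
  if (df1 <= 0) abort("contrast is empty: reduced design is not smaller")
  G <- length(fit_full$deviance)
  df_res <- fit_full$df_residual
  s2 <- pmax(fit_full$deviance / df_res, 1e-10)
  sq <- limma::squeezeVar(s2, df = df_res)
  df_prior <- sq$df.prior
  if (!is.finite(df_prior)) df_prior <- 1e6
  ddev <- pmax(fit_reduced$deviance - fit_full$deviance, 0)
  Fstat <- (ddev / df1) / sq$var.post
  df2 <- df_prior + df_res
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  bad <- !(fit_full$converged & fit_reduced$converged)
  p[bad] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- tibble(stat = Fstat, p = p, df1 = df1, df2 = df2,
                s2_post = sq$var.post)
  attr(out, "df_prior") <- df_prior
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement
#' (delegates to `stats::p.adjust`).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}
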