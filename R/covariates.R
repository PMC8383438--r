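#' Declare covariate candidates from a metadata table
#'
#' Builds the candidate table consumed by the selection loop. A candidate is
#' continuous when its metadata column is numeric, categorical otherwise
#' (`n_levels` = number of observed levels). `is_technical` marks variables
#' that describe the assay rather than the subject; the selection rule
#' prefers these.
#'
#' @param metadata Per-sample tibble.
#' @param names Columns to consider.
#' @param technical Subset of `names` that are assay-related.
#' @return Tibble: `name`, `kind`, `n_levels`, `is_technical`.
#' @export
covariate_candidates <- function(metadata, names,
                                 technical = intersect(names, c(
                                   "sort_date", "nrf", "alignment_pct",
                                   "nuclei_count", "gc_pct",
                                   "normalized_peak_calls", "passing_bp",
                                   "transposase_batch"))) {
  miss <- setdiff(names, colnames(metadata))
  if (length(miss) > 0) abort(paste0("unknown metadata column: ", miss[1]))
  tibble(
    name = names,
    kind = ifelse(purrr::map_lgl(names, ~ is.numeric(metadata[[.x]])),
                  "continuous", "categorical"),
    n_levels = purrr::map_int(names, function(nm) {
      if (is.numeric(metadata[[nm]])) 1L
      else length(unique(stats::na.omit(metadata[[nm]])))
    }),
    is_technical = names %in% technical
  )
}

#' Associate candidate covariates with count principal components
#'
#' PCA (centering only) of the samples on a log-scale peak matrix, then for
#' each candidate and each of the first `n_pcs` score vectors a univariate
#' linear model `PC ~ candidate` (one-way ANOVA F-test for categorical
#' candidates). Constant candidates get p = 1 with a warning.
#'
#' @param log_counts Numeric matrix, peaks x samples.
#' @param metadata Per-sample tibble aligned to `colnames(log_counts)` via
#'   `sample_id`.
#' @param candidates Tibble from [covariate_candidates()].
#' @param n_pcs Number of leading PCs (default 10; requires more samples
#'   than PCs).
#' @return List of class `pc_association`: `pvals` (candidate x PC matrix),
#'   `varshare` (variance proportion per PC), `scores` (sample x PC).
#' @export
pc_association <- function(log_counts, metadata, candidates, n_pcs = 10) {
  n <- ncol(log_counts)
  if (n <= n_pcs) abort("need more samples than principal components")
  ord <- match(colnames(log_counts), metadata$sample_id)
  if (anyNA(ord)) abort("metadata does not cover every sample")
  md <- metadata[ord, , drop = FALSE]

  pc <- prcomp(t(log_counts), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  varshare <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)]

  pvals <- matrix(NA_real_, nrow(candidates), n_pcs,
                  dimnames = list(candidates$name, colnames(scores)))
  for (i in seq_len(nrow(candidates))) {
    v <- md[[candidates$name[i]]]
    if (length(unique(stats::na.omit(v))) < 2) {
      warn(paste0("candidate constant across samples: ", candidates$name[i]))
      pvals[i, ] <- 1
      next
    }
    if (candidates$kind[i] == "categorical") v <- factor(v)
    for (j in seq_len(n_pcs)) {
      fit <- lm(scores[, j] ~ v)
      a <- anova(fit)
      pvals[i, j] <- a$`Pr(>F)`[1]
    }
  }
  structure(list(pvals = pvals, varshare = varshare, scores = scores),
            class = "pc_association")
}

#' Pick the next covariate to adjust for
#'
#' A candidate is significant when any of its PC p-values beats the
#' Bonferroni bound `alpha / (n_candidates * n_pcs)`. Significant candidates
#' are ranked by: assay-related (technical) first; then larger
#' `sum(-log10 p * PC variance share)` (the variance-weighted evidence
#' score); then fewer parameters (`n_levels`); then name. Returns `NULL`
#' when nothing is significant (loop termination).
#'
#' @param assoc A [pc_association()] result.
#' @param candidates Candidate tibble (rows matching `assoc$pvals`).
#' @param alpha Family-wise level before Bonferroni division (default 0.05).
#' @return Single candidate name, or `NULL`.
#' @export
select_next <- function(assoc, candidates, alpha = 0.05) {
  pv <- assoc$pvals
  thresh <- alpha / (nrow(pv) * ncol(pv))
  sig <- apply(pv, 1, function(p) any(p < thresh, na.rm = TRUE))
  if (!any(sig)) return(NULL)
  score <- as.vector(
    (-log10(pmax(pv, 1e-300))) %*% assoc$varshare
  )
  ranked <- tibble(
    name = candidates$name,
    sig = sig,
    tech = candidates$is_technical,
    score = score,
    n_levels = candidates$n_levels
  ) |>
    filter(.data$sig) |>
    arrange(dplyr::desc(.data$tech), dplyr::desc(.data$score),
            .data$n_levels, .data$name)
  ranked$name[1]
}

#' Regress a covariate out of a peak matrix
#'
#' Per-peak linear model `value ~ covariate` (indicator coding for factors);
#' returns residuals plus the per-peak intercept, so peak means are kept.
#' Continuous case leaves residuals with zero sample covariance with the
#' covariate (to numerical precision). Idempotent.
#'
#' @param log_counts Numeric matrix, peaks x samples.
#' @param values Covariate vector aligned to columns (numeric or factor).
#' @return Residual matrix, same dimensions/dimnames.
#' @export
regress_out <- function(log_counts, values) {
  n <- ncol(log_counts)
  if (length(values) != n) abort("covariate length must match sample count")
  if (is.character(values)) values <- factor(values)
  if (is.factor(values)) {
    sizes <- table(values)
    if (any(sizes == 1)) {
      warn("covariate level with a single sample: its residuals are 0 by construction")
    }
  }
  if (length(unique(values)) < 2) {
    return(log_counts)  # constant covariate: nothing to remove
  }
  X <- model.matrix(~values)
  Xc <- X[, -1, drop = FALSE]
  Xc <- sweep(Xc, 2, colMeans(Xc), "-")
  qr_x <- qr(Xc)
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  centered <- log_counts - rowMeans(log_counts)
  fitted <- (centered %*% Q) %*% t(Q)
  log_counts - fitted
}

#' Iterative PC-based covariate selection
#'
#' Repeats: associate candidates with the leading PCs; pick the strongest
#' significant candidate (see [select_next()]); regress it out of the
#' (residual) matrix; recompute the PCA. Stops when no candidate is
#' Bonferroni significant, when candidates are exhausted, or at `max_iter`.
#' Selected variables are removed from candidacy, so the loop always
#' terminates.
#'
#' @inheritParams pc_association
#' @param alpha Family-wise level (default 0.05).
#' @param max_iter Iteration cap (default: number of candidates).
#' @return Object of class `covariate_selection`: `selected` (ordered
#'   names), `iterations` (list of per-iteration records), `stop_reason`,
#'   `residual_matrix`.
#' @export
run_selection <- function(log_counts, metadata, candidates, n_pcs = 10,
                          alpha = 0.05, max_iter = nrow(candidates)) {
  mat <- log_counts
  remaining <- candidates
  iterations <- list()
  selected <- character(0)
  stop_reason <- "converged"
  it <- 0
  while (it < max_iter && nrow(remaining) > 0) {
    it <- it + 1
    assoc <- pc_association(mat, metadata, remaining, n_pcs = n_pcs)
    pick <- select_next(assoc, remaining, alpha = alpha)
    iterations[[it]] <- list(
      selected = pick %||% NA_character_,
      pvals = assoc$pvals,
      varshare = assoc$varshare,
      threshold = alpha / (nrow(assoc$pvals) * ncol(assoc$pvals))
    )
    if (is.null(pick)) {
      stop_reason <- "no significant candidate"
      break
    }
    selected <- c(selected, pick)
    ord <- match(colnames(mat), metadata$sample_id)
    mat <- regress_out(mat, metadata[[pick]][ord])
    remaining <- remaining[remaining$name != pick, , drop = FALSE]
    if (it == max_iter) stop_reason <- "max_iter"
  }
  if (nrow(remaining) == 0 && stop_reason == "converged") {
    stop_reason <- "candidates exhausted"
  }
  structure(
    list(selected = selected, iterations = iterations,
         stop_reason = stop_reason, residual_matrix = mat),
    class = "covariate_selection"
  )
}

#' Simple imputation of missing covariate values
#'
#' Continuous variables get their median, categorical their mode. Imputed
#' cells are flagged in the `imputed` attribute (a logical matrix). A
#' deliberately simple stand-in for chained-equation imputation.
#'
#' @param metadata Per-sample tibble.
#' @param method Only `"median"` (median/mode) is implemented.
#' @return Completed tibble with attribute `imputed`.
#' @export
impute_missing <- function(metadata, method = "median") {
  method <- match.arg(method)
  flags <- matrix(FALSE, nrow(metadata), ncol(metadata),
                  dimnames = list(NULL, colnames(metadata)))
  out <- metadata
  for (nm in colnames(metadata)) {
    v <- metadata[[nm]]
    na <- is.na(v)
    if (!any(na)) next
    if (all(na)) abort(paste0("variable entirely missing: ", nm))
    if (mean(na) >= 0.5) {
      warn(paste0("variable more than half missing: ", nm))
    }
    if (is.numeric(v)) {
      out[[nm]][na] <- median(v, na.rm = TRUE)
    } else {
      tab <- table(v[!na])
      out[[nm]][na] <- names(tab)[which.max(tab)]
    }
    flags[na, nm] <- TRUE
  }
  attr(out, "imputed") <- flags
  out
}
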