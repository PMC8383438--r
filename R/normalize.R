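#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values between-sample normalization for count
#' matrices (robust to composition bias). Each sample is compared to a
#' reference column; log-ratios (M) are trimmed two-sided by `trim_m` and
#' absolute intensities (A) by `trim_a`; the factor is 2 to the
#' precision-weighted mean of the surviving M-values, and factors are
#' rescaled to geometric mean 1. The reference is the sample whose
#' upper-quartile count fraction is closest to the mean upper quartile
#' (when `ref = "auto"`). Computation is delegated to the standard edgeR
#' implementation; this wrapper fixes the interface and output contract.
#'
#' @param counts Integer matrix, peaks x samples, with column names.
#' @param ref Reference sample id, or `"auto"`.
#' @param trim_m,trim_a Two-sided trim fractions for log-ratios and absolute
#'   intensity (defaults 0.30 / 0.05, the original method's values).
#' @return Tibble: `sample_id`, `library_size`, `tmm_factor`,
#'   `effective_library_size`.
#' @export
tmm_factors <- function(counts, ref = "auto", trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero) > 0) {
    abort(paste0("sample has all-zero counts: ", colnames(counts)[zero[1]]))
  }
  ref_col <- if (identical(ref, "auto")) {
    NULL
  } else {
    i <- match(ref, colnames(counts))
    if (is.na(i)) abort(paste0("unknown reference sample: ", ref))
    i
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref_col,
                              logratioTrim = trim_m, sumTrim = trim_a)
  tibble(
    sample_id = colnames(counts),
    library_size = unname(lib),
    tmm_factor = unname(f),
    effective_library_size = unname(lib * f)
  )
}

#' Log2 counts per million on effective library sizes
#'
#' `log2((count + prior) / (effective_library_size + 2*prior) * 1e6)`;
#' finite everywhere for `prior > 0`, invariant to doubling all counts and
#' library sizes, monotone in the count within a column.
#'
#' @param counts Count matrix (peaks x samples).
#' @param norm Tibble from [tmm_factors()] covering all samples, or `NULL`
#'   to use raw library sizes.
#' @param prior Pseudo-count added to each count (default 0.5).
#' @return Numeric matrix, same dimensions and dimnames as `counts`.
#' @export
cpm_log <- function(counts, norm = NULL, prior = 0.5) {
  if (is.null(norm)) {
    eff <- colSums(counts)
  } else {
    i <- match(colnames(counts), norm$sample_id)
    if (anyNA(i)) {
      abort(paste0("norm factors missing for sample: ",
                   colnames(counts)[which(is.na(i))[1]]))
    }
    eff <- norm$effective_library_size[i]
  }
  log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
}
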