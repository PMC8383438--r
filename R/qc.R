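#' ENCODE-style library complexity metrics
#'
#' Computes the Non-Redundant Fraction and PCR bottleneck coefficients from a
#' multiset of read positions:
#' NRF = distinct positions / total reads;
#' PBC1 = positions seen exactly once / distinct positions;
#' PBC2 = positions seen exactly once / positions seen exactly twice
#' (`Inf` when no position is seen twice but some are seen once).
#' Metrics are invariant to read order.
#'
#' @param positions Vector of genomic positions (one element per read).
#' @param sample_id Optional id recorded in the output.
#' @return One-row tibble: `sample_id`, `total_reads`, `distinct_reads`,
#'   `nrf`, `pbc1`, `pbc2`.
#' @examples
#' complexity_metrics(c(1, 1, 2, 3))  # NRF 0.75, PBC1 2/3, PBC2 2
#' @export
complexity_metrics <- function(positions, sample_id = NA_character_) {
  if (length(positions) == 0) abort("no reads")
  cnt <- table(positions)
  total <- length(positions)
  distinct <- length(cnt)
  m1 <- sum(cnt == 1)
  m2 <- sum(cnt == 2)
  pbc2 <- if (m2 == 0) {
    if (m1 > 0) Inf else NaN
  } else {
    m1 / m2
  }
  tibble(
    sample_id = sample_id,
    total_reads = total,
    distinct_reads = distinct,
    nrf = distinct / total,
    pbc1 = m1 / distinct,
    pbc2 = pbc2
  )
}

#' Sample-level QC filter
#'
#' Applies the study's sample filters: drop any dataset whose depth-normalized
#' peak-call count falls below `min_normalized_peak_calls`, then, where a
#' donor/cell-fraction combination still has replicate datasets, keep only the
#' replicate with the highest normalized peak calls (the quantitative proxy
#' for signal-to-noise).
#'
#' @param qc Tibble with `sample_id`, `normalized_peak_calls`, and (for
#'   replicate resolution) optional `donor_id`, `cell_fraction`.
#' @param min_normalized_peak_calls Threshold (peaks per million mapped
#'   reads); default 100.
#' @return Tibble `sample_id`, `kept` (logical), `reason` (NA when kept).
#' @export
filter_samples <- function(qc, min_normalized_peak_calls = 100) {
  if (nrow(qc) == 0) abort("qc table is empty")
  out <- tibble(sample_id = qc$sample_id, kept = TRUE, reason = NA_character_)
  low <- qc$normalized_peak_calls < min_normalized_peak_calls
  out$kept[low] <- FALSE
  out$reason[low] <- sprintf("normalized_peak_calls<%g", min_normalized_peak_calls)

  if (all(c("donor_id", "cell_fraction") %in% names(qc))) {
    surv <- qc[out$kept, , drop = FALSE]
    key <- paste(surv$donor_id, surv$cell_fraction, sep = "/")
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      best <- rows[which.max(surv$normalized_peak_calls[rows])]
      losers <- setdiff(rows, best)
      idx <- match(surv$sample_id[losers], out$sample_id)
      out$kept[idx] <- FALSE
      out$reason[idx] <- "lower-signal replicate"
    }
  }
  if (!any(out$kept)) warn("QC filter removed every sample")
  out
}

#' Flag outlier samples by PCA + Ward clustering
#'
#' Computes sample scores on the top principal components of a log-scale
#' count matrix, clusters them with classic Ward linkage on squared Euclidean
#' distances (the `ward.D`-on-squared-distances variant), and flags every
#' member of any cluster smaller than `min_cluster_frac` of the samples
#' (at least 1). Deterministic; ties in symmetric configurations resolve to
#' the lexicographically smallest sample ids via hclust's ordering.
#'
#' @param log_counts Numeric matrix, peaks x samples (column names = ids).
#' @param k Number of clusters to cut into (default 2).
#' @param n_pcs Number of PCs used (default 10, capped at the rank).
#' @param min_cluster_frac Clusters below this fraction are outliers.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(log_counts, k = 2, n_pcs = 10,
                                   min_cluster_frac = 0.05) {
  n <- ncol(log_counts)
  if (n < 3) abort("need at least 3 samples")
  if (all(apply(log_counts, 1, function(r) all(r == r[1])))) abort("no variance")
  pc <- prcomp(t(log_counts), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  hc <- hclust(dist(scores)^2, method = "ward.D")
  cl <- cutree(hc, k = k)
  sizes <- table(cl)
  cut <- max(1, floor(min_cluster_frac * n))
  small <- as.integer(names(sizes)[sizes <= cut])
  ids <- colnames(log_counts) %||% as.character(seq_len(n))
  sort(ids[cl %in% small])
}
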