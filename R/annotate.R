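#' Classify peaks by genomic feature category
#'
#' Assigns each peak exactly one of `promoter`, `first_exon`, `utr5`,
#' `utr3`, `intragenic`, `intergenic` by >= 1 bp overlap with gene-model
#' features, with precedence promoter > first_exon > utr5 > utr3 >
#' intragenic > intergenic. Promoters span the 1 kb upstream of the TSS:
#' `[TSS - 1000, TSS]` on the + strand, `[TSS, TSS + 1000]` on the - strand.
#'
#' @param peaks Interval tibble.
#' @param genes Gene-model tibble, one row per transcript: `chrom`,
#'   `strand` (`"+"`/`"-"`), `tx_start`, `tx_end`, `first_exon_start`,
#'   `first_exon_end`, and optional `utr5_start`, `utr5_end`, `utr3_start`,
#'   `utr3_end` (NA when absent); 0-based half-open.
#' @return Input tibble plus a `category` factor column.
#' @export
classify_peaks <- function(peaks, genes) {
  validate_intervals(peaks, "peak table")
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- which(!genes$strand %in% c("+", "-"))[1]
    abort(sprintf("gene model on unknown strand at row %d: '%s'",
                  bad, genes$strand[bad]))
  }
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  feat <- function(chrom, start, end) {
    keep <- !is.na(start) & !is.na(end) & end > start
    tibble(chrom = chrom[keep], start = start[keep], end = end[keep])
  }
  feature_sets <- list(
    promoter = feat(genes$chrom,
                    ifelse(genes$strand == "+", pmax(tss - 1000, 0), tss),
                    ifelse(genes$strand == "+", tss, tss + 1000)),
    first_exon = feat(genes$chrom, genes$first_exon_start,
                      genes$first_exon_end),
    utr5 = if (all(c("utr5_start", "utr5_end") %in% names(genes))) {
      feat(genes$chrom, genes$utr5_start, genes$utr5_end)
    } else {
      feat(character(), numeric(), numeric())
    },
    utr3 = if (all(c("utr3_start", "utr3_end") %in% names(genes))) {
      feat(genes$chrom, genes$utr3_start, genes$utr3_end)
    } else {
      feat(character(), numeric(), numeric())
    },
    intragenic = feat(genes$chrom, genes$tx_start, genes$tx_end)
  )
  levels <- c(names(feature_sets), "intergenic")
  out <- as_tibble(peaks)
  category <- rep("intergenic", nrow(out))
  if (nrow(out) > 0) {
    pgr <- as_granges(out)
    for (nm in names(feature_sets)) {
      fs <- feature_sets[[nm]]
      if (nrow(fs) == 0) next
      hit <- IRanges::overlapsAny(pgr, as_granges(fs))
      category[hit & category == "intergenic"] <- nm
      # precedence: once labelled, a peak is never relabelled, so process
      # feature sets in precedence order and only fill "intergenic" slots
    }
  }
  out$category <- factor(category, levels = levels)
  out
}

#' Multi-set binary overlap of peak sets
#'
#' Partitions the merged union of 2-4 named peak sets by which inputs each
#' union interval intersects (>= 1 bp), returning the count per membership
#' combination — the numbers behind a peak-set Venn diagram.
#'
#' @param sets Named list (2-4 elements) of interval tibbles.
#' @return Tibble: one logical column per set, `combination` label, `count`.
#' @export
multiset_overlap <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4) abort("need 2-4 peak sets")
  nms <- names(sets)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("sets must have unique non-empty names")
  }
  union_peaks <- merge_peak_sets(sets)
  ugr <- as_granges(union_peaks)
  membership <- purrr::map(sets, function(s) {
    IRanges::overlapsAny(ugr, as_granges(s))
  })
  memb_df <- as_tibble(membership)
  memb_df$combination <- apply(memb_df, 1, function(r) {
    paste(nms[as.logical(r)], collapse = "&")
  })
  memb_df |>
    dplyr::count(dplyr::across(dplyr::all_of(c(nms, "combination"))),
                 name = "count") |>
    arrange(dplyr::desc(.data$count))
}
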