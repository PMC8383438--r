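#' Interval tibbles and their conversion to GRanges
#'
#' Peaks, GWAS windows and gene features are carried as plain tibbles with
#' `chrom`, `start`, `end` columns in the package-internal convention:
#' 0-based, half-open `[start, end)`, matching BED. These helpers validate
#' interval tibbles and convert to/from `GenomicRanges::GRanges` (1-based,
#' closed), which backs all overlap arithmetic.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return `as_granges()` returns a `GRanges`; `validate_intervals()` returns
#'   the input (invisibly) or aborts on the first malformed record.
#' @keywords internal
#' @noRd
validate_intervals <- function(x, what = "interval table") {
  if (!is.data.frame(x)) abort(paste0(what, " must be a data frame"))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!(x$end > x$start))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed interval (end <= start) at row %d: %s:%s-%s",
      bad[1], x$chrom[bad[1]], format(x$start[bad[1]], scientific = FALSE),
      format(x$end[bad[1]], scientific = FALSE)
    ))
  }
  if (any(x$start < 0)) {
    bad <- which(x$start < 0)[1]
    abort(sprintf("negative start at row %d", bad))
  }
  invisible(x)
}

as_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Canonical peak identifier
#'
#' Peak ids are `"chrom:start-end"` in 0-based half-open coordinates.
#'
#' @param x Interval tibble.
#' @return Character vector of ids.
#' @export
peak_id <- function(x) {
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
}

#' Parse canonical peak identifiers back into an interval tibble
#'
#' @param ids Character vector of `"chrom:start-end"` ids.
#' @return Tibble with `chrom`, `start`, `end`, `peak_id`.
#' @export
parse_peak_id <- function(ids) {
  m <- stringr::str_match(ids, "^(.+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(paste0("unparseable peak id: ", ids[which(is.na(m[, 1]))[1]]))
  }
  tibble(
    chrom = m[, 2],
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4]),
    peak_id = ids
  )
}

#' Merge peak sets into a disjoint union
#'
#' Takes any number of peak interval tables, pools them, and coalesces
#' overlapping or bookended (end == start) intervals, mirroring how per-sample
#' peak calls are re-merged into a comparison-specific peak universe.
#'
#' @param sets A single interval data frame or a list of them
#'   (`chrom`, `start`, `end`; 0-based half-open).
#' @return Tibble of disjoint intervals sorted by (chrom, start), with a
#'   `peak_id` column.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' merge_peak_sets(list(a, b)) # chr1:100-250
#' @export
merge_peak_sets <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  if (length(sets) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  peak_id = character()))
  }
  pooled <- bind_rows(lapply(sets, function(s) {
    validate_intervals(s, "peak set")
    tibble(chrom = as.character(s$chrom), start = s$start, end = s$end)
  }))
  if (nrow(pooled) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  peak_id = character()))
  }
  gr <- GenomicRanges::reduce(as_granges(pooled), min.gapwidth = 1L)
  out <- granges_to_tibble(GenomicRanges::sort(gr))
  out$peak_id <- peak_id(out)
  out
}

#' Drop sex-chromosome records
#'
#' Removes all rows on chrX/chrY (case-insensitive; with or without the
#' `"chr"` prefix, per the declared chromosome-naming dialect). Cohorts with
#' unequal numbers of female and male donors require this before testing.
#'
#' @param x Interval tibble with a `chrom` column, or a count matrix whose
#'   rownames are canonical peak ids.
#' @param dialect `"ucsc"` accepts both `"chrX"` and `"X"` spellings;
#'   `"ensembl"` only the bare names.
#' @return Filtered object of the same type.
#' @export
drop_sex_chromosomes <- function(x, dialect = c("ucsc", "ensembl")) {
  dialect <- match.arg(dialect)
  sex_names <- c("x", "y")
  is_sex <- function(chrom) {
    ch <- tolower(as.character(chrom))
    if (dialect == "ucsc") ch <- sub("^chr", "", ch)
    ch %in% sex_names
  }
  if (is.matrix(x)) {
    ids <- parse_peak_id(rownames(x))
    return(x[!is_sex(ids$chrom), , drop = FALSE])
  }
  validate_intervals(x)
  x[!is_sex(x$chrom), , drop = FALSE]
}
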