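# Readers and writers for the plain-text formats the pipeline exchanges.
# Internal convention everywhere: 0-based half-open intervals (BED);
# 1-based inclusive input is accepted via `coords = "1-based"` and shifted
# on the way in, and re-exported in its original convention on request.

#' Read a BED peak file
#'
#' @param path File path (3+ columns, tab-separated, no header).
#' @param coords `"0-based"` (BED, default) or `"1-based"` (inclusive;
#'   shifted internally).
#' @return Interval tibble with `peak_id`.
#' @export
read_bed <- function(path, coords = c("0-based", "1-based")) {
  coords <- match.arg(coords)
  lines <- readr::read_lines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  peak_id = character()))
  }
  parts <- stringr::str_split(lines, "\t")
  bad <- which(purrr::map_int(parts, length) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields", bad[1]))
  }
  out <- tibble(
    chrom = purrr::map_chr(parts, 1),
    start = suppressWarnings(as.integer(purrr::map_chr(parts, 2))),
    end = suppressWarnings(as.integer(purrr::map_chr(parts, 3)))
  )
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  }
  if (coords == "1-based") out$start <- out$start - 1L
  bad <- which(out$start < 0)
  if (length(bad) > 0) abort(sprintf("negative start at line %d", bad[1]))
  validate_intervals(out, "BED file")
  out$peak_id <- peak_id(out)
  out
}

#' Write peaks as 3-column BED
#'
#' @param peaks Interval tibble.
#' @param path Output path.
#' @param coords Coordinate convention to emit.
#' @return The path, invisibly.
#' @export
write_bed <- function(peaks, path, coords = c("0-based", "1-based")) {
  coords <- match.arg(coords)
  start <- if (coords == "1-based") peaks$start + 1L else peaks$start
  readr::write_tsv(
    tibble(chrom = peaks$chrom, start = as.integer(start),
           end = as.integer(peaks$end)),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a peak-by-sample count matrix from TSV
#'
#' Rows are canonical peak ids (`"chrom:start-end"`), columns sample ids;
#' the first column holds the peak id.
#'
#' @param path File path.
#' @return Integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  parse_peak_id(rownames(m))  # validates the ids
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix, rownames = peak ids.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- bind_cols(tibble(peak_id = rownames(counts)),
                  as_tibble(as.data.frame(counts)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write per-sample metadata CSV
#'
#' @param path File path.
#' @return Tibble (read) or the path invisibly (write).
#' @export
read_metadata_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_metadata_csv
#' @param metadata Tibble to write.
#' @export
write_metadata_csv <- function(metadata, path) {
  readr::write_csv(metadata, path)
  invisible(path)
}

#' Read / write GWAS tag-SNP region tables (TSV)
#'
#' Columns: `snp_id`, `chrom`, `pos`, `label`, and window bounds when
#' present.
#'
#' @param path File path.
#' @return Tibble (read) or the path invisibly (write).
#' @export
read_regions_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("snp_id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("regions file missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  df
}

#' @rdname read_regions_tsv
#' @param regions Tibble to write.
#' @export
write_regions_tsv <- function(regions, path) {
  readr::write_tsv(regions, path)
  invisible(path)
}
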