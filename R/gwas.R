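#' Build GWAS tag-SNP windows
#'
#' Expands each tag SNP to the window `[pos - flank, pos + flank]` on the
#' printed coordinate scale (no 0/1-based correction is applied to the
#' window arithmetic), clamping the lower bound at 0. The default flank of
#' 100 kb yields 200-kb regions.
#'
#' @param snps Tibble: `snp_id`, `chrom`, `pos`, optional `label` (gene).
#' @param flank Half-width in bp (default 1e5).
#' @return Tibble: input columns plus `window_start`, `window_end`.
#' @examples
#' build_gwas_windows(
#'   tibble::tibble(snp_id = "rs429358", chrom = "chr19", pos = 45411941)
#' )
#' @export
build_gwas_windows <- function(snps, flank = 1e5) {
  if (flank <= 0) abort("flank must be > 0")
  if (any(snps$pos < 0)) abort("SNP positions must be >= 0")
  out <- as_tibble(snps)
  if (!"label" %in% names(out)) out$label <- NA_character_
  out$window_start <- pmax(out$pos - flank, 0)
  out$window_end <- out$pos + flank
  out
}

#' Count differential sites overlapping GWAS windows
#'
#' A site counts when it intersects at least `min_overlap_bp` of a window
#' (`containment = TRUE` instead requires the site to lie fully inside).
#' Returns the number of distinct sites with any hit, the number of
#' distinct windows hit, and the full (site, window) pair list.
#'
#' @param diff_peaks Interval tibble of differential sites (0-based
#'   half-open `start`/`end`).
#' @param regions Window tibble from [build_gwas_windows()].
#' @param min_overlap_bp Minimum intersection (default 1).
#' @param containment Require full containment of the site (default FALSE).
#' @return List of class `atac_overlap`: `n_sites`, `n_regions`, `pairs`
#'   (tibble `peak_id`, `snp_id`, `label`).
#' @export
overlap_regions <- function(diff_peaks, regions, min_overlap_bp = 1,
                            containment = FALSE) {
  if (nrow(diff_peaks) == 0) {
    return(structure(list(n_sites = 0L, n_regions = 0L,
                          pairs = tibble(peak_id = character(),
                                         snp_id = character(),
                                         label = character())),
                     class = "atac_overlap"))
  }
  pk <- as_tibble(diff_peaks)
  if (!"peak_id" %in% names(pk)) pk$peak_id <- peak_id(pk)
  pgr <- as_granges(pk)
  rgr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$window_start + 1, regions$window_end)
  )
  hits <- GenomicRanges::findOverlaps(
    pgr, rgr,
    minoverlap = min_overlap_bp,
    type = if (containment) "within" else "any"
  )
  pairs <- tibble(
    peak_id = pk$peak_id[S4Vectors::queryHits(hits)],
    snp_id = regions$snp_id[S4Vectors::subjectHits(hits)],
    label = (regions$label %||% rep(NA_character_, nrow(regions)))[
      S4Vectors::subjectHits(hits)]
  )
  structure(
    list(
      n_sites = length(unique(pairs$peak_id)),
      n_regions = length(unique(pairs$snp_id)),
      pairs = pairs
    ),
    class = "atac_overlap"
  )
}

#' @export
print.atac_overlap <- function(x, ...) {
  cat(sprintf("%d site(s) overlapping %d GWAS region(s)\n",
              x$n_sites, x$n_regions))
  invisible(x)
}

#' Permutation enrichment of differential sites in GWAS windows
#'
#' Draws `n_diff` peaks uniformly without replacement from the peak
#' universe `n_perm` times, recomputes the overlap statistic for each draw,
#' and reports the add-one empirical p-value
#' `(1 + #{perm >= observed}) / (1 + n_perm)` (never exactly 0).
#'
#' @param diff_peaks Differential site tibble (its row count sets the draw
#'   size and its overlap the observed statistic).
#' @param universe Peak universe tibble (the merged peak calls the sites
#'   were selected from).
#' @param regions GWAS window tibble.
#' @param n_perm Number of permutations (default 10000).
#' @param statistic `"regions_hit"` (distinct windows hit) or
#'   `"sites_overlapping"` (distinct sites with a hit).
#' @param seed Integer seed.
#' @return List of class `atac_enrichment`: `observed_sites_overlapping`,
#'   `observed_regions_hit`, `statistic`, `n_perm`, `perm_counts`,
#'   `empirical_p`, `seed`.
#' @export
permutation_enrichment <- function(diff_peaks, universe, regions,
                                   n_perm = 10000,
                                   statistic = c("regions_hit",
                                                 "sites_overlapping"),
                                   seed = 1L) {
  statistic <- match.arg(statistic)
  n_diff <- nrow(diff_peaks)
  n_univ <- nrow(universe)
  if (n_diff > n_univ) abort("more differential sites than universe peaks")
  obs <- overlap_regions(diff_peaks, regions)
  observed <- if (statistic == "regions_hit") obs$n_regions else obs$n_sites

  if (nrow(regions) == 0 || n_diff == 0) {
    return(structure(
      list(observed_sites_overlapping = obs$n_sites,
           observed_regions_hit = obs$n_regions,
           statistic = statistic, n_perm = as.integer(n_perm),
           perm_counts = rep(0L, n_perm), empirical_p = 1.0,
           seed = as.integer(seed)),
      class = "atac_enrichment"
    ))
  }

  # precompute peak -> region membership over the universe once
  univ_hits <- overlap_regions(universe, regions)
  hit_idx <- match(univ_hits$pairs$peak_id, universe$peak_id)
  reg_idx <- match(univ_hits$pairs$snp_id, regions$snp_id)
  member <- matrix(FALSE, n_univ, nrow(regions))
  member[cbind(hit_idx, reg_idx)] <- TRUE
  any_hit <- rowSums(member) > 0

  perm_counts <- with_child_seed(seed, 7, {
    vapply(seq_len(n_perm), function(i) {
      draw <- sample.int(n_univ, n_diff)
      draw <- draw[any_hit[draw]]
      if (length(draw) == 0) return(0L)
      if (statistic == "sites_overlapping") {
        length(draw)
      } else {
        sum(colSums(member[draw, , drop = FALSE]) > 0)
      }
    }, integer(1))
  })
  structure(
    list(
      observed_sites_overlapping = obs$n_sites,
      observed_regions_hit = obs$n_regions,
      statistic = statistic,
      n_perm = as.integer(n_perm),
      perm_counts = perm_counts,
      empirical_p = (1 + sum(perm_counts >= observed)) / (1 + n_perm),
      seed = as.integer(seed)
    ),
    class = "atac_enrichment"
  )
}

#' @export
print.atac_enrichment <- function(x, ...) {
  obs <- if (x$statistic == "regions_hit") {
    x$observed_regions_hit
  } else {
    x$observed_sites_overlapping
  }
  cat(sprintf(
    "observed %s = %d; permutation mean %.2f (n = %d); empirical p = %.4g\n",
    x$statistic, obs, mean(x$perm_counts), x$n_perm, x$empirical_p))
  invisible(x)
}

#' @method tidy atac_enrichment
#' @export
tidy.atac_enrichment <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    observed = if (x$statistic == "regions_hit") x$observed_regions_hit
               else x$observed_sites_overlapping,
    perm_mean = mean(x$perm_counts),
    perm_sd = sd(x$perm_counts),
    n_perm = x$n_perm,
    empirical_p = x$empirical_p
  )
}

#' Histogram of the permutation null with the observed statistic
#'
#' @param object An `atac_enrichment` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot atac_enrichment
#' @export
autoplot.atac_enrichment <- function(object, ...) {
  obs <- if (object$statistic == "regions_hit") {
    object$observed_regions_hit
  } else {
    object$observed_sites_overlapping
  }
  df <- tibble(count = object$perm_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = obs, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = sprintf("permutation %s", object$statistic), y = "permutations",
      title = sprintf("empirical p = %.4g", object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}
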