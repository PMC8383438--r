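#' Specify a case-control comparison
#'
#' A design specification names the contrast (disease status within a
#' nuclei fraction, or neuronal vs non-neuronal), the stratum of samples it
#' runs on, whether donors are treated as a blocking factor (the paired
#' whole-cohort comparison), and the nominal group sizes it corresponds to
#' in the study design.
#'
#' @param contrast `"disease"` (case vs control) or `"cell_type"`
#'   (neuronal vs non-neuronal).
#' @param fraction Sample stratum: `"all"`, `"neuronal"`, `"non_neuronal"`.
#' @param sex Sample stratum: `"all"`, `"F"`, `"M"`.
#' @param paired_by_donor Add donor as an additive blocking factor.
#' @param include_unpaired Keep samples from donors without a matched pair
#'   (only the supplemented female non-neuronal comparison uses them).
#' @param nominal_n Optional `c(case, control)` group sizes recorded for the
#'   preset; realized sizes are checked with a warning, not an error.
#' @param label Preset name for reporting.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(contrast = c("disease", "cell_type"),
                        fraction = c("all", "neuronal", "non_neuronal"),
                        sex = c("all", "F", "M"),
                        paired_by_donor = FALSE,
                        include_unpaired = FALSE,
                        nominal_n = NULL,
                        label = "custom") {
  spec <- list(
    contrast = match.arg(contrast),
    fraction = match.arg(fraction),
    sex = match.arg(sex),
    paired_by_donor = paired_by_donor,
    include_unpaired = include_unpaired,
    nominal_n = nominal_n,
    label = label
  )
  class(spec) <- "design_spec"
  spec
}

#' Study-level comparison presets
#'
#' Encodes the study's comparison ladder: `L1` neuronal vs non-neuronal on
#' 40 matched donor pairs (donor-blocked); `L2_neuronal` / `L2_non_neuronal`
#' case vs control per fraction (19 vs 21); `L3A`-`L3D` the sex-stratified
#' case-control comparisons (females 11 vs 11, males 8 vs 10, per fraction);
#' `L3E` the supplemented female non-neuronal comparison including unpaired
#' donors (nominal 14 vs 13).
#'
#' @param name Preset name.
#' @return A [design_spec()].
#' @export
level_preset <- function(name = c("L1", "L2_neuronal", "L2_non_neuronal",
                                  "L3A", "L3B", "L3C", "L3D", "L3E")) {
  name <- match.arg(name)
  switch(name,
    L1 = design_spec("cell_type", "all", "all", paired_by_donor = TRUE,
                     nominal_n = c(40, 40), label = "L1"),
    L2_neuronal = design_spec("disease", "neuronal", "all",
                              nominal_n = c(19, 21), label = "L2_neuronal"),
    L2_non_neuronal = design_spec("disease", "non_neuronal", "all",
                                  nominal_n = c(19, 21),
                                  label = "L2_non_neuronal"),
    L3A = design_spec("disease", "non_neuronal", "F",
                      nominal_n = c(11, 11), label = "L3A"),
    L3B = design_spec("disease", "non_neuronal", "M",
                      nominal_n = c(8, 10), label = "L3B"),
    L3C = design_spec("disease", "neuronal", "F",
                      nominal_n = c(11, 11), label = "L3C"),
    L3D = design_spec("disease", "neuronal", "M",
                      nominal_n = c(8, 10), label = "L3D"),
    L3E = design_spec("disease", "non_neuronal", "F", include_unpaired = TRUE,
                      nominal_n = c(14, 13), label = "L3E")
  )
}

subset_samples <- function(metadata, spec) {
  md <- metadata
  if (spec$fraction != "all") md <- md[md$cell_fraction == spec$fraction, ]
  if (spec$sex != "all") md <- md[md$sex == spec$sex, ]
  if (!spec$include_unpaired) {
    # donors contributing both fractions define the paired cohort
    paired <- unique(metadata$donor_id[duplicated(metadata$donor_id)])
    md <- md[md$donor_id %in% paired, ]
  }
  md
}

#' Run one differential accessibility contrast
#'
#' The full per-comparison pipeline: subset samples to the stratum, drop
#' sex-chromosome peaks, remove low-abundance peaks (total count below
#' `min_total_count`), TMM-normalize, estimate dispersions, fit full and
#' reduced NB GLMs (full adds the group factor to the covariates, plus donor
#' when blocked), quasi-likelihood F-test, BH adjustment, direction labels
#' (`more_accessible_in_case` = positive case-vs-control log2FC; for the
#' cell-type contrast "case" is the neuronal fraction).
#'
#' @param counts Count matrix (peaks x samples; rownames are canonical peak
#'   ids `"chrom:start-end"`).
#' @param metadata Per-sample tibble (`sample_id`, `donor_id`,
#'   `cell_fraction`, `diagnosis`, `sex`, covariate columns).
#' @param spec A [design_spec()] or preset name for [level_preset()].
#' @param covariates Character vector of metadata columns to adjust for
#'   (typically the output of [run_selection()]).
#' @param min_total_count Abundance filter on the peak's total count.
#' @param prior_df Tagwise-dispersion prior df (see
#'   [estimate_dispersions()]).
#' @return Tibble of class `atac_deres`: `peak_id`, `chrom`, `start`, `end`,
#'   `log2FC`, `mean_logCPM`, `stat`, `p`, `q`, `direction`, ordered by `p`.
#' @export
run_contrast <- function(counts, metadata, spec, covariates = character(),
                         min_total_count = 10, prior_df = 10) {
  if (is.character(spec)) spec <- level_preset(spec)
  stopifnot(inherits(spec, "design_spec"))
  miss <- setdiff(covariates, colnames(metadata))
  if (length(miss) > 0) abort(paste0("covariate not in metadata: ", miss[1]))

  md <- subset_samples(metadata, spec)
  md <- md[md$sample_id %in% colnames(counts), , drop = FALSE]
  grp <- if (spec$contrast == "disease") {
    factor(ifelse(md$diagnosis == "control", "control", "case"),
           levels = c("control", "case"))
  } else {
    factor(md$cell_fraction, levels = c("non_neuronal", "neuronal"))
  }
  sizes <- table(grp)
  if (length(sizes) < 2 || any(sizes < 2)) abort("each group needs >= 2 samples")
  if (!is.null(spec$nominal_n) &&
        !all(sort(as.integer(sizes)) == sort(spec$nominal_n))) {
    warn(sprintf("realized group sizes (%s) differ from preset nominal (%s)",
                 paste(rev(as.integer(sizes)), collapse = " vs "),
                 paste(spec$nominal_n, collapse = " vs ")))
  }

  y <- counts[, md$sample_id, drop = FALSE]
  y <- drop_sex_chromosomes(y)
  y <- y[rowSums(y) >= min_total_count, , drop = FALSE]
  if (nrow(y) == 0) abort("no peaks left after filtering")

  norm <- tmm_factors(y)
  offsets <- log(norm$effective_library_size[match(md$sample_id,
                                                   norm$sample_id)])

  fml_terms <- c(covariates, if (spec$paired_by_donor) "donor_id")
  md_design <- md
  for (cv in fml_terms) {
    if (is.character(md_design[[cv]])) md_design[[cv]] <- factor(md_design[[cv]])
  }
  reduced_fml <- if (length(fml_terms) > 0) {
    stats::as.formula(paste("~", paste(fml_terms, collapse = " + ")))
  } else {
    ~1
  }
  X_reduced <- model.matrix(reduced_fml, data = md_design)
  X_full <- cbind(X_reduced, group = as.numeric(grp) - 1)
  if (qr(X_full)$rank < ncol(X_full)) {
    abort("design is confounded: group is collinear with the covariates")
  }

  disp <- estimate_dispersions(y, X_full, offsets, prior_df = prior_df)
  phi <- ifelse(is.na(disp$trended), disp$common, disp$trended)
  fit_full <- fit_nb_glm(y, X_full, offsets, phi = phi)
  fit_reduced <- fit_nb_glm(y, X_reduced, offsets, phi = phi)
  qlf <- ql_f_test(fit_full, fit_reduced)

  log2fc <- fit_full$coefficients[, ncol(X_full)] / log(2)
  coords <- parse_peak_id(rownames(y))
  out <- tibble(
    peak_id = rownames(y),
    chrom = coords$chrom,
    start = coords$start,
    end = coords$end,
    log2FC = log2fc,
    mean_logCPM = rowMeans(cpm_log(y, norm)),
    stat = qlf$stat,
    p = qlf$p,
    q = bh_adjust(qlf$p),
    direction = ifelse(log2fc > 0, "more_accessible_in_case",
                       "less_accessible_in_case")
  ) |>
    arrange(.data$p)
  structure(
    out,
    class = c("atac_deres", class(out)),
    spec = spec,
    covariates = covariates,
    group_sizes = as.integer(sizes),
    df_prior = attr(qlf, "df_prior"),
    dispersion_common = disp$common
  )
}

#' @method tidy atac_deres
#' @export
tidy.atac_deres <- function(x, ...) {
  as_tibble(x)
}

#' @method glance atac_deres
#' @export
glance.atac_deres <- function(x, fdr = 0.05, ...) {
  spec <- attr(x, "spec")
  tibble(
    label = spec$label,
    contrast = spec$contrast,
    fraction = spec$fraction,
    sex = spec$sex,
    n_peaks = nrow(x),
    n_significant = sum(x$q < fdr),
    n_more_accessible = sum(x$q < fdr & x$direction == "more_accessible_in_case"),
    n_less_accessible = sum(x$q < fdr & x$direction == "less_accessible_in_case"),
    dispersion_common = attr(x, "dispersion_common"),
    df_prior = attr(x, "df_prior")
  )
}

#' MA plot of a differential result
#'
#' @param object An `atac_deres` tibble.
#' @param fdr Significance threshold for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot atac_deres
#' @export
autoplot.atac_deres <- function(object, fdr = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$q < fdr
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_logCPM, y = .data$log2FC)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean log2 CPM", y = "log2 fold change",
                  colour = sprintf("q < %g", fdr)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
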