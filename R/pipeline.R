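#' Configure an end-to-end pipeline run
#'
#' A run either simulates its inputs (supply `sim`, a [sim_config()]) or
#' loads them from disk (supply `inputs`, a named list of paths: `peaks`
#' BED, `counts` TSV, `metadata` CSV, `regions` TSV). Thresholds default to
#' the study's settings: FDR 0.05, minimum 100 depth-normalized peak calls,
#' 100 kb GWAS flank, 10,000 permutations.
#'
#' @param preset Comparison preset name (see [level_preset()]) or a
#'   [design_spec()].
#' @param sim Optional [sim_config()].
#' @param inputs Optional named list of input paths.
#' @param fdr_q Significance threshold on BH q-values.
#' @param min_norm_peak_calls QC threshold on normalized peak calls.
#' @param flank GWAS window half-width (bp).
#' @param n_perm Permutations for the enrichment test.
#' @param select_covariates Run the iterative covariate selection and adjust
#'   for its picks (default TRUE).
#' @param candidate_names Metadata columns offered to the selection loop
#'   (default: the simulated technical covariates plus age and PMI, whichever
#'   are present).
#' @param seed Integer seed for every stochastic stage.
#' @param output_dir Directory for artifacts; `NULL` skips writing.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(preset = "L2_neuronal", sim = NULL, inputs = NULL,
                            fdr_q = 0.05, min_norm_peak_calls = 100,
                            flank = 1e5, n_perm = 10000,
                            select_covariates = TRUE,
                            candidate_names = NULL,
                            seed = 1L, output_dir = NULL) {
  if (is.null(sim) && is.null(inputs)) {
    abort("supply either a simulation config or input paths")
  }
  structure(
    list(preset = preset, sim = sim, inputs = inputs, fdr_q = fdr_q,
         min_norm_peak_calls = min_norm_peak_calls, flank = flank,
         n_perm = n_perm, select_covariates = select_covariates,
         candidate_names = candidate_names, seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

stage_record <- function(name, n_in, n_out, note = NA_character_) {
  tibble(stage = name, n_in = n_in, n_out = n_out, note = note)
}

#' Run the full differential accessibility pipeline
#'
#' Stages, in order: acquire inputs (simulate or load); QC filter on
#' normalized peak calls and replicate resolution; PCA/Ward outlier
#' removal; metadata imputation; iterative covariate selection on the
#' comparison's sample subset; NB quasi-likelihood differential testing
#' (sex chromosomes excluded, TMM normalization); permutation enrichment of
#' significant sites in GWAS windows. Identical config + seed reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `atac_manifest`: per-stage records, the
#'   differential result, the enrichment result, selected covariates, file
#'   checksums (when `output_dir` is set), and the seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- if (is.character(config$preset)) {
    level_preset(config$preset)
  } else {
    config$preset
  }
  stages <- list()

  if (!is.null(config$sim)) {
    cfg <- config$sim
    peaks <- simulate_peak_universe(cfg)
    metadata <- simulate_metadata(cfg)
    sim <- simulate_counts(cfg, peaks, metadata)
    counts <- sim$counts
    truth_ids <- sim$truth$differential$disease_glial_female
    regions <- plant_gwas_regions(cfg, peaks, truth_ids)
    truth <- sim$truth
  } else {
    peaks <- read_bed(config$inputs$peaks)
    counts <- read_counts_tsv(config$inputs$counts)
    metadata <- read_metadata_csv(config$inputs$metadata)
    regions <- build_gwas_windows(read_regions_tsv(config$inputs$regions),
                                  flank = config$flank)
    truth <- NULL
  }
  stages[[length(stages) + 1]] <-
    stage_record("acquire", NA_integer_, ncol(counts),
                 sprintf("%d peaks", nrow(peaks)))

  # --- QC: normalized peak calls + replicate resolution -------------------
  if ("normalized_peak_calls" %in% names(metadata)) {
    qc <- filter_samples(metadata, config$min_norm_peak_calls)
    kept <- qc$sample_id[qc$kept]
  } else {
    kept <- metadata$sample_id
  }
  stages[[length(stages) + 1]] <-
    stage_record("qc_filter", nrow(metadata), length(kept))
  metadata <- metadata[metadata$sample_id %in% kept, , drop = FALSE]
  counts <- counts[, metadata$sample_id, drop = FALSE]

  # --- outlier removal ----------------------------------------------------
  logcpm <- cpm_log(counts)
  flagged <- detect_outlier_samples(logcpm)
  if (length(flagged) > 0) {
    metadata <- metadata[!metadata$sample_id %in% flagged, , drop = FALSE]
    counts <- counts[, metadata$sample_id, drop = FALSE]
  }
  stages[[length(stages) + 1]] <-
    stage_record("outlier_removal", length(kept), ncol(counts),
                 if (length(flagged)) paste(flagged, collapse = ",")
                 else NA_character_)

  metadata <- impute_missing(metadata)

  # --- covariate selection on the comparison's samples --------------------
  selected <- character(0)
  if (config$select_covariates) {
    md_sub <- subset_samples(metadata, spec)
    md_sub <- md_sub[md_sub$sample_id %in% colnames(counts), , drop = FALSE]
    y_sub <- counts[, md_sub$sample_id, drop = FALSE]
    y_sub <- drop_sex_chromosomes(y_sub)
    y_sub <- y_sub[rowSums(y_sub) >= 10, , drop = FALSE]
    cand_names <- config$candidate_names %||% intersect(
      c("sort_date", "nrf", "alignment_pct", "nuclei_count", "gc_pct",
        "normalized_peak_calls", "age", "pmi"),
      colnames(metadata)
    )
    n_pcs <- min(10, nrow(md_sub) - 2)
    if (length(cand_names) > 0 && n_pcs >= 2) {
      cands <- covariate_candidates(md_sub, cand_names)
      sel <- run_selection(cpm_log(y_sub, tmm_factors(y_sub)), md_sub, cands,
                           n_pcs = n_pcs)
      selected <- sel$selected
    }
  }
  stages[[length(stages) + 1]] <-
    stage_record("covariate_selection", NA_integer_, length(selected),
                 if (length(selected)) paste(selected, collapse = ",")
                 else "none")

  # --- differential testing ----------------------------------------------
  res <- run_contrast(counts, metadata, spec, covariates = selected)
  n_sig <- sum(res$q < config$fdr_q)
  stages[[length(stages) + 1]] <-
    stage_record("differential", nrow(res), n_sig,
                 sprintf("q<%g", config$fdr_q))

  # --- GWAS enrichment ----------------------------------------------------
  universe <- parse_peak_id(res$peak_id)
  sig <- res[res$q < config$fdr_q, , drop = FALSE]
  enrich <- permutation_enrichment(sig, universe, regions,
                                   n_perm = config$n_perm,
                                   seed = config$seed)
  stages[[length(stages) + 1]] <-
    stage_record("enrichment", nrow(sig), enrich$observed_regions_hit,
                 sprintf("p=%.4g", enrich$empirical_p))

  manifest <- structure(
    list(
      stages = bind_rows(stages),
      result = res,
      enrichment = enrich,
      selected_covariates = selected,
      truth = truth,
      config_hash = digest::digest(config[setdiff(names(config),
                                                  "output_dir")]),
      seed = config$seed,
      files = NULL
    ),
    class = "atac_manifest"
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      results = file.path(config$output_dir, "differential_results.tsv"),
      up_bed = file.path(config$output_dir, "significant_up.bed"),
      down_bed = file.path(config$output_dir, "significant_down.bed"),
      enrichment = file.path(config$output_dir, "enrichment.json"),
      manifest = file.path(config$output_dir, "manifest.json")
    )
    readr::write_tsv(as_tibble(res), paths[["results"]])
    write_bed(sig[sig$direction == "more_accessible_in_case", ],
              paths[["up_bed"]])
    write_bed(sig[sig$direction == "less_accessible_in_case", ],
              paths[["down_bed"]])
    jsonlite::write_json(
      list(statistic = enrich$statistic,
           observed_regions_hit = enrich$observed_regions_hit,
           observed_sites_overlapping = enrich$observed_sites_overlapping,
           empirical_p = enrich$empirical_p, n_perm = enrich$n_perm,
           histogram = as.list(table(enrich$perm_counts))),
      paths[["enrichment"]], auto_unbox = TRUE, digits = NA
    )
    files <- tibble(
      name = names(paths)[1:4],
      path = unname(paths[1:4]),
      checksum = purrr::map_chr(unname(paths[1:4]), digest::digest,
                                file = TRUE)
    )
    manifest$files <- files
    jsonlite::write_json(
      list(config_hash = manifest$config_hash, seed = config$seed,
           stages = manifest$stages, files = files,
           selected_covariates = selected),
      paths[["manifest"]], auto_unbox = TRUE, digits = NA
    )
  }
  manifest
}

#' @export
print.atac_manifest <- function(x, ...) {
  cat("differential accessibility pipeline run (seed", x$seed, ")\n")
  print(x$stages)
  invisible(x)
}

#' @method glance atac_manifest
#' @export
glance.atac_manifest <- function(x, ...) {
  g <- glance(x$result)
  g$enrichment_p <- x$enrichment$empirical_p
  g$selected_covariates <- paste(x$selected_covariates, collapse = ",")
  g
}
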