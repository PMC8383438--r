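#' Evaluate an expression under a deterministic child random stream
#'
#' All generator randomness flows from one user-supplied seed; each component
#' draws from its own child stream so partial re-runs stay reproducible.
#' @noRd
with_child_seed <- function(seed, stream, expr) {
  child <- (as.double(seed) * 1009 + stream * 9176) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(child))
  force(expr)
}

#' Default sorted-nuclei cohort design
#'
#' Builds the per-sample design emulating a paired FANS cohort: 40 donors each
#' contributing one neuronal and one non-neuronal sample (21 controls: 11 F /
#' 10 M; 16 mild cases: 11 F with 3 severe included below / 8 M total cases),
#' plus 9 unpaired non-neuronal female samples (3 control, 6 mild). Case sex
#' balance follows the sex-stratified comparison sizes (11 F vs 11 F, 8 M vs
#' 10 M per fraction).
#'
#' @param n_unpaired_glia Number of extra unpaired female non-neuronal
#'   samples (default 9: 3 control, 6 mild).
#' @return Tibble with one row per sample: `sample_id`, `donor_id`,
#'   `cell_fraction`, `diagnosis`, `sex`.
#' @export
cohort_design <- function(n_unpaired_glia = 9) {
  donors <- tibble(
    donor_id = sprintf("D%02d", 1:40),
    diagnosis = c(rep("control", 21), rep("mild_LOAD", 16), rep("severe_LOAD", 3)),
    sex = c(
      rep(c("F", "M"), c(11, 10)),      # 21 controls
      rep(c("F", "M"), c(10, 6)),       # 16 mild
      c("F", "M", "M")                  # 3 severe -> cases: 11 F, 8 M
    )
  )
  paired <- tidyr::crossing(donors, cell_fraction = c("neuronal", "non_neuronal"))
  n_extra_ctrl <- round(n_unpaired_glia / 3)  # 9 unpaired -> 3 control, 6 mild
  extra <- tibble(
    donor_id = sprintf("U%02d", seq_len(n_unpaired_glia)),
    diagnosis = rep(c("control", "mild_LOAD"),
                    c(n_extra_ctrl, n_unpaired_glia - n_extra_ctrl)),
    sex = "F",
    cell_fraction = "non_neuronal"
  )
  design <- bind_rows(paired, extra)
  design$sample_id <- sprintf(
    "%s_%s", design$donor_id,
    ifelse(design$cell_fraction == "neuronal", "NeuNpos", "NeuNneg")
  )
  design[, c("sample_id", "donor_id", "cell_fraction", "diagnosis", "sex")]
}

#' Default technical-covariate specification
#'
#' Six technical variables generated as `center + scale * (loading * latent +
#' noise_sd * e)`, `e ~ N(0,1)`. The shared latent factor is later injected
#' into the counts, so nonzero loadings create genuine confounding between
#' these covariates and the leading count principal components.
#'
#' @param loading Common loading applied to every variable (overridable per
#'   row afterwards).
#' @return Tibble with columns `name`, `kind`, `n_levels`, `loading`,
#'   `noise_sd`, `center`, `scale`.
#' @export
default_confounders <- function(loading = 0.6) {
  tibble(
    name = c("sort_date", "nrf", "alignment_pct", "nuclei_count",
             "gc_pct", "normalized_peak_calls"),
    kind = c("categorical", rep("continuous", 5)),
    n_levels = c(5L, 1L, 1L, 1L, 1L, 1L),
    loading = loading,
    noise_sd = 0.6,
    center = c(NA, 0.82, 95, 3e5, 45, 400),
    scale = c(NA, 0.05, 2, 8e4, 2, 120)
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' study conditions: a paired 89-sample cohort, negative-binomial counts with
#' cell-type main effects, disease effects in neuronal samples of both sexes,
#' disease effects in non-neuronal samples of females only (attenuated in
#' males), technical covariates confounded with a latent factor that also
#' drives counts, and GWAS tag-SNP windows that can be planted over
#' differential peaks.
#'
#' @param n_peaks Number of peaks in the simulated universe.
#' @param chrom_sizes Named vector of chromosome lengths in bp; must include
#'   `chrX` and `chrY` so sex-chromosome exclusion is exercised.
#' @param design Tibble of samples (see [cohort_design()]).
#' @param baseline_log_mean_range Range (natural-log scale) of per-peak
#'   baseline relative abundances.
#' @param dispersion_model List `(phi0, decay)`; peak dispersion is
#'   `phi0 + decay / mean`.
#' @param n_cell_type_peaks,cell_type_lfc_range Number of peaks carrying a
#'   neuronal-vs-non-neuronal effect and the |log2FC| range they are drawn
#'   from (sign random).
#' @param n_disease_neuronal_peaks,n_disease_glial_female_peaks Numbers of
#'   peaks carrying disease effects in the neuronal fraction (both sexes) and
#'   in the non-neuronal fraction (females; attenuated in males).
#' @param disease_lfc_range |log2FC| range for disease effects.
#' @param male_glia_attenuation Multiplier applied to non-neuronal disease
#'   effects in male samples (0.3: same direction, weaker, typically below
#'   detection at cohort size).
#' @param confounders Technical covariate spec (see [default_confounders()]).
#' @param confounder_peak_fraction,confounder_peak_sd Fraction of peaks whose
#'   abundance responds to the latent factor, and the SD (log2 scale) of their
#'   response loadings.
#' @param library_size List `(meanlog, cv)` of the log-normal library-size
#'   distribution. The default mean 1e5 keeps desk-scale runs fast; deep
#'   cohorts would use 2e7.
#' @param n_gwas_regions,flank,planted_fraction Enrichment scenario: number of
#'   tag-SNP windows, half-width in bp, and the fraction of differential peaks
#'   forced inside windows.
#' @param n_missing_pmi Number of donors whose PMI is set missing.
#' @param peak_length List `(meanlog, sdlog, min, max)` of the truncated
#'   log-normal peak-width distribution (median 500 bp).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_peaks = 5000,
                       chrom_sizes = c(chr1 = 2.4e8, chr2 = 2.4e8, chr3 = 2e8,
                                       chr8 = 1.4e8, chr19 = 6e7,
                                       chrX = 1.5e8, chrY = 5e7),
                       design = cohort_design(),
                       baseline_log_mean_range = c(-2.5, 2.5),
                       dispersion_model = list(phi0 = 0.2, decay = 0),
                       n_cell_type_peaks = round(0.15 * n_peaks),
                       cell_type_lfc_range = c(1, 3),
                       n_disease_neuronal_peaks = round(0.02 * n_peaks),
                       n_disease_glial_female_peaks = round(0.04 * n_peaks),
                       disease_lfc_range = c(0.5, 2),
                       male_glia_attenuation = 0.3,
                       confounders = default_confounders(),
                       confounder_peak_fraction = 0.2,
                       confounder_peak_sd = 0.25,
                       library_size = list(meanlog = log(1e5), cv = 0.3),
                       n_gwas_regions = 25,
                       flank = 1e5,
                       planted_fraction = 0,
                       n_missing_pmi = 2,
                       peak_length = list(meanlog = log(500), sdlog = 0.5,
                                          min = 100, max = 5000),
                       seed = 1L) {
  cfg <- list(
    n_peaks = as.integer(n_peaks), chrom_sizes = chrom_sizes, design = design,
    baseline_log_mean_range = baseline_log_mean_range,
    dispersion_model = dispersion_model,
    n_cell_type_peaks = n_cell_type_peaks,
    cell_type_lfc_range = cell_type_lfc_range,
    n_disease_neuronal_peaks = n_disease_neuronal_peaks,
    n_disease_glial_female_peaks = n_disease_glial_female_peaks,
    disease_lfc_range = disease_lfc_range,
    male_glia_attenuation = male_glia_attenuation,
    confounders = confounders,
    confounder_peak_fraction = confounder_peak_fraction,
    confounder_peak_sd = confounder_peak_sd,
    library_size = library_size,
    n_gwas_regions = as.integer(n_gwas_regions), flank = flank,
    planted_fraction = planted_fraction,
    n_missing_pmi = as.integer(n_missing_pmi),
    peak_length = peak_length,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_peaks < 0) abort("n_peaks must be >= 0")
  if (!all(c("chrX", "chrY") %in% names(cfg$chrom_sizes))) {
    abort("chrom_sizes must include chrX and chrY")
  }
  if (any(cfg$chrom_sizes <= 0)) abort("chromosome sizes must be positive")
  if (cfg$dispersion_model$phi0 <= 0) abort("phi0 must be > 0")
  if (cfg$dispersion_model$decay < 0) abort("dispersion decay must be >= 0")
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1) {
    abort("planted_fraction must lie in [0, 1]")
  }
  dup <- duplicated(cfg$design[, c("donor_id", "cell_fraction")])
  if (any(dup)) {
    abort(sprintf("duplicate (donor, cell_fraction): %s/%s",
                  cfg$design$donor_id[dup][1], cfg$design$cell_fraction[dup][1]))
  }
  invisible(cfg)
}

#' Simulate a disjoint peak universe
#'
#' Draws peak widths from a truncated log-normal (median ~500 bp) and places
#' them without overlap across the configured chromosomes, allocating peak
#' counts proportionally to chromosome length. Placement uses the uniform
#' spacing construction: free space is split by sorted uniform draws so any
#' disjoint arrangement is equally likely.
#'
#' @param cfg A [sim_config()].
#' @return Interval tibble (`chrom`, `start`, `end`, `peak_id`), sorted,
#'   disjoint.
#' @export
simulate_peak_universe <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_peaks == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  peak_id = character()))
  }
  with_child_seed(cfg$seed, 1, {
    sizes <- cfg$chrom_sizes
    alloc <- as.vector(stats::rmultinom(1, cfg$n_peaks, sizes / sum(sizes)))
    names(alloc) <- names(sizes)
    pl <- cfg$peak_length
    out <- purrr::map(names(sizes), function(ch) {
      k <- alloc[[ch]]
      if (k == 0) return(NULL)
      len <- pmin(pmax(round(rlnorm(k, pl$meanlog, pl$sdlog)), pl$min), pl$max)
      slack <- sizes[[ch]] - sum(len) - k  # >=1 bp gap between peaks
      if (slack < 0) {
        abort(sprintf("chromosome %s too small for %d peaks", ch, k))
      }
      gaps <- diff(c(0, sort(runif(k, 0, slack))))
      start <- cumsum(gaps + 1) + cumsum(c(0, len[-k])) - 1
      tibble(chrom = ch, start = as.integer(round(start)),
             end = as.integer(round(start) + len))
    })
    out <- bind_rows(out) |>
      arrange(.data$chrom, .data$start)
    out$peak_id <- peak_id(out)
    out
  })
}

#' Simulate per-sample metadata with confounded technical covariates
#'
#' Each sample receives a latent factor score `z ~ N(0,1)`; technical
#' covariates are `center + scale*(loading*z + noise_sd*e)`. Because the same
#' `z` is injected into the counts by [simulate_counts()], covariates with
#' nonzero loadings genuinely associate with the count principal components.
#' Neuronal fraction percentages are drawn per diagnosis group (means 35.27 /
#' 38.59 / 19.16, SD 13.26 / 14.70 / 7.49 for control / mild / severe),
#' truncated to [0, 100]; severe cases therefore get markedly lower values.
#' Age and PMI are drawn per group; `n_missing_pmi` donors get missing PMI.
#'
#' @param cfg A [sim_config()].
#' @return Tibble: design columns plus `age`, `pmi`, `neuronal_fraction_pct`,
#'   one column per technical covariate, and `latent` (the factor score;
#'   ground truth, dropped before analysis).
#' @export
simulate_metadata <- function(cfg) {
  validate_sim_config(cfg)
  design <- cfg$design
  if (nrow(design) == 0) abort("design is empty")
  with_child_seed(cfg$seed, 2, {
    n <- nrow(design)
    md <- as_tibble(design)
    md$latent <- rnorm(n)

    grp <- match(md$diagnosis, c("control", "mild_LOAD", "severe_LOAD"))
    nf_mean <- c(35.27, 38.59, 19.16)[grp]
    nf_sd <- c(13.26, 14.70, 7.49)[grp]
    md$neuronal_fraction_pct <- pmin(pmax(rnorm(n, nf_mean, nf_sd), 0), 100)

    age_mean <- c(81.10, 79.75, 76.67)[grp]
    age_sd <- c(9.70, 7.23, 7.77)[grp]
    pmi_mean <- c(7.91, 7.09, 5.43)[grp]
    pmi_sd <- c(5.54, 5.58, 1.65)[grp]
    donor_tab <- md |>
      distinct(.data$donor_id, .keep_all = TRUE)
    donor_age <- setNames(
      rnorm(nrow(donor_tab),
            age_mean[match(donor_tab$donor_id, md$donor_id)],
            age_sd[match(donor_tab$donor_id, md$donor_id)]),
      donor_tab$donor_id
    )
    donor_pmi <- setNames(
      pmax(rnorm(nrow(donor_tab),
                 pmi_mean[match(donor_tab$donor_id, md$donor_id)],
                 pmi_sd[match(donor_tab$donor_id, md$donor_id)]), 0.5),
      donor_tab$donor_id
    )
    md$age <- round(donor_age[md$donor_id], 1)
    md$pmi <- round(donor_pmi[md$donor_id], 2)
    if (cfg$n_missing_pmi > 0) {
      miss <- sample(names(donor_age), min(cfg$n_missing_pmi, length(donor_age)))
      md$pmi[md$donor_id %in% miss] <- NA_real_
    }

    for (i in seq_len(nrow(cfg$confounders))) {
      cv <- cfg$confounders[i, ]
      raw <- cv$loading * md$latent + cv$noise_sd * rnorm(n)
      if (cv$kind == "categorical") {
        br <- quantile(raw, probs = seq(0, 1, length.out = cv$n_levels + 1))
        br[1] <- -Inf; br[length(br)] <- Inf
        md[[cv$name]] <- factor(
          paste0("batch", as.integer(cut(raw, unique(br), include.lowest = TRUE)))
        )
      } else {
        md[[cv$name]] <- cv$center + cv$scale * raw
      }
    }
    if ("nrf" %in% names(md)) md$nrf <- pmin(pmax(md$nrf, 0.01), 1)
    if ("alignment_pct" %in% names(md)) {
      md$alignment_pct <- pmin(pmax(md$alignment_pct, 1), 100)
    }
    if ("nuclei_count" %in% names(md)) {
      md$nuclei_count <- pmax(round(md$nuclei_count), 1e4)
    }
    if ("normalized_peak_calls" %in% names(md)) {
      md$normalized_peak_calls <- pmax(md$normalized_peak_calls, 1)
    }
    md
  })
}

draw_effect_table <- function(peak_ids, n_effect, lfc_range) {
  n_effect <- min(n_effect, length(peak_ids))
  if (n_effect == 0) {
    return(tibble(peak_id = character(), lfc = numeric()))
  }
  idx <- sample(length(peak_ids), n_effect)
  tibble(
    peak_id = peak_ids[idx],
    lfc = sample(c(-1, 1), n_effect, replace = TRUE) *
      runif(n_effect, lfc_range[1], lfc_range[2])
  )
}

#' Simulate a negative-binomial count matrix with planted ground truth
#'
#' Counts follow `y_ij ~ NB(mu_ij, phi_i)` with
#' `log mu_ij = log s_j + b_i0 + log(2) * (cell + disease + latent) terms`,
#' where `s_j` scales each column so its expected sum equals the sampled
#' library size. Disease effects obey the headline structure: neuronal peaks
#' respond in both sexes; non-neuronal ("glial") peaks respond fully in
#' females and attenuated (factor `male_glia_attenuation`) in males.
#'
#' @param cfg A [sim_config()].
#' @param peaks Peak universe from [simulate_peak_universe()].
#' @param metadata Metadata from [simulate_metadata()] (needs `latent`).
#' @param effects Optional externally supplied effect tables (list with
#'   elements `cell_type`, `disease_neuronal`, `disease_glial_female`, each a
#'   tibble `peak_id`, `lfc` in log2 units). Peak ids must exist in `peaks`.
#' @return List of class `atac_sim`: `counts` (integer matrix, peaks x
#'   samples), `truth` (effect tables, latent scores, library sizes).
#' @export
simulate_counts <- function(cfg, peaks, metadata, effects = NULL) {
  validate_sim_config(cfg)
  if (!all(c("sample_id", "cell_fraction", "diagnosis", "sex", "latent") %in%
             names(metadata))) {
    abort("metadata must carry sample_id, cell_fraction, diagnosis, sex, latent")
  }
  G <- nrow(peaks); n <- nrow(metadata)
  with_child_seed(cfg$seed, 3, {
    if (is.null(effects)) {
      effects <- list(
        cell_type = draw_effect_table(peaks$peak_id, cfg$n_cell_type_peaks,
                                      cfg$cell_type_lfc_range),
        disease_neuronal = draw_effect_table(
          peaks$peak_id, cfg$n_disease_neuronal_peaks, cfg$disease_lfc_range),
        disease_glial_female = draw_effect_table(
          peaks$peak_id, cfg$n_disease_glial_female_peaks, cfg$disease_lfc_range)
      )
    }
    for (tab in effects) {
      bad <- setdiff(tab$peak_id, peaks$peak_id)
      if (length(bad) > 0) {
        abort(paste0("effect table indexes unknown peak: ", bad[1]))
      }
    }
    lfc_vec <- function(tab) {
      v <- numeric(G)
      v[match(tab$peak_id, peaks$peak_id)] <- tab$lfc
      v
    }
    b0 <- runif(G, cfg$baseline_log_mean_range[1], cfg$baseline_log_mean_range[2])
    ct <- lfc_vec(effects$cell_type)
    dn <- lfc_vec(effects$disease_neuronal)
    dg <- lfc_vec(effects$disease_glial_female)
    gamma <- numeric(G)
    n_conf <- round(cfg$confounder_peak_fraction * G)
    if (n_conf > 0) {
      gamma[sample(G, n_conf)] <- rnorm(n_conf, 0, cfg$confounder_peak_sd)
    }

    is_neu <- metadata$cell_fraction == "neuronal"
    is_case <- metadata$diagnosis != "control"
    is_f <- metadata$sex == "F"
    glia_w <- ifelse(is_f, 1, cfg$male_glia_attenuation)

    # G x n log2-scale effect matrix
    eff <- outer(ct, as.numeric(is_neu)) +
      outer(dn, as.numeric(is_neu & is_case)) +
      outer(dg, as.numeric(!is_neu & is_case) * glia_w) +
      outer(gamma, metadata$latent)
    w <- exp(b0 + log(2) * eff)  # relative rates

    lib <- rlnorm(n, cfg$library_size$meanlog,
                  sqrt(log(1 + cfg$library_size$cv^2)))
    mu <- sweep(w, 2, lib / colSums(w), "*")
    mu_bar <- rowMeans(mu)
    phi <- cfg$dispersion_model$phi0 +
      cfg$dispersion_model$decay / pmax(mu_bar, 1e-8)
    counts <- matrix(
      rnbinom(G * n, mu = as.vector(mu), size = rep(1 / phi, n)),
      nrow = G, dimnames = list(peaks$peak_id, metadata$sample_id)
    )
    storage.mode(counts) <- "integer"
    truth <- list(
      effects = effects,
      differential = list(
        cell_type = effects$cell_type$peak_id,
        disease_neuronal = effects$disease_neuronal$peak_id,
        disease_glial_female = effects$disease_glial_female$peak_id
      ),
      baseline_log_mean = b0,
      confounder_loadings = gamma,
      latent = setNames(metadata$latent, metadata$sample_id),
      library_sizes = setNames(lib, metadata$sample_id),
      dispersion = phi
    )
    structure(list(counts = counts, truth = truth), class = "atac_sim")
  })
}

#' Simulate a read-position multiset with controlled duplication
#'
#' Produces abstract genomic positions (integers) whose distinct/total ratio
#' is `distinct_fraction` up to rounding, or whose counts-per-position
#' histogram matches `duplication_profile` exactly. Feeds the library
#' complexity metrics (NRF/PBC1/PBC2).
#'
#' @param depth Total number of reads.
#' @param distinct_fraction Target fraction of distinct positions (ignored
#'   when `duplication_profile` given).
#' @param duplication_profile Optional named vector: multiplicity ->
#'   number of positions with that multiplicity; must sum to `depth`.
#' @param seed Integer seed.
#' @return Integer vector of positions (length `depth`), shuffled.
#' @export
simulate_read_positions <- function(depth, distinct_fraction = 1,
                                    duplication_profile = NULL, seed = 1L) {
  if (depth < 0) abort("depth must be >= 0")
  if (depth == 0) return(integer(0))
  with_child_seed(seed, 4, {
    if (!is.null(duplication_profile)) {
      mult <- as.integer(names(duplication_profile))
      npos <- as.integer(duplication_profile)
      if (any(is.na(mult)) || any(mult < 1) || any(npos < 0)) {
        abort("duplication_profile must map multiplicity >= 1 to counts >= 0")
      }
      if (sum(mult * npos) != depth) {
        abort(sprintf("infeasible profile: reads sum to %d, depth is %d",
                      sum(mult * npos), depth))
      }
      pos <- rep(seq_len(sum(npos)), rep.int(mult, npos))
    } else {
      if (distinct_fraction <= 0 || distinct_fraction > 1) {
        abort("distinct_fraction must lie in (0, 1]")
      }
      n_distinct <- max(1L, round(depth * distinct_fraction))
      extra <- depth - n_distinct
      pos <- seq_len(n_distinct)
      if (extra > 0) {
        pos <- c(pos, sample(seq_len(n_distinct), extra, replace = TRUE))
      }
    }
    offset <- sample.int(1e6, 1)
    sample(pos + offset)
  })
}

#' Plant GWAS tag-SNP regions relative to differential peaks
#'
#' Places `n_gwas_regions` tag SNPs. A `planted_fraction` of the supplied
#' differential peaks get a window centred on them (SNP at the peak
#' midpoint); remaining SNPs are placed so their windows avoid every
#' differential peak. This gives exact control of the observed overlap for
#' calibration of the permutation test.
#'
#' @param cfg A [sim_config()] (supplies `n_gwas_regions`, `flank`,
#'   `planted_fraction`, `chrom_sizes`, `seed`).
#' @param peaks Peak universe tibble.
#' @param diff_peak_ids Character vector of differential peak ids (ground
#'   truth for one contrast).
#' @return Tibble: `snp_id`, `chrom`, `pos`, `label` plus window bounds
#'   `window_start`, `window_end`.
#' @export
plant_gwas_regions <- function(cfg, peaks, diff_peak_ids) {
  validate_sim_config(cfg)
  if (cfg$flank <= 0) abort("flank must be > 0")
  n_reg <- cfg$n_gwas_regions
  n_plant <- round(cfg$planted_fraction * length(diff_peak_ids))
  if (n_plant > n_reg) {
    abort(sprintf("planted_fraction requires %d windows but only %d available",
                  n_plant, n_reg))
  }
  with_child_seed(cfg$seed, 5, {
    dp <- peaks[match(diff_peak_ids, peaks$peak_id), , drop = FALSE]
    planted <- dp[sample(nrow(dp), n_plant), , drop = FALSE]
    snp <- tibble(
      chrom = planted$chrom,
      pos = as.integer(round((planted$start + planted$end) / 2))
    )
    n_rest <- n_reg - n_plant
    if (n_rest > 0) {
      chroms <- names(cfg$chrom_sizes)
      got <- 0L; acc <- list()
      dgr <- if (nrow(dp) > 0) as_granges(dp) else NULL
      tries <- 0L
      while (got < n_rest && tries < 200L) {
        tries <- tries + 1L
        k <- (n_rest - got) * 2L
        ch <- sample(chroms, k, replace = TRUE,
                     prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
        pos <- as.integer(round(runif(k, cfg$flank,
                                      cfg$chrom_sizes[ch] - cfg$flank)))
        cand <- tibble(chrom = ch, pos = pos)
        if (!is.null(dgr) && nrow(dp) > 0) {
          win <- GenomicRanges::GRanges(
            cand$chrom,
            IRanges::IRanges(pmax(cand$pos - cfg$flank, 0) + 1,
                             cand$pos + cfg$flank)
          )
          hit <- IRanges::overlapsAny(win, dgr)
          cand <- cand[!hit, , drop = FALSE]
        }
        if (nrow(cand) > 0) {
          take <- head(cand, n_rest - got)
          acc[[length(acc) + 1]] <- take
          got <- got + nrow(take)
        }
      }
      if (got < n_rest) abort("could not place null GWAS windows away from differential peaks")
      snp <- bind_rows(snp, bind_rows(acc))
    }
    snp$snp_id <- sprintf("rsSIM%04d", seq_len(nrow(snp)))
    snp$label <- sprintf("LOCUS%02d", seq_len(nrow(snp)))
    build_gwas_windows(snp[, c("snp_id", "chrom", "pos", "label")],
                       flank = cfg$flank)
  })
}

#' Write every simulated artifact to disk
#'
#' Emits the generator outputs in the plain-text formats the pipeline reads:
#' peaks as BED, counts as TSV, metadata as CSV, GWAS regions as TSV, ground
#' truth as JSON.
#'
#' @param sim List from [simulate_counts()].
#' @param peaks,metadata,regions Remaining artifacts.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
write_simulation <- function(sim, peaks, metadata, regions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peaks = file.path(dir, "peaks.bed"),
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    regions = file.path(dir, "gwas_regions.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_bed(peaks, paths[["peaks"]])
  write_counts_tsv(sim$counts, paths[["counts"]])
  write_metadata_csv(metadata, paths[["metadata"]])
  write_regions_tsv(regions, paths[["regions"]])
  jsonlite::write_json(
    list(differential = sim$truth$differential,
         latent = as.list(sim$truth$latent)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
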