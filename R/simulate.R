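#' Draw a spatially smooth map on the cortical sphere
#'
#' Samples a zero-mean Gaussian process over the cortical centroids with
#' exponential covariance `amplitude^2 * exp(-d / correlation_length)`,
#' where `d` is geodesic distance in radians (a small diagonal jitter of
#' 1e-8 stabilizes the Cholesky factorization). Such draws mimic the
#' spatial autocorrelation of real effect-size maps — the regime that
#' motivates spin permutation tests.
#'
#' @param atlas a [parcel_atlas()] with cortical centroids.
#' @param correlation_length positive correlation length in radians.
#' @param amplitude marginal standard deviation of the process.
#' @param seed integer seed (same seed, same map).
#' @param measure,modality passed to [effect_size_map()].
#' @return An [effect_size_map()] over the cortical regions.
#' @export
smooth_map <- function(atlas, correlation_length = 0.8, amplitude = 1,
                       seed = 1L, measure = "cohens_d",
                       modality = "thickness") {
  if (correlation_length <= 0) {
    stop("correlation_length must be positive", call. = FALSE)
  }
  D <- geodesic_distance_matrix(atlas)
  K <- amplitude^2 * exp(-D / correlation_length)
  diag(K) <- diag(K) + 1e-8
  Lc <- chol(K)
  z <- local_seed_eval(seed, stats::rnorm(nrow(D)))
  effect_size_map(atlas, drop(crossprod(Lc, z)), measure = measure,
                  modality = modality)
}

#' Default subcortical region set
#'
#' The standard bilateral subcortical structures used in large-scale
#' morphometry studies: thalamus, caudate, putamen, pallidum, accumbens,
#' hippocampus and amygdala per hemisphere (14 structures), optionally
#' plus the lateral ventricles (16).
#'
#' @param include_ventricles logical; append left/right lateral ventricle.
#' @return Character vector of region names.
#' @export
subcortical_region_names <- function(include_ventricles = FALSE) {
  base <- c("thalamus", "caudate", "putamen", "pallidum", "accumbens",
            "hippocampus", "amygdala")
  if (include_ventricles) base <- c(base, "lateral_ventricle")
  as.vector(t(outer(c("L", "R"), base, paste, sep = "_")))
}

#' Define a multi-site simulation scenario
#'
#' Fixes every parameter of the synthetic cohort generator. The defaults
#' emulate the structure of a large multi-site trait-morphometry study:
#' 29 sites totalling about 3,004 subjects (each at least 30), ages
#' spanning 12-68 years, roughly 46.5% male, site-specific questionnaire
#' scalings (affine transforms of the latent trait), three multi-scanner
#' sites with additive scanner offsets, small spatially smooth true
#' effects (|r| well below 0.1) and mild between-site heterogeneity.
#'
#' @param atlas a [parcel_atlas()]; defaults to
#'   `synthetic_sphere_atlas(34, seed)` (68 bilateral parcels).
#' @param n_sites number of sites.
#' @param total_n approximate total subject count across sites.
#' @param true_effect_map [effect_size_map()] of population partial
#'   correlations (measure `"partial_r"`); defaults to a smooth map of
#'   amplitude `effect_amplitude`. All values must stay below 0.5 in
#'   magnitude — the small-effect regime of trait-morphometry studies.
#' @param planted optional named numeric vector of region -> partial r
#'   overriding individual entries of the true map (e.g.
#'   `c(L_region_01 = 0.067)`).
#' @param effect_amplitude marginal SD of the default smooth true map.
#' @param spatial_correlation_length correlation length (radians) of the
#'   true map and other smooth fixtures.
#' @param tau2_between_site between-site variance of the region effect
#'   (on the correlation scale).
#' @param n_multiscanner number of sites with more than one scanner.
#' @param residual_sd residual SD of a region value after all model terms
#'   (morphometry units).
#' @param include_smoking logical; generate a smoking column.
#' @param trait_distribution `"gaussian"` (default) or `"gamma"` — a
#'   standardized, right-skewed latent trait for sensitivity analyses,
#'   mimicking the skew of real questionnaire totals. The planted partial
#'   correlations only involve second moments, so calibration is
#'   unaffected.
#' @param modality `"thickness"`, `"surface_area"` or
#'   `"subcortical_volume"`.
#' @param seed integer seed controlling every scenario-level draw.
#' @return Object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(atlas = NULL, n_sites = 29, total_n = 3004,
                                true_effect_map = NULL, planted = NULL,
                                effect_amplitude = 0.02,
                                spatial_correlation_length = 0.8,
                                tau2_between_site = 0.001,
                                n_multiscanner = 3, residual_sd = 0.12,
                                include_smoking = TRUE,
                                trait_distribution = c("gaussian", "gamma"),
                                modality = c("thickness", "surface_area",
                                             "subcortical_volume"),
                                seed = 1L) {
  modality <- match.arg(modality)
  trait_distribution <- match.arg(trait_distribution)
  if (is.null(atlas)) atlas <- synthetic_sphere_atlas(34, seed = seed)
  regions <- atlas_regions(atlas, modality_class(modality))
  nr <- length(regions)

  if (is.null(true_effect_map)) {
    if (modality_class(modality) == "cortical") {
      true_effect_map <- smooth_map(atlas, spatial_correlation_length,
                                    amplitude = effect_amplitude,
                                    seed = seed + 101L,
                                    measure = "partial_r",
                                    modality = modality)
    } else {
      vals <- local_seed_eval(seed + 101L,
                              stats::rnorm(nr, 0, effect_amplitude))
      true_effect_map <- effect_size_map(atlas, vals, measure = "partial_r",
                                         modality = modality)
    }
  }
  if (!is.null(planted)) {
    vals <- true_effect_map$values
    bad <- setdiff(names(planted), names(vals))
    if (length(bad)) {
      stop("planted effect names not in atlas: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    vals[names(planted)] <- planted
    true_effect_map <- effect_size_map(atlas, vals, measure = "partial_r",
                                       modality = modality)
  }
  if (any(abs(true_effect_map$values) >= 0.5)) {
    stop("true effects must satisfy |r| < 0.5 (small-effect regime)",
         call. = FALSE)
  }

  params <- local_seed_eval(seed + 202L, {
    raw <- exp(stats::rnorm(n_sites, 0, 0.6))
    sizes <- pmax(30L, as.integer(round(raw / sum(raw) * total_n)))
    # nudge the largest site so totals land on target
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] +
      (total_n - sum(sizes))
    sizes <- pmax(30L, sizes)

    age_lo <- stats::runif(n_sites, 12, 30)
    age_hi <- pmin(68, age_lo + stats::runif(n_sites, 10, 38))
    list(
      site_sizes = sizes,
      scanner_counts = c(rep(2L, min(n_multiscanner, n_sites)),
                         rep(1L, max(0, n_sites - n_multiscanner))),
      questionnaire_scale = cbind(a = stats::runif(n_sites, 10, 40),
                                  b = stats::runif(n_sites, 5, 15)),
      sex_prop = pmin(0.8, pmax(0.2, stats::rnorm(n_sites, 0.465, 0.05))),
      age_range = cbind(lo = age_lo, hi = age_hi),
      smoking_prop = stats::runif(n_sites, 0.2, 0.5),
      baseline = stats::rnorm(nr, 2.5, 0.15),
      beta_age = stats::rnorm(nr, -0.010, 0.003),
      beta_sex = stats::rnorm(nr, 0.03, 0.01),
      loading = stats::runif(nr, 0.05, 0.20)
    )
  })

  structure(c(list(atlas = atlas, n_sites = as.integer(n_sites),
                   regions = regions, true_effect_map = true_effect_map,
                   spatial_correlation_length = spatial_correlation_length,
                   tau2_between_site = tau2_between_site,
                   residual_sd = residual_sd,
                   include_smoking = include_smoking,
                   trait_distribution = trait_distribution,
                   modality = modality, seed = as.integer(seed)),
              params),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("<simulation_scenario> ", x$n_sites, " sites, total n=",
      sum(x$site_sizes), ", ", length(x$regions), " ", x$modality,
      " regions, tau2=", x$tau2_between_site, ", seed=", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Generate a multi-site cohort with known ground truth
#'
#' Simulates one subject table per site under the scenario's generative
#' model. Per site: a standard-normal latent trait reported through the
#' site's affine questionnaire transform; age uniform within the site's
#' range; sex Bernoulli at the site's proportion; scanner assignment with
#' additive offsets for multi-scanner sites; and region values
#' `baseline + age*slope + sex*offset + loading*global_factor +
#' scanner_offset + gamma*latent + noise`. The trait loading `gamma` is
#' calibrated analytically so the population partial correlation given
#' the model covariates equals the scenario's true effect plus a
#' site-specific deviation with variance `tau2_between_site`:
#' since the covariates are independent of the latent trait,
#' `gamma = rho * residual_sd / sqrt(1 - rho^2)`.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed; defaults to the scenario seed so the default
#'   cohort is the scenario's own realization.
#' @return Named list of per-site data.frames (columns
#'   `trait,age,sex,scanner,smoking,global,<regions>`), each carrying a
#'   `site_id` attribute. The list carries the per-site true region
#'   effects in attribute `site_true_r`.
#' @export
generate_cohort <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  nr <- length(sc$regions)
  rho0 <- unname(sc$true_effect_map$values)

  local_seed_eval(seed, {
    site_true <- matrix(NA_real_, sc$n_sites, nr,
                        dimnames = list(NULL, sc$regions))
    cohort <- vector("list", sc$n_sites)
    names(cohort) <- sprintf("site%02d", seq_len(sc$n_sites))
    for (s in seq_len(sc$n_sites)) {
      n <- sc$site_sizes[s]
      rho <- rho0 + stats::rnorm(nr, 0, sqrt(sc$tau2_between_site))
      if (any(abs(rho) >= 0.95)) {
        stop("infeasible calibration: |target partial r| too large for ",
             "the noise model", call. = FALSE)
      }
      site_true[s, ] <- rho
      gamma <- rho * sc$residual_sd / sqrt(1 - rho^2)

      z <- if (sc$trait_distribution == "gamma") {
        (stats::rgamma(n, shape = 2, rate = 1) - 2) / sqrt(2)
      } else {
        stats::rnorm(n)
      }
      trait <- sc$questionnaire_scale[s, "a"] +
        sc$questionnaire_scale[s, "b"] * z
      age <- stats::runif(n, sc$age_range[s, "lo"], sc$age_range[s, "hi"])
      sex <- stats::rbinom(n, 1, sc$sex_prop[s])
      g <- stats::rnorm(n)
      global <- 2.5 + 0.1 * g
      m <- sc$scanner_counts[s]
      scanner <- paste0("scan", sample.int(m, n, replace = TRUE))
      offsets <- stats::rnorm(m, 0, 0.05)
      scan_off <- offsets[as.integer(sub("scan", "", scanner))]

      Y <- matrix(stats::rnorm(n * nr, 0, sc$residual_sd), n, nr)
      Y <- Y + outer(rep(1, n), sc$baseline) +
        outer(age, sc$beta_age) + outer(as.numeric(sex), sc$beta_sex) +
        outer(g, sc$loading) + outer(z, gamma) + scan_off
      colnames(Y) <- sc$regions

      df <- data.frame(trait = trait, age = age, sex = sex,
                       scanner = scanner,
                       smoking = if (sc$include_smoking)
                         stats::rbinom(n, 1, sc$smoking_prop[s]) else NA,
                       global = global, stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(Y))
      attr(df, "site_id") <- names(cohort)[s]
      cohort[[s]] <- df
    }
    attr(cohort, "site_true_r") <- site_true
    cohort
  })
}

#' Write a simulated cohort to per-site files
#'
#' @param cohort output of [generate_cohort()].
#' @param dir destination directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(cohort), function(s) {
    p <- file.path(dir, paste0(s, ".csv"))
    write_subject_table(cohort[[s]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Generate a disorder-style effect-size map with controlled similarity
#'
#' Mixes the standardized base map with an independent smooth map:
#' `target_correlation * std(base) + sqrt(1 - target_correlation^2) *
#' std(independent)`, rescaled to the requested amplitude, so the
#' expected Pearson correlation with `base` is approximately
#' `target_correlation`. Used as a stand-in for published case-control
#' Cohen's d maps when testing the similarity stage.
#'
#' @param base an [effect_size_map()] (e.g. the true or estimated trait
#'   map).
#' @param target_correlation desired correlation with `base`, in
#'   \[-1, 1\].
#' @param amplitude marginal SD of the returned map (Cohen's d scale).
#' @param correlation_length smoothness of the independent component.
#' @param seed integer seed.
#' @return An [effect_size_map()] with measure `"cohens_d"`.
#' @export
generate_disorder_map <- function(base, target_correlation, amplitude = 0.3,
                                  correlation_length = 0.8, seed = 1L) {
  stopifnot(inherits(base, "effect_size_map"))
  if (abs(target_correlation) > 1) {
    stop("|target_correlation| must be <= 1", call. = FALSE)
  }
  std <- function(x) (x - mean(x)) / stats::sd(x)
  if (modality_class(base$modality) == "cortical") {
    indep <- smooth_map(base$atlas, correlation_length, amplitude = 1,
                        seed = seed, modality = base$modality)$values
  } else {
    indep <- local_seed_eval(seed, stats::rnorm(length(base$values)))
  }
  mix <- target_correlation * std(unname(base$values)) +
    sqrt(1 - target_correlation^2) * std(unname(indep))
  if (stats::sd(mix) > 0) mix <- std(mix)
  effect_size_map(base$atlas, mix * amplitude, measure = "cohens_d",
                  modality = base$modality)
}
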