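#' Assemble and validate a pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the atlas, the per-site
#' subject tables (in memory or as a directory of delimited files), the
#' covariate model, meta-analysis settings, optional site-level
#' moderators, and optional disorder effect-size maps for the similarity
#' stage.
#'
#' @param atlas a [parcel_atlas()] or path to an atlas file.
#' @param site_tables named list of per-site data.frames (see
#'   [read_subject_table()]); alternative to `site_dir`.
#' @param site_dir directory of per-site `.csv` subject tables.
#' @param model a [covariate_model()]; default cortical model 1.
#' @param modality `"thickness"`, `"surface_area"` or
#'   `"subcortical_volume"`.
#' @param scale effect transform for pooling (`"fisher_z"` or `"raw_r"`).
#' @param method tau2 estimator (`"REML"` or `"DL"`).
#' @param alpha FDR level, in (0, 1).
#' @param n_perm permutations/rotations for the similarity stage.
#' @param tail tail for the similarity tests.
#' @param seed integer master seed for every stochastic stage.
#' @param moderators optional data.frame with column `site` plus one
#'   column per site-level moderator (questionnaire type, scanner count,
#'   field strength, ...).
#' @param disorder_maps optional named list of [effect_size_map()]s (or
#'   file paths) to correlate with the pooled trait map; with two or more
#'   maps, Steiger comparisons against the first are added.
#' @param out_dir output directory for report files.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(atlas, site_tables = NULL, site_dir = NULL,
                            model = default_models()$model1,
                            modality = c("thickness", "surface_area",
                                         "subcortical_volume"),
                            scale = c("fisher_z", "raw_r"),
                            method = c("REML", "DL"),
                            alpha = 0.05, n_perm = 10000,
                            tail = c("two_sided", "greater", "less"),
                            seed = 1L, moderators = NULL,
                            disorder_maps = NULL, out_dir = tempfile("run")) {
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (is.character(atlas)) {
    if (!file.exists(atlas)) stop("atlas file not found: ", atlas, call. = FALSE)
  } else {
    stopifnot(inherits(atlas, "parcel_atlas"))
  }
  if (is.null(site_tables) && is.null(site_dir)) {
    stop("provide site_tables or site_dir", call. = FALSE)
  }
  if (!is.null(site_dir) && !dir.exists(site_dir)) {
    stop("site_dir not found: ", site_dir, call. = FALSE)
  }
  if (!is.null(moderators) && !"site" %in% names(moderators)) {
    stop("moderators needs a `site` column", call. = FALSE)
  }
  stopifnot(inherits(model, "covariate_model"))
  structure(list(atlas = atlas, site_tables = site_tables,
                 site_dir = site_dir, model = model, modality = modality,
                 scale = scale, method = method, alpha = alpha,
                 n_perm = as.integer(n_perm), tail = tail,
                 seed = as.integer(seed), moderators = moderators,
                 disorder_maps = disorder_maps, out_dir = out_dir),
            class = "pipeline_config")
}

# 32-bit FNV-1a over a string; used only to fingerprint the config in logs.
# out_dir is excluded so reruns into different directories are recognized
# as the same analysis.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
             collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_report <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full multi-site analysis pipeline
#'
#' Executes the two analyses end to end: (1) per-site partial
#' correlations pooled region-wise by random-effects meta-analysis with
#' FDR, plus optional categorical moderator tests; (2) optional spatial
#' similarity between the pooled trait map and supplied disorder maps
#' (spin test for cortical modalities, label shuffling for subcortical),
#' with Steiger comparisons of the dependent similarity coefficients
#' against the first disorder map. Writes delimited report files with a
#' commented configuration header and a run log; identical configuration
#' and seed produce bit-identical outputs. Any stage error aborts with a
#' stage-labeled message and no partial report files are left behind.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `region_table`, `moderator_table`,
#'   `similarity_table`, `steiger_table`, `exclusions`, and `paths` of
#'   the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", label, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  atlas <- stage("config", {
    if (is.character(config$atlas)) load_atlas(config$atlas) else config$atlas
  })
  tables <- stage("config", {
    if (!is.null(config$site_tables)) config$site_tables
    else {
      paths <- sort(list.files(config$site_dir, pattern = "\\.csv$",
                               full.names = TRUE))
      if (!length(paths)) stop("no .csv site tables in ", config$site_dir)
      stats::setNames(lapply(paths, read_subject_table),
                      sub("\\.csv$", "", basename(paths)))
    }
  })

  effects_list <- stage("site_effects", {
    lapply(names(tables), function(s) {
      site_effects(tables[[s]], config$model, atlas,
                   modality = config$modality, site_id = s)
    })
  })
  effects <- do.call(rbind, effects_list)
  exclusions <- effects[!is.na(effects$reason),
                        c("site", "region", "reason")]

  regions <- atlas_regions(atlas, modality_class(config$modality))
  region_table <- stage("meta_analysis", {
    meta_analyze(effects, scale = config$scale, method = config$method,
                 region_order = regions)
  })

  moderator_table <- NULL
  if (!is.null(config$moderators)) {
    moderator_table <- stage("moderators", {
      cols <- setdiff(names(config$moderators), "site")
      do.call(rbind, lapply(cols, function(cl) {
        moderator_analysis(
          effects,
          stats::setNames(config$moderators[[cl]], config$moderators$site),
          moderator = cl, scale = config$scale, method = config$method)
      }))
    })
  }

  similarity_table <- NULL
  steiger_table <- NULL
  if (!is.null(config$disorder_maps) && length(config$disorder_maps)) {
    sim <- stage("similarity", {
      maps <- lapply(config$disorder_maps, function(m) {
        if (is.character(m)) {
          read_effect_map(m, atlas, measure = "cohens_d",
                          modality = config$modality)
        } else m
      })
      pooled <- region_table$pooled_r
      if (anyNA(pooled)) stop("pooled map contains NA regions")
      trait_map <- effect_size_map(
        atlas, stats::setNames(pmin(1, pmax(-1, pooled)),
                               region_table$region),
        measure = "partial_r", modality = config$modality)
      cortical <- modality_class(config$modality) == "cortical"
      spin <- if (cortical) {
        build_spin_null(atlas, config$n_perm, seed = config$seed)
      }
      res <- lapply(maps, function(m) {
        if (cortical) spin_test(trait_map, m, spin, tail = config$tail)
        else label_shuffle_test(trait_map, m, n_perm = config$n_perm,
                                seed = config$seed, tail = config$tail)
      })
      sim_tab <- data.frame(
        map = names(maps),
        method = vapply(res, `[[`, character(1), "method"),
        coefficient = vapply(res, `[[`, numeric(1), "coefficient"),
        p_perm = vapply(res, `[[`, numeric(1), "p_perm"),
        tail = config$tail, n_perm = config$n_perm,
        stringsAsFactors = FALSE
      )
      st_tab <- NULL
      if (length(maps) >= 2) {
        cmeth <- if (cortical) "pearson" else "spearman"
        vals <- lapply(maps, function(m) align_map(m, regions))
        tvals <- align_map(trait_map, regions)
        st_rows <- lapply(seq(2, length(maps)), function(h) {
          st <- steiger_test(
            r_jk = stats::cor(tvals, vals[[1]], method = cmeth),
            r_jh = stats::cor(tvals, vals[[h]], method = cmeth),
            r_kh = stats::cor(vals[[1]], vals[[h]], method = cmeth),
            n = length(regions), tail = "greater")
          data.frame(map_k = names(maps)[1], map_h = names(maps)[h],
                     r_jk = st$r_jk, r_jh = st$r_jh, r_kh = st$r_kh,
                     Z = st$Z, p = st$p, n = st$n, stringsAsFactors = FALSE)
        })
        st_tab <- do.call(rbind, st_rows)
      }
      list(sim = sim_tab, steiger = st_tab)
    })
    similarity_table <- sim$sim
    steiger_table <- sim$steiger
  }

  # single write phase so failures never leave partial reports
  paths <- stage("report", {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                                recursive = TRUE)
    hash <- config_hash(config)
    header <- c(
      paste0("config_hash=", hash),
      paste0("seed=", config$seed),
      paste0("model=", config$model$name,
             " terms=", paste(config$model$terms, collapse = "+")),
      paste0("modality=", config$modality, " scale=", config$scale,
             " method=", config$method, " alpha=", config$alpha),
      paste0("n_perm=", config$n_perm, " tail=", config$tail),
      paste0("n_sites=", length(tables))
    )
    written <- character(0)
    ok <- FALSE
    on.exit(if (!ok) unlink(written), add = TRUE)
    p <- list()
    p$region_table <- file.path(config$out_dir, "region_table.csv")
    write_report(region_table, p$region_table, header)
    written <- c(written, p$region_table)
    if (!is.null(moderator_table)) {
      p$moderator_table <- file.path(config$out_dir, "moderator_table.csv")
      write_report(moderator_table, p$moderator_table, header)
      written <- c(written, p$moderator_table)
    }
    if (!is.null(similarity_table)) {
      p$similarity_table <- file.path(config$out_dir, "similarity_table.csv")
      write_report(similarity_table, p$similarity_table, header)
      written <- c(written, p$similarity_table)
      if (!is.null(steiger_table)) {
        p$steiger_table <- file.path(config$out_dir, "steiger_table.csv")
        write_report(steiger_table, p$steiger_table, header)
        written <- c(written, p$steiger_table)
      }
    }
    p$run_log <- file.path(config$out_dir, "run_log.txt")
    log_lines <- c(
      header,
      paste0("sites: ", paste(names(tables), collapse = ", ")),
      paste0("regions_analyzed=", sum(!is.na(region_table$p_unc)),
             "/", nrow(region_table)),
      paste0("excluded_site_regions=", nrow(exclusions)),
      if (nrow(exclusions)) paste0("  ", exclusions$site, "/",
                                   exclusions$region, ": ",
                                   exclusions$reason)
    )
    writeLines(log_lines, p$run_log)
    written <- c(written, p$run_log)
    ok <- TRUE
    p
  })

  invisible(list(region_table = region_table,
                 moderator_table = moderator_table,
                 similarity_table = similarity_table,
                 steiger_table = steiger_table,
                 exclusions = exclusions, paths = paths))
}
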