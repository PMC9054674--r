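#' Define a covariate adjustment model
#'
#' Standard models used in multi-site morphometry analyses:
#' * cortical model 1 — `age`, `sex`, `global` (global mean thickness or
#'   total surface area) plus within-site scanner dummies,
#' * cortical model 2 — the same without the global term,
#' * subcortical model — `age`, `sex`, `global` (here intracranial
#'   volume) plus scanner dummies,
#' * smoking sensitivity variant — model 1 plus `smoking`.
#'
#' `scanner` expands within each site to (number of scanners - 1) binary
#' indicator columns; for a single-scanner site the block is empty and the
#' term is a no-op.
#'
#' @param terms character vector drawn from
#'   `c("age", "sex", "global", "smoking", "scanner")`.
#' @param name label used in logs and output headers.
#' @return An object of class `covariate_model`.
#' @export
#' @examples
#' covariate_model(c("age", "sex", "global", "scanner"), "model1")
covariate_model <- function(terms, name = paste(terms, collapse = "+")) {
  allowed <- c("age", "sex", "global", "smoking", "scanner")
  terms <- as.character(terms)
  bad <- setdiff(terms, allowed)
  if (length(bad)) {
    stop("unknown covariate term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(terms)) stop("duplicated covariate terms", call. = FALSE)
  structure(list(terms = terms, name = name), class = "covariate_model")
}

#' @rdname covariate_model
#' @export
default_models <- function() {
  list(
    model1 = covariate_model(c("age", "sex", "global", "scanner"), "model1"),
    model2 = covariate_model(c("age", "sex", "scanner"), "model2"),
    subcortical = covariate_model(c("age", "sex", "global", "scanner"),
                                  "subcortical"),
    smoking = covariate_model(c("age", "sex", "global", "smoking", "scanner"),
                              "model1+smoking")
  )
}

#' Partial correlation with covariate adjustment
#'
#' Residual method: both `x` and `y` are regressed (ordinary least
#' squares, with an explicit intercept) on the covariates and the Pearson
#' correlation of the two residual vectors is returned. The t transform
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` gives the
#' two-sided p-value.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix (n x k) of covariate columns, or
#'   `NULL`/zero columns for a plain Pearson correlation.
#' @return list with elements `r`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) {
    stop("covariates must have one row per observation", call. = FALSE)
  }
  k <- ncol(covariates)
  if (anyNA(x) || anyNA(y) || anyNA(covariates)) {
    stop("missing values are not allowed; filter complete cases first",
         call. = FALSE)
  }
  if (n <= k + 2) {
    stop("insufficient n: need n > k + 2 (n=", n, ", k=", k, ")",
         call. = FALSE)
  }
  X <- cbind(1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient covariate matrix (collinear or constant column)",
         call. = FALSE)
  }
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  sx <- sqrt(sum(rx^2))
  sy <- sqrt(sum(ry^2))
  if (sx == 0 || sy == 0) {
    stop("constant residuals: correlation undefined", call. = FALSE)
  }
  r <- sum(rx * ry) / (sx * sy)
  r <- min(1, max(-1, r))
  df <- n - 2 - k
  p <- pcor_pvalue(r, df)
  list(r = r, df = df, p = p)
}

pcor_pvalue <- function(r, df) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

# Within-site scanner dummy block: (n_scanners - 1) indicators, empty
# matrix for a single scanner.
scanner_dummies <- function(scanner) {
  f <- droplevels(factor(scanner))
  if (nlevels(f) < 2) {
    return(matrix(numeric(0), nrow = length(scanner), ncol = 0))
  }
  mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(mm) <- paste0("scanner_", levels(f)[-1])
  mm
}

build_covariates <- function(table, model, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(table))
  blocks <- list()
  for (term in model$terms) {
    if (term == "scanner") {
      blocks[[term]] <- scanner_dummies(table$scanner[rows])
    } else {
      blocks[[term]] <- matrix(as.numeric(table[[term]][rows]),
                               ncol = 1, dimnames = list(NULL, term))
    }
  }
  if (!length(blocks)) {
    return(matrix(numeric(0), nrow = length(rows), ncol = 0))
  }
  do.call(cbind, blocks)
}

#' Per-site, per-region partial correlations
#'
#' Fits the requested covariate model within one site and returns the
#' partial correlation between the trait and each atlas region of the
#' requested modality. Complete-case filtering is per region: a missing
#' region value drops that row for that region only, while rows missing
#' the trait or any model covariate are dropped everywhere. A site
#' contributes to a region only when the residual degrees of freedom
#' `n - k - 2` are at least `min_df`; regions failing that (or any model
#' precondition, e.g. scanner dummies collapsing to a constant within the
#' complete cases) are emitted with `r = NA` and the reason recorded.
#'
#' @param table data.frame for one site with columns `trait`, `age`,
#'   `sex`, `scanner`, optionally `smoking`, `global`, and one column per
#'   atlas region (named as in the atlas). A `site_id` attribute or the
#'   `site_id` argument labels the output.
#' @param model a [covariate_model()].
#' @param atlas a [parcel_atlas()].
#' @param modality `"thickness"`, `"surface_area"` or
#'   `"subcortical_volume"`; selects the atlas regions analyzed.
#' @param site_id site label (defaults to `attr(table, "site_id")`).
#' @param min_df minimum residual degrees of freedom for a region to be
#'   analyzed (default 10, keeping the t approximation sane).
#' @return data.frame with one row per region: `site`, `region`, `r`,
#'   `n` (complete cases used), `k` (covariate columns after dummy
#'   expansion), `p`, `reason` (`NA` for analyzed regions).
#' @export
site_effects <- function(table, model, atlas,
                         modality = c("thickness", "surface_area",
                                      "subcortical_volume"),
                         site_id = NULL, min_df = 10) {
  stopifnot(is.data.frame(table), inherits(model, "covariate_model"),
            inherits(atlas, "parcel_atlas"))
  modality <- match.arg(modality)
  if (is.null(site_id)) site_id <- attr(table, "site_id")
  if (is.null(site_id)) site_id <- "site"

  regions <- atlas_regions(atlas, modality_class(modality))
  missing_regions <- setdiff(regions, names(table))
  if (length(missing_regions)) {
    stop("table lacks region column(s): ",
         paste(utils::head(missing_regions, 5), collapse = ", "),
         call. = FALSE)
  }
  needed <- setdiff(model$terms, "scanner")
  if ("scanner" %in% model$terms) needed <- c(needed, "scanner")
  absent <- setdiff(c("trait", needed), names(table))
  if (length(absent)) {
    stop("model term column(s) absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  base_cols <- c("trait", needed)
  base_ok <- stats::complete.cases(table[, base_cols, drop = FALSE])

  out <- data.frame(
    site = site_id, region = regions, r = NA_real_, n = NA_integer_,
    k = NA_integer_, p = NA_real_, reason = NA_character_,
    stringsAsFactors = FALSE
  )

  region_na <- vapply(regions, function(rg) anyNA(table[[rg]][base_ok]),
                      logical(1))

  fit_rows <- function(rows, region_names) {
    Z <- build_covariates(table, model, rows)
    n <- length(rows)
    k <- ncol(Z)
    if (n - k - 2 < min_df) {
      return(list(ok = FALSE, reason = "insufficient n", n = n, k = k))
    }
    X <- cbind(1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      return(list(ok = FALSE, reason = "collinear covariates", n = n, k = k))
    }
    rt <- qr.resid(qx, as.numeric(table$trait[rows]))
    st <- sqrt(sum(rt^2))
    if (st == 0) {
      return(list(ok = FALSE, reason = "constant trait", n = n, k = k))
    }
    Y <- as.matrix(table[rows, region_names, drop = FALSE])
    RY <- qr.resid(qx, Y)
    sy <- sqrt(colSums(RY^2))
    r <- as.numeric(crossprod(RY, rt)) / (sy * st)
    r[sy == 0] <- NA_real_
    r <- pmin(1, pmax(-1, r))
    df <- n - 2 - k
    p <- vapply(r, function(ri) if (is.na(ri)) NA_real_ else pcor_pvalue(ri, df),
                numeric(1))
    list(ok = TRUE, r = r, n = n, k = k, p = p, const = sy == 0)
  }

  # regions with no extra missingness share one least-squares projection
  batch <- regions[!region_na]
  if (length(batch)) {
    rows <- which(base_ok)
    res <- fit_rows(rows, batch)
    idx <- match(batch, out$region)
    out$n[idx] <- res$n
    out$k[idx] <- res$k
    if (res$ok) {
      out$r[idx] <- res$r
      out$p[idx] <- res$p
      if (any(res$const)) out$reason[idx[res$const]] <- "constant region value"
    } else {
      out$reason[idx] <- res$reason
    }
  }
  for (rg in regions[region_na]) {
    rows <- which(base_ok & !is.na(table[[rg]]))
    idx <- match(rg, out$region)
    if (length(rows) == 0) {
      out$reason[idx] <- "insufficient n"
      out$n[idx] <- 0L
      next
    }
    res <- fit_rows(rows, rg)
    out$n[idx] <- res$n
    out$k[idx] <- res$k
    if (res$ok) {
      out$r[idx] <- res$r
      out$p[idx] <- res$p
      if (res$const) out$reason[idx] <- "constant region value"
    } else {
      out$reason[idx] <- res$reason
    }
  }
  out
}

#' Transform a site effect for meta-analysis
#'
#' Converts a partial correlation and its sample size into an effect
#' estimate `y` with sampling variance `v`:
#' * `fisher_z`: `y = atanh(r)`, `v = 1 / (n - 3 - k)` — the Fisher
#'   transform with the covariate-adjusted variance;
#' * `raw_r`: `y = r`, `v = (1 - r^2)^2 / (n - 1)`.
#'
#' All arguments are vectorized.
#'
#' @param r partial correlation(s).
#' @param n complete-case sample size(s).
#' @param k number of covariate columns.
#' @param scale `"fisher_z"` or `"raw_r"`.
#' @return list with numeric vectors `y` and `v`.
#' @export
effect_to_meta_input <- function(r, n, k = 0, scale = c("fisher_z", "raw_r")) {
  scale <- match.arg(scale)
  r <- as.numeric(r)
  n <- as.numeric(n)
  k <- as.numeric(k)
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1", call. = FALSE)
  if (scale == "fisher_z") {
    if (any(abs(r) >= 1 - 1e-6, na.rm = TRUE)) {
      stop("|r| too close to 1 for the Fisher transform (degenerate site)",
           call. = FALSE)
    }
    if (any(n - 3 - k <= 0, na.rm = TRUE)) {
      stop("need n > k + 3 for the Fisher-z variance", call. = FALSE)
    }
    list(y = atanh(r), v = 1 / (n - 3 - k))
  } else {
    if (any(n <= 1, na.rm = TRUE)) stop("need n > 1", call. = FALSE)
    list(y = r, v = (1 - r^2)^2 / (n - 1))
  }
}

#' Read / write per-site subject tables
#'
#' Subject tables are comma-delimited text, one file per site, with
#' columns `trait,age,sex,scanner,smoking,global,<region names...>`;
#' missing values are empty fields.
#'
#' @param path file path.
#' @param site_id site label; defaults to the file name without extension.
#' @return [read_subject_table()] returns the data.frame with a
#'   `site_id` attribute; [write_subject_table()] returns `path`
#'   invisibly.
#' @export
read_subject_table <- function(path, site_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(site_id)) {
    site_id <- sub("\\.[^.]*$", "", basename(path))
  }
  attr(df, "site_id") <- site_id
  df
}

#' @rdname read_subject_table
#' @param table per-site subject data.frame.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(format_full_precision(table), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

# doubles printed with 17 significant digits round-trip exactly through
# the delimited format
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- NA_character_
      df[[j]] <- x
    }
  }
  df
}
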