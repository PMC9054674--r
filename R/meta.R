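#' Random-effects pooling of per-site effects
#'
#' Pools effect estimates `y` with known sampling variances `v` under the
#' additive between-site heterogeneity model `y_i ~ N(mu, v_i + tau2)`.
#' Two tau-squared estimators are available:
#' * `"DL"` — DerSimonian-Laird method of moments: with fixed-effect
#'   weights `w = 1/v`, `Q = sum(w (y - ybar_w)^2)` and
#'   `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`;
#' * `"REML"` — tau2 maximizing the restricted log-likelihood, found by
#'   iterative root-finding on the restricted score to tolerance 1e-12
#'   (at most 100 iterations); if the search fails the function falls
#'   back to DL and flags it.
#'
#' The pooled mean uses random-effects weights `w* = 1/(v + tau2)`:
#' `mu = sum(w* y)/sum(w*)`, `se = sqrt(1/sum(w*))`. Heterogeneity is
#' summarized by Cochran's Q (always computed with fixed-effect weights)
#' and `I2 = max(0, (Q - (k-1))/Q) * 100`. A single study returns its own
#' estimate with `tau2 = 0`.
#'
#' @param y numeric vector of effect estimates (e.g. Fisher-z correlations).
#' @param v positive sampling variances, same length as `y`.
#' @param method `"REML"` (default) or `"DL"`.
#' @return list with `mu`, `se`, `tau2`, `Q`, `I2`, `k`, `method`, and
#'   logical `fallback_dl` (TRUE when REML failed and DL was used).
#' @export
pool_random_effects <- function(y, v, method = c("REML", "DL")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  v <- as.numeric(v)
  k <- length(y)
  if (k < 1) stop("need at least one study", call. = FALSE)
  if (length(v) != k) stop("y and v must have equal length", call. = FALSE)
  if (anyNA(y) || anyNA(v)) stop("missing values in y or v", call. = FALSE)
  if (any(v <= 0)) stop("non-positive sampling variance", call. = FALSE)

  if (k == 1) {
    return(list(mu = y, se = sqrt(v), tau2 = 0, Q = 0, I2 = 0, k = 1L,
                method = method, fallback_dl = FALSE))
  }

  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2_dl <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))

  fallback <- FALSE
  if (method == "DL") {
    tau2 <- tau2_dl
  } else {
    tau2 <- tryCatch(reml_tau2(y, v), error = function(e) NA_real_)
    if (is.na(tau2)) {
      warning("REML did not converge; falling back to DerSimonian-Laird")
      tau2 <- tau2_dl
      fallback <- TRUE
    }
  }

  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(mu = mu, se = se, tau2 = tau2, Q = Q, I2 = I2, k = as.integer(k),
       method = method, fallback_dl = fallback)
}

# Restricted log-likelihood of tau2 (design matrix X; intercept-only for
# plain pooling).
reml_loglik <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, X * w)
  b <- solve(XtWX, crossprod(X, y * w))
  e <- y - X %*% b
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus +
            sum(w * e^2))
}

# REML tau2 as the root of the restricted-likelihood score
#   s(tau2) = -(tr(P) - y'PPy)/2,  P = W - WX(X'WX)^{-1}X'W,
# solved by bracketed iteration (uniroot, tol 1e-12). A non-positive
# score at tau2 = 0 means the boundary solution tau2 = 0.
reml_score <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, X * w)
  A <- solve(XtWX)
  B1 <- crossprod(X, X * w^2)
  b <- A %*% crossprod(X, y * w)
  e <- drop(y - X %*% b)
  trP <- sum(w) - sum(diag(A %*% B1))
  -0.5 * (trP - sum((w * e)^2))
}

reml_tau2 <- function(y, v, X = matrix(1, length(y), 1)) {
  if (reml_score(0, y, v, X) <= 0) return(0)
  upper <- max(stats::var(y), max(v), 1e-4)
  for (i in seq_len(60)) {
    if (reml_score(upper, y, v, X) < 0) break
    upper <- upper * 4
    if (i == 60) stop("REML did not converge: score has no finite root",
                      call. = FALSE)
  }
  stats::uniroot(reml_score, c(0, upper), y = y, v = v, X = X,
                 tol = 1e-12, maxiter = 100)$root
}

#' Meta-analyze one region across sites
#'
#' Transforms per-site partial correlations via [effect_to_meta_input()],
#' pools them with [pool_random_effects()], and back-transforms the
#' pooled mean and its 95% confidence bounds to the correlation scale
#' (through `tanh` when `scale = "fisher_z"`, making the interval
#' asymmetric in r by design). The two-sided p-value uses the normal
#' approximation `z = mu / se`. Regions with a single contributing site
#' are returned but flagged (`single_site = TRUE`).
#'
#' @param effects data.frame of site effects for one region, with columns
#'   `r`, `n`, `k` (rows with `NA` r are dropped as non-contributing).
#' @param scale `"fisher_z"` or `"raw_r"`.
#' @param method tau2 estimator passed to [pool_random_effects()].
#' @param region region label for the output row.
#' @return One-row data.frame: `region, pooled_r, ci_low, ci_high, tau2,
#'   Q, I2, k_sites, n_total, p_unc, single_site`.
#' @export
meta_region <- function(effects, scale = c("fisher_z", "raw_r"),
                        method = c("REML", "DL"),
                        region = effects$region[1]) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  ok <- !is.na(effects$r)
  eff <- effects[ok, , drop = FALSE]
  if (nrow(eff) == 0) {
    return(data.frame(region = region, pooled_r = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      tau2 = NA_real_, Q = NA_real_, I2 = NA_real_,
                      k_sites = 0L, n_total = 0L, p_unc = NA_real_,
                      single_site = NA, stringsAsFactors = FALSE))
  }
  yv <- effect_to_meta_input(eff$r, eff$n, eff$k, scale = scale)
  fit <- pool_random_effects(yv$y, yv$v, method = method)
  ci <- fit$mu + c(-1, 1) * stats::qnorm(0.975) * fit$se
  if (scale == "fisher_z") {
    pooled <- tanh(fit$mu)
    ci <- tanh(ci)
  } else {
    pooled <- fit$mu
  }
  p <- if (fit$se > 0) 2 * stats::pnorm(-abs(fit$mu / fit$se)) else 0
  data.frame(region = region, pooled_r = pooled, ci_low = ci[1],
             ci_high = ci[2], tau2 = fit$tau2, Q = fit$Q, I2 = fit$I2,
             k_sites = fit$k, n_total = as.integer(sum(eff$n)),
             p_unc = p, single_site = fit$k < 2, stringsAsFactors = FALSE)
}

#' Meta-analyze all regions of one modality
#'
#' Runs [meta_region()] for every region in the stacked site-effect table
#' and applies Benjamini-Hochberg FDR across the regions of this call
#' (i.e. one FDR family per modality). Single-site regions are reported
#' but excluded from the FDR family (their `p_fdr` is `NA`).
#'
#' @param effects stacked output of [site_effects()] across sites
#'   (columns `site, region, r, n, k, p`).
#' @param region_order optional character vector fixing the output row
#'   order (e.g. [atlas_regions()]); defaults to order of appearance.
#' @inheritParams meta_region
#' @return data.frame with one row per region, columns of [meta_region()]
#'   plus `p_fdr`.
#' @export
meta_analyze <- function(effects, scale = c("fisher_z", "raw_r"),
                         method = c("REML", "DL"), region_order = NULL) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  if (is.null(region_order)) region_order <- unique(effects$region)
  rows <- lapply(region_order, function(rg) {
    meta_region(effects[effects$region == rg, , drop = FALSE],
                scale = scale, method = method, region = rg)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  family <- which(!is.na(out$p_unc) & !out$single_site)
  if (length(family)) out$p_fdr[family] <- bh_fdr(out$p_unc[family])
  out
}

#' Categorical moderator test (mixed-effects meta-regression)
#'
#' Fits a meta-regression of the effects on indicator columns for the
#' moderator levels, with residual heterogeneity tau2 estimated by REML
#' (or a DerSimonian-Laird-type method of moments), and tests all
#' non-intercept coefficients with the omnibus Wald statistic `QM`
#' against a chi-square distribution with (levels - 1) degrees of
#' freedom.
#'
#' @param y,v effect estimates and sampling variances.
#' @param levels categorical moderator, one value per effect.
#' @param method tau2 estimator: `"REML"` (default) or `"DL"`.
#' @return list with `QM`, `df`, `p`, `tau2`, `coef`, `levels`.
#' @export
moderator_test <- function(y, v, levels, method = c("REML", "DL")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  v <- as.numeric(v)
  f <- droplevels(factor(levels))
  k <- length(y)
  if (length(v) != k || length(f) != k) {
    stop("y, v and levels must have equal length", call. = FALSE)
  }
  if (any(v <= 0)) stop("non-positive sampling variance", call. = FALSE)
  if (nlevels(f) < 2) stop("need at least 2 moderator levels", call. = FALSE)
  if (any(table(f) < 1)) stop("moderator level with zero studies", call. = FALSE)
  if (k <= nlevels(f)) stop("saturated model: k must exceed level count",
                            call. = FALSE)
  X <- stats::model.matrix(~f)
  p <- ncol(X)

  if (method == "DL") {
    w0 <- 1 / v
    XtW0X <- crossprod(X, X * w0)
    b0 <- solve(XtW0X, crossprod(X, y * w0))
    e0 <- y - X %*% b0
    QE <- sum(w0 * e0^2)
    # tr(P) for the moment estimator with fixed weights
    trP <- sum(w0) - sum(diag(solve(XtW0X, crossprod(X, X * w0^2))))
    tau2 <- max(0, (QE - (k - p)) / trP)
  } else {
    tau2 <- reml_tau2(y, v, X)
  }

  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, X * w)
  b <- solve(XtWX, crossprod(X, y * w))
  covb <- solve(XtWX)
  idx <- seq(2, p)
  QM <- drop(t(b[idx]) %*% solve(covb[idx, idx, drop = FALSE], b[idx]))
  dfm <- p - 1
  list(QM = QM, df = dfm, p = stats::pchisq(QM, dfm, lower.tail = FALSE),
       tau2 = tau2, coef = drop(b), levels = levels(f))
}

#' Moderator tests across all regions
#'
#' Runs [moderator_test()] per region on site effects joined to a
#' site-level moderator and FDR-adjusts the omnibus p-values across
#' regions.
#'
#' @param effects stacked [site_effects()] table.
#' @param site_levels named vector or data.frame(site, level) giving the
#'   moderator level of each site.
#' @param moderator label for the output.
#' @inheritParams meta_region
#' @return data.frame `moderator, region, QM, df, p_unc, p_fdr` (regions
#'   where the test is not estimable carry `NA`).
#' @export
moderator_analysis <- function(effects, site_levels, moderator = "moderator",
                               scale = c("fisher_z", "raw_r"),
                               method = c("REML", "DL")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  if (is.data.frame(site_levels)) {
    site_levels <- stats::setNames(site_levels$level, site_levels$site)
  }
  regions <- unique(effects$region)
  rows <- lapply(regions, function(rg) {
    eff <- effects[effects$region == rg & !is.na(effects$r), , drop = FALSE]
    lev <- site_levels[eff$site]
    res <- tryCatch({
      yv <- effect_to_meta_input(eff$r, eff$n, eff$k, scale = scale)
      moderator_test(yv$y, yv$v, lev, method = method)
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(moderator = moderator, region = rg, QM = NA_real_,
                 df = NA_integer_, p_unc = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(moderator = moderator, region = rg, QM = res$QM,
                 df = res$df, p_unc = res$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_unc)
  if (any(ok)) out$p_fdr[ok] <- bh_fdr(out$p_unc[ok])
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `p_adj_(i) = min_{j >= i} (p_(j) * m / j)` clipped at 1, returned in
#' the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
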