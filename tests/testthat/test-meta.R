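test_that("DerSimonian-Laird pooling reproduces hand-computed values", {
  # homogeneous studies: no heterogeneity, pooled mean is the common value
  f <- pool_random_effects(c(0.5, 0.5), c(0.04, 0.04), "DL")
  expect_equal(f$Q, 0)
  expect_equal(f$tau2, 0)
  expect_equal(f$mu, 0.5)
  expect_equal(f$I2, 0)

  # y=(0,1), v=(.25,.25): w=4, ybar=.5, Q = 4*.25+4*.25 = 2,
  # tau2 = (2-1)/(8-32/8) = 0.25, mu = .5 by symmetry
  f <- pool_random_effects(c(0, 1), c(0.25, 0.25), "DL")
  expect_equal(f$Q, 2)
  expect_equal(f$tau2, 0.25)
  expect_equal(f$mu, 0.5)
  expect_equal(f$I2, 50)

  # single study passes through
  f1 <- pool_random_effects(0.3, 0.01)
  expect_equal(f1$mu, 0.3)
  expect_equal(f1$se, 0.1)
  expect_equal(f1$tau2, 0)

  expect_error(pool_random_effects(c(0, 1), c(0.1, -0.1)), "non-positive")
})

test_that("DL matches a literal-formula reimplementation on random instances", {
  set.seed(10)
  for (i in 1:300) {
    k <- sample(2:30, 1)
    y <- rnorm(k, 0, 0.3)
    v <- runif(k, 0.001, 0.2)
    f <- pool_random_effects(y, v, "DL")
    o <- dl_literal(y, v)
    expect_lt(abs(f$tau2 - o$tau2), 1e-12)
    expect_lt(abs(f$mu - o$mu), 1e-12)
    expect_lt(abs(f$Q - o$Q) / max(1, o$Q), 1e-12)
    # pooled mean is a convex combination of the study estimates
    expect_gte(f$mu, min(y) - 1e-12)
    expect_lte(f$mu, max(y) + 1e-12)
  }
})

test_that("zero heterogeneity reduces pooling to the fixed-effect average", {
  set.seed(2)
  v <- runif(8, 0.01, 0.1)
  mu0 <- sum(0.2 / v) / sum(1 / v)   # all y equal -> Q = 0 -> tau2 = 0
  f <- pool_random_effects(rep(0.2, 8), v, "DL")
  expect_equal(f$tau2, 0)
  expect_equal(f$mu, mu0, tolerance = 1e-12)

  y <- rnorm(8, 0, 0.001)            # Q < k-1 -> tau2 truncated to 0
  f2 <- pool_random_effects(y, v, "DL")
  expect_equal(f2$tau2, 0)
  expect_equal(f2$mu, sum(y / v) / sum(1 / v), tolerance = 1e-12)
})

test_that("REML pooling agrees with an independent reference implementation", {
  set.seed(33)
  for (i in 1:20) {
    k <- sample(5:30, 1)
    v <- 1 / (sample(30:300, k) - 7)
    y <- rnorm(k, 0.05, sqrt(v + 0.002))
    f <- pool_random_effects(y, v, "REML")
    ref <- metafor::rma(yi = y, vi = v, method = "REML",
                        control = list(threshold = 1e-12))
    expect_equal(f$tau2, ref$tau2, tolerance = 1e-5)
    expect_equal(f$mu, as.numeric(ref$b), tolerance = 1e-7)
    expect_equal(f$se, ref$se, tolerance = 1e-6)

    fd <- pool_random_effects(y, v, "DL")
    refd <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(fd$tau2, refd$tau2, tolerance = 1e-12)
    expect_equal(fd$I2, refd$I2, tolerance = 1e-8)
  }
})

test_that("meta_region pools, back-transforms, and respects sign symmetry", {
  eff <- data.frame(site = paste0("s", 1:5), region = "roi",
                    r = rep(0.25, 5), n = rep(120, 5), k = 3,
                    p = NA_real_)
  m <- meta_region(eff)
  expect_equal(m$pooled_r, 0.25, tolerance = 1e-12)
  expect_true(m$ci_low <= m$pooled_r && m$pooled_r <= m$ci_high)
  expect_false(m$single_site)

  set.seed(5)
  eff$r <- runif(5, -0.2, 0.3)
  m1 <- meta_region(eff)
  eff2 <- eff
  eff2$r <- -eff$r
  m2 <- meta_region(eff2)
  expect_equal(m2$pooled_r, -m1$pooled_r, tolerance = 1e-12)
  expect_equal(m2$p_unc, m1$p_unc, tolerance = 1e-12)
  expect_equal(m2$ci_low, -m1$ci_high, tolerance = 1e-12)

  # asymmetry of the back-transformed CI on the r scale
  effb <- eff
  effb$r <- rep(0.6, 5)
  effb$n <- 40
  mb <- meta_region(effb)
  expect_lt(mb$ci_high - mb$pooled_r, mb$pooled_r - mb$ci_low)

  m_single <- meta_region(eff[1, , drop = FALSE])
  expect_true(m_single$single_site)
})

test_that("meta_analyze applies one FDR family and flags single-site regions", {
  set.seed(8)
  eff <- expand.grid(site = paste0("s", 1:6), region = paste0("roi", 1:10),
                     stringsAsFactors = FALSE)
  eff$r <- rnorm(nrow(eff), 0, 0.1)
  eff$n <- 100
  eff$k <- 3
  eff$r[eff$region == "roi1" & eff$site != "s1"] <- NA  # single-site region
  out <- meta_analyze(eff, region_order = paste0("roi", 1:10))
  expect_equal(out$region, paste0("roi", 1:10))
  expect_true(out$single_site[1])
  expect_true(is.na(out$p_fdr[1]))
  multi <- !out$single_site
  expect_true(all(out$p_fdr[multi] >= out$p_unc[multi]))
  expect_equal(out$p_fdr[multi], bh_fdr(out$p_unc[multi]))
  expect_true(all(out$tau2[multi] >= 0))
  expect_true(all(out$I2[multi] >= 0 & out$I2[multi] <= 100))
})

test_that("moderator test detects separation and matches the reference QM", {
  v <- rep(0.01, 12)
  lev <- rep(c("A", "B"), each = 6)

  # identical level means: no moderation
  y <- rep(0.1, 12)
  res <- moderator_test(y, v, lev, "DL")
  expect_lt(res$QM, 1e-20)
  expect_gt(res$p, 0.999)

  # huge separation: decisive moderation
  y2 <- c(rep(0, 6), rep(2, 6))
  expect_lt(moderator_test(y2, v, lev)$p, 1e-6)

  set.seed(21)
  for (i in 1:10) {
    k <- 24
    lev3 <- sample(rep(c("x", "y", "z"), each = 8))
    vv <- runif(k, 0.005, 0.05)
    yy <- rnorm(k, 0.1, sqrt(vv + 0.001))
    mine <- moderator_test(yy, vv, lev3, "REML")
    ref <- metafor::rma(yi = yy, vi = vv, mods = ~factor(lev3),
                        method = "REML", control = list(threshold = 1e-12))
    expect_equal(mine$QM, ref$QM, tolerance = 1e-4)
    expect_equal(mine$p, ref$QMp, tolerance = 1e-4)
    expect_equal(mine$df, 2)
  }

  expect_error(moderator_test(y, v, rep("A", 12)), "2 moderator levels")
  expect_error(moderator_test(y[1:2], v[1:2], c("A", "B")), "saturated")
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # worked step-up: m=4, sorted p * m/i, cumulative minimum from the top
  p <- c(0.005, 0.04, 0.03, 0.9)
  expect_equal(bh_fdr(p), c(0.02, 0.04 * 4 / 3, 0.04 * 4 / 3, 0.9))

  set.seed(4)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # step-up adjustment is monotone in the raw p-values
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
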