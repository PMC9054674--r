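# Shared fixtures, built in code.

small_atlas <- function(n = 8, seed = 1, subcortical = NULL) {
  synthetic_sphere_atlas(n, seed = seed, subcortical = subcortical)
}

# independent oracle: partial correlation via the precision matrix of
# (x, y, covariates) -- a different algebraic route than residualization
pcor_precision <- function(x, y, C) {
  R <- stats::cor(cbind(x, y, C))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# independent oracle: literal DerSimonian-Laird formulas, written as the
# textbook equations with explicit loops
dl_literal <- function(y, v) {
  k <- length(y)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / v[i]
  ybar <- sum(w * y) / sum(w)
  Q <- 0
  for (i in seq_len(k)) Q <- Q + w[i] * (y[i] - ybar)^2
  tau2 <- (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))
  tau2 <- max(0, tau2)
  ws <- 1 / (v + tau2)
  list(mu = sum(ws * y) / sum(ws), tau2 = tau2, Q = Q)
}

# Gaussian-process map pairs over an atlas, sharing one covariance factor
gp_map <- function(chol_K, atlas, modality = "thickness") {
  effect_size_map(atlas, drop(crossprod(chol_K, stats::rnorm(ncol(chol_K)))),
                  measure = "cohens_d", modality = modality)
}

gp_chol <- function(atlas, correlation_length = 0.8) {
  D <- geodesic_distance_matrix(atlas)
  K <- exp(-D / correlation_length)
  diag(K) <- diag(K) + 1e-8
  chol(K)
}

# one-site subject table with a planted partial correlation between the
# trait and every region (covariates: age, sex, global)
planted_site <- function(n, rho, regions, seed = 1, sigma = 0.12,
                         scanners = 1) {
  set.seed(seed)
  z <- rnorm(n)
  age <- runif(n, 18, 60)
  sex <- rbinom(n, 1, 0.5)
  g <- rnorm(n)
  gamma <- rho * sigma / sqrt(1 - rho^2)
  Y <- sapply(regions, function(r) {
    2.5 - 0.01 * age + 0.03 * sex + 0.1 * g + gamma * z + rnorm(n, 0, sigma)
  })
  df <- data.frame(trait = 10 + 5 * z, age = age, sex = sex,
                   scanner = paste0("scan", sample.int(scanners, n, TRUE)),
                   smoking = rbinom(n, 1, 0.3), global = 2.5 + 0.1 * g)
  df <- cbind(df, as.data.frame(Y))
  attr(df, "site_id") <- "fixture"
  df
}
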