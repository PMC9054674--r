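test_that("random rotations are proper, deterministic, and directionally uniform", {
  set.seed(1)
  for (i in 1:20) {
    M <- random_rotation()
    expect_equal(crossprod(M), diag(3), tolerance = 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }

  set.seed(99)
  M1 <- random_rotation()
  set.seed(99)
  expect_identical(M1, random_rotation())

  # uniformity over SO(3): images of a fixed vector have tiny resultant
  set.seed(3)
  v <- c(1, 0, 0)
  imgs <- t(vapply(1:10000, function(i) drop(random_rotation() %*% v),
                   numeric(3)))
  expect_lt(sqrt(sum(colMeans(imgs)^2)), 0.05)
})

test_that("spin assignments are hemisphere-closed, reproducible, and prefix-stable", {
  at <- synthetic_sphere_atlas(16, seed = 2)
  left <- which(at$regions$hemisphere == "left")
  right <- which(at$regions$hemisphere == "right")

  sn <- build_spin_null(at, 40, seed = 7)
  expect_true(all(sn$assignments[left, ] %in% left))
  expect_true(all(sn$assignments[right, ] %in% right))

  sn2 <- build_spin_null(at, 40, seed = 7)
  expect_identical(sn$assignments, sn2$assignments)

  # extending the rotation count preserves the earlier null as a prefix
  sn80 <- build_spin_null(at, 80, seed = 7)
  expect_identical(sn80$assignments[, 1:40], sn$assignments)
})

test_that("nearest-centroid reassignment matches a brute-force search and fixes the identity", {
  at <- synthetic_sphere_atlas(12, seed = 5)
  L <- at$centroids[at$regions$hemisphere == "left", ]

  # identity rotation: every region keeps its own value
  expect_identical(roimeta:::hemi_assignment(L, L), seq_len(nrow(L)))

  set.seed(11)
  for (i in 1:10) {
    M <- random_rotation()
    rot <- L %*% t(M)
    got <- roimeta:::hemi_assignment(L, rot)
    # exhaustive pairwise oracle on geodesic distance
    want <- vapply(seq_len(nrow(L)), function(a) {
      d <- acos(pmin(1, pmax(-1, rot %*% L[a, ])))
      which.min(d)
    }, integer(1))
    expect_equal(got, want)
  }
})

test_that("one-to-one spins permute values within each hemisphere (conservation)", {
  at <- synthetic_sphere_atlas(10, seed = 3)
  left <- which(at$regions$hemisphere == "left")
  right <- which(at$regions$hemisphere == "right")
  sn <- build_spin_null(at, 25, seed = 4, one_to_one = TRUE)
  vals <- seq_len(20) * 1.5
  for (t in 1:25) {
    spun <- vals[sn$assignments[, t]]
    expect_equal(sort(spun[left]), sort(vals[left]))
    expect_equal(sort(spun[right]), sort(vals[right]))
  }
})

test_that("spin test handles identity, antisymmetry, and bounds on empirical p", {
  at <- synthetic_sphere_atlas(16, seed = 6)
  ck <- gp_chol(at)
  set.seed(2)
  a <- gp_map(ck, at)
  b <- gp_map(ck, at)
  sn <- build_spin_null(at, 200, seed = 8)

  self <- spin_test(a, a, sn)
  expect_equal(self$coefficient, 1)
  expect_gte(self$p_perm, 1 / 201)

  neg <- effect_size_map(at, -a$values, "cohens_d", "thickness")
  anti <- spin_test(a, neg, sn)
  expect_equal(anti$coefficient, -1)
  expect_equal(anti$p_perm, self$p_perm)  # two-sided null is sign-symmetric

  res <- spin_test(a, b, sn, tail = "greater")
  expect_true(res$p_perm > 0 && res$p_perm <= 1)
  expect_equal(length(res$nulls), 200)

  const <- effect_size_map(at, rep(0.2, 32), "cohens_d", "thickness")
  expect_error(spin_test(a, const, sn), "constant")
  sub <- effect_size_map(
    parcel_atlas(data.frame(name = subcortical_region_names(),
                            hemisphere = "none", class = "subcortical")),
    rnorm(14), "cohens_d", "subcortical_volume")
  expect_error(spin_test(a, sub, sn), "cortical")
})

test_that("label shuffling is rank-invariant with exact extreme-case p", {
  at <- parcel_atlas(data.frame(name = subcortical_region_names(),
                                hemisphere = "none", class = "subcortical"))
  set.seed(9)
  vals <- rnorm(14)
  a <- effect_size_map(at, vals, "cohens_d", "subcortical_volume")
  b <- effect_size_map(at, exp(2 * vals), "cohens_d", "subcortical_volume")

  res <- label_shuffle_test(a, b, n_perm = 1000, seed = 1, tail = "greater")
  expect_equal(res$coefficient, 1)
  expect_equal(res$p_perm, 1 / 1001)

  # p is invariant to a strictly increasing transform of map_b
  b2 <- effect_size_map(at, 3 * b$values^3 + 1, "cohens_d",
                        "subcortical_volume")
  c0 <- effect_size_map(at, rnorm(14), "cohens_d", "subcortical_volume")
  p1 <- label_shuffle_test(c0, b, n_perm = 500, seed = 2)$p_perm
  p2 <- label_shuffle_test(c0, b2, n_perm = 500, seed = 2)$p_perm
  expect_equal(p1, p2)

  expect_identical(label_shuffle_test(a, b, 100, seed = 5)$nulls,
                   label_shuffle_test(a, b, 100, seed = 5)$nulls)
})

test_that("spin and shuffle nulls agree in distribution without spatial autocorrelation", {
  at <- synthetic_sphere_atlas(34, seed = 10)
  set.seed(20)
  a <- effect_size_map(at, rnorm(68), "cohens_d", "thickness")
  b <- effect_size_map(at, rnorm(68), "cohens_d", "thickness")
  sn <- build_spin_null(at, 500, seed = 21, one_to_one = TRUE)
  spin_nulls <- spin_test(a, b, sn)$nulls

  set.seed(22)
  shuffle_nulls <- vapply(1:500, function(i) {
    cor(sample(a$values), b$values)
  }, numeric(1))
  # duplicate null draws tie occasionally; the approximate p suffices here
  ks <- suppressWarnings(stats::ks.test(spin_nulls, shuffle_nulls))
  expect_gt(ks$p.value, 0.01)
})

test_that("Steiger's test is null-centered, antisymmetric, and matches the stated formula", {
  s0 <- steiger_test(0.3, 0.3, 0.5, 68)
  expect_equal(s0$Z, 0)
  expect_equal(s0$p, 0.5)

  s1 <- steiger_test(0.4, 0.1, 0.3, 68)
  s2 <- steiger_test(0.1, 0.4, 0.3, 68)
  expect_equal(s1$Z, -s2$Z, tolerance = 1e-12)

  # hand evaluation of the dependent-correlation Z
  rbar <- (0.4 + 0.1) / 2
  cv <- (0.3 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - 0.09)) /
    (1 - rbar^2)^2
  zh <- (atanh(0.4) - atanh(0.1)) * sqrt((68 - 3) / (2 - 2 * cv))
  expect_equal(s1$Z, zh, tolerance = 1e-12)
  expect_equal(s1$p, pnorm(zh, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(steiger_test(1, 0.2, 0.1, 68), "\\(-1, 1\\)")
  expect_error(steiger_test(0.5, 0.2, 0.1, 3), "n > 3")
})
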