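#' Uniform random rotation of 3-space
#'
#' Draws a proper rotation matrix uniformly over SO(3): the QR
#' decomposition of a standard-Gaussian 3x3 matrix with the Q factor
#' sign-corrected so the diagonal of R is positive (Haar measure on O(3)),
#' then a column flip forcing determinant +1. Consumes the current RNG
#' stream; seed control belongs to the caller (see [build_spin_null()]).
#'
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qrd <- qr(M)
  Q <- qr.Q(qrd)
  R <- qr.R(qrd)
  Q <- Q %*% diag(sign(diag(R)))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Build a spin-permutation null for a bilateral cortical atlas
#'
#' For each of `n_rotations` draws a uniform rotation `M`, rotates the
#' left-hemisphere centroids by `M` and the right-hemisphere centroids by
#' the mirrored rotation `F M F` (with `F` the reflection through the
#' x = 0 plane), and reassigns each original region the value of the
#' nearest rotated centroid within its own hemisphere. Nearest-centroid
#' reassignment permits duplicates by default (some source regions used
#' twice, others dropped in a given rotation); `one_to_one = TRUE`
#' switches to a greedy one-to-one matching, since published
#' implementations differ on this point.
#'
#' @param atlas a bilateral [parcel_atlas()] with cortical centroids.
#' @param n_rotations number of random rotations.
#' @param seed integer seed; assignments are reproducible from
#'   `(atlas, n_rotations, seed)`, and extending `n_rotations` under the
#'   same seed preserves the earlier rotations as a prefix.
#' @param one_to_one logical; use greedy one-to-one matching instead of
#'   nearest-neighbor-with-duplicates.
#' @return Object of class `spin_null`: list with `atlas`, `n_rotations`,
#'   `seed`, `one_to_one`, and `assignments`, an integer matrix
#'   (cortical regions x rotations) mapping each region to the source
#'   region index whose value it receives.
#' @export
build_spin_null <- function(atlas, n_rotations = 10000, seed = 1L,
                            one_to_one = FALSE) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (!is_bilateral(atlas)) {
    stop("spin nulls require a bilateral cortical atlas", call. = FALSE)
  }
  cort <- atlas$regions[atlas$regions$class == "cortical", ]
  li <- which(cort$hemisphere == "left")
  ri <- which(cort$hemisphere == "right")
  L <- atlas$centroids[li, , drop = FALSE]
  R <- atlas$centroids[ri, , drop = FALSE]
  Fm <- diag(c(-1, 1, 1))

  assignments <- local_seed_eval(seed, {
    vapply(seq_len(n_rotations), function(t) {
      M <- random_rotation()
      Mr <- Fm %*% M %*% Fm
      a <- integer(nrow(cort))
      a[li] <- li[hemi_assignment(L, L %*% t(M), one_to_one)]
      a[ri] <- ri[hemi_assignment(R, R %*% t(Mr), one_to_one)]
      a
    }, integer(nrow(cort)))
  })
  structure(list(atlas = atlas, n_rotations = as.integer(n_rotations),
                 seed = as.integer(seed), one_to_one = one_to_one,
                 assignments = assignments),
            class = "spin_null")
}

# Map each original centroid (rows of `orig`) to the nearest rotated
# centroid (rows of `rot`), by maximal dot product on the unit sphere.
hemi_assignment <- function(orig, rot, one_to_one = FALSE) {
  dots <- tcrossprod(orig, rot)
  if (!one_to_one) {
    return(max.col(dots, ties.method = "first"))
  }
  n <- nrow(dots)
  out <- integer(n)
  for (step in seq_len(n)) {
    best <- arrayInd(which.max(dots), dim(dots))
    out[best[1]] <- best[2]
    dots[best[1], ] <- -Inf
    dots[, best[2]] <- -Inf
  }
  out
}

empirical_p <- function(obs, nulls, tail) {
  m <- length(nulls)
  b <- switch(tail,
    two_sided = sum(abs(nulls) >= abs(obs)),
    greater   = sum(nulls >= obs),
    less      = sum(nulls <= obs)
  )
  (1 + b) / (1 + m)
}

similarity_result <- function(coefficient, p_perm, tail, n_perm, method,
                              nulls) {
  structure(list(coefficient = coefficient, p_perm = p_perm, tail = tail,
                 n_perm = as.integer(n_perm), method = method,
                 nulls = nulls),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> %s: coefficient=%.4f, p_perm=%.4g (%s, %d permutations)\n",
              x$method, x$coefficient, x$p_perm, x$tail, x$n_perm))
  invisible(x)
}

align_map <- function(map, regions) {
  miss <- setdiff(regions, names(map$values))
  if (length(miss)) {
    stop("map does not cover atlas region(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  unname(map$values[regions])
}

#' Spin permutation test for cortical map similarity
#'
#' Correlates two cortical effect-size maps (Pearson) and assigns
#' significance against a spatial-autocorrelation-preserving null built
#' by spherical rotation of the parcel centroids ([build_spin_null()]):
#' `map_a` is spun, `map_b` held fixed, and the empirical p-value uses
#' the add-one estimator `(1 + b) / (1 + n_rotations)`.
#'
#' @param map_a,map_b cortical [effect_size_map()]s on the null's atlas
#'   (`map_a` is the map that gets rotated).
#' @param null a [build_spin_null()] object.
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`.
#' @return A `similarity_result` with the observed coefficient, empirical
#'   p-value and the full null distribution.
#' @export
spin_test <- function(map_a, map_b, null,
                      tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(inherits(map_a, "effect_size_map"),
            inherits(map_b, "effect_size_map"),
            inherits(null, "spin_null"))
  if (map_a$modality == "subcortical_volume" ||
      map_b$modality == "subcortical_volume") {
    stop("spin tests apply to cortical maps only; use label_shuffle_test()",
         call. = FALSE)
  }
  regions <- atlas_regions(null$atlas, "cortical")
  a <- align_map(map_a, regions)
  b <- align_map(map_b, regions)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant map: correlation undefined", call. = FALSE)
  }
  obs <- stats::cor(a, b)
  A <- matrix(a[null$assignments], nrow = length(regions))
  nulls <- as.numeric(stats::cor(A, b))
  similarity_result(obs, empirical_p(obs, nulls, tail), tail,
                    null$n_rotations, "spin", nulls)
}

#' Label-shuffle permutation test for subcortical map similarity
#'
#' Spearman rank correlation of two subcortical maps, with significance
#' from uniformly random permutations of `map_a`'s region labels —
#' subcortical structures have no spherical embedding, so rotation nulls
#' do not apply.
#'
#' @param map_a,map_b subcortical [effect_size_map()]s over the same
#'   region set (`map_a` is shuffled).
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`.
#' @return A `similarity_result`.
#' @export
label_shuffle_test <- function(map_a, map_b, n_perm = 10000, seed = 1L,
                               tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(inherits(map_a, "effect_size_map"),
            inherits(map_b, "effect_size_map"))
  regions <- names(map_b$values)
  if (!setequal(regions, names(map_a$values))) {
    stop("maps cover different region sets", call. = FALSE)
  }
  a <- align_map(map_a, regions)
  b <- align_map(map_b, regions)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant map: correlation undefined", call. = FALSE)
  }
  obs <- stats::cor(a, b, method = "spearman")
  ra <- rank(a)
  rb <- rank(b)
  n <- length(a)
  perms <- local_seed_eval(seed, {
    vapply(seq_len(n_perm), function(t) sample.int(n), integer(n))
  })
  A <- matrix(ra[perms], nrow = n)
  nulls <- as.numeric(stats::cor(A, rb))
  similarity_result(obs, empirical_p(obs, nulls, tail), tail, n_perm,
                    "label_shuffle", nulls)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Compares `r_jk` and `r_jh` — the correlations of maps k and h with a
#' shared map j — accounting for the correlation `r_kh` between k and h.
#' With `rbar = (r_jk + r_jh)/2`,
#' `c = (r_kh (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_kh^2)/2) / (1 - rbar^2)^2`
#' and
#' `Z = (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 - 2c))`,
#' referred to the standard normal; the one-tailed p tests
#' `r_jk > r_jh`.
#'
#' @param r_jk,r_jh,r_kh pairwise correlations, each in (-1, 1).
#' @param n number of paired observations (here: regions); must exceed 3.
#' @param tail `"greater"` (one-tailed, the default), `"two_sided"` or
#'   `"less"`.
#' @return list with `Z`, `p`, `n`, `r_jk`, `r_jh`, `r_kh`, `tail`.
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n,
                         tail = c("greater", "two_sided", "less")) {
  tail <- match.arg(tail)
  rs <- c(r_jk, r_jh, r_kh)
  if (any(abs(rs) >= 1)) stop("correlations must lie in (-1, 1)", call. = FALSE)
  if (n <= 3) stop("need n > 3", call. = FALSE)
  rbar <- (r_jk + r_jh) / 2
  cval <- (r_kh * (1 - 2 * rbar^2) -
             0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)) / (1 - rbar^2)^2
  Z <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 - 2 * cval))
  p <- switch(tail,
    greater   = stats::pnorm(Z, lower.tail = FALSE),
    less      = stats::pnorm(Z),
    two_sided = 2 * stats::pnorm(-abs(Z))
  )
  list(Z = Z, p = p, n = n, r_jk = r_jk, r_jh = r_jh, r_kh = r_kh,
       tail = tail)
}
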