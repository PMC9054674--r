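#' Construct a parcellation atlas
#'
#' A `parcel_atlas` is the shared coordinate frame for every map and
#' subject table handled by the package: an ordered set of named regions,
#' each cortical region carrying a unit-sphere centroid. Subcortical
#' regions carry no geometry, and any geometric operation invoked on them
#' errors rather than silently skipping (spherical rotation nulls are only
#' meaningful for cortex).
#'
#' @param regions data.frame with columns `name` (unique strings),
#'   `hemisphere` (`"left"`, `"right"` or `"none"`) and `class`
#'   (`"cortical"` or `"subcortical"`).
#' @param centroids numeric matrix with one row per *cortical* region (in
#'   the order they appear in `regions`) and columns x, y, z. Rows must
#'   have Euclidean norm within `1e-6` of 1 and are renormalized to exactly
#'   unit length.
#'
#' @return An object of class `parcel_atlas`: a list with elements
#'   `regions` (the validated data.frame) and `centroids` (matrix with
#'   rownames set to the cortical region names; `NULL` if the atlas has no
#'   cortical regions).
#' @export
parcel_atlas <- function(regions, centroids = NULL) {
  stopifnot(is.data.frame(regions))
  required <- c("name", "hemisphere", "class")
  if (!all(required %in% names(regions))) {
    stop("`regions` must have columns name, hemisphere, class", call. = FALSE)
  }
  regions <- regions[, required]
  regions$name <- as.character(regions$name)
  regions$hemisphere <- as.character(regions$hemisphere)
  regions$class <- as.character(regions$class)

  if (anyDuplicated(regions$name)) {
    stop("duplicate region names: ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_hemi <- setdiff(unique(regions$hemisphere), c("left", "right", "none"))
  if (length(bad_hemi)) {
    stop("unknown hemisphere code: ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(regions$class), c("cortical", "subcortical"))
  if (length(bad_class)) {
    stop("unknown structure class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }

  cortical <- regions$class == "cortical"
  n_cort <- sum(cortical)
  if (n_cort > 0) {
    if (is.null(centroids)) {
      stop("cortical regions require centroids", call. = FALSE)
    }
    centroids <- as.matrix(centroids)
    if (nrow(centroids) != n_cort || ncol(centroids) != 3) {
      stop("`centroids` must be a ", n_cort, " x 3 matrix", call. = FALSE)
    }
    storage.mode(centroids) <- "double"
    norms <- sqrt(rowSums(centroids^2))
    off <- abs(norms - 1) > 1e-6
    if (any(off)) {
      stop("non-normalizable centroid (|norm - 1| > 1e-6) for region(s): ",
           paste(regions$name[cortical][off], collapse = ", "), call. = FALSE)
    }
    centroids <- centroids / norms
    rownames(centroids) <- regions$name[cortical]
    colnames(centroids) <- c("x", "y", "z")
  } else {
    centroids <- NULL
  }

  structure(list(regions = regions, centroids = centroids),
            class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  n_cort <- sum(x$regions$class == "cortical")
  n_sub <- sum(x$regions$class == "subcortical")
  cat("<parcel_atlas> ", nrow(x$regions), " regions (",
      n_cort, " cortical, ", n_sub, " subcortical)",
      if (is_bilateral(x)) ", bilateral cortex" else "", "\n", sep = "")
  invisible(x)
}

#' Region names of one structure class
#'
#' @param atlas a `parcel_atlas`.
#' @param class `"cortical"` or `"subcortical"`.
#' @return Character vector of region names in atlas order.
#' @export
atlas_regions <- function(atlas, class = c("cortical", "subcortical")) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  class <- match.arg(class)
  atlas$regions$name[atlas$regions$class == class]
}

#' @rdname atlas_regions
#' @export
is_bilateral <- function(atlas) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  cort <- atlas$regions[atlas$regions$class == "cortical", ]
  nrow(cort) > 0 && sum(cort$hemisphere == "left") == sum(cort$hemisphere == "right") &&
    all(cort$hemisphere %in% c("left", "right"))
}

#' Read a parcellation atlas from a delimited file
#'
#' Expects comma-delimited UTF-8 text with header
#' `name,hemisphere,class,x,y,z`; the coordinate fields are empty for
#' subcortical regions. Centroids within `1e-6` of unit norm are
#' renormalized; anything further off is an error.
#'
#' @param path file path.
#' @return A [parcel_atlas()].
#' @export
load_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "hemisphere", "class", "x", "y", "z")
  if (!all(required %in% names(df))) {
    stop("atlas file must have columns name,hemisphere,class,x,y,z",
         call. = FALSE)
  }
  cortical <- df$class == "cortical"
  if (any(cortical)) {
    xyz <- as.matrix(df[cortical, c("x", "y", "z")])
    if (anyNA(xyz)) {
      stop("cortical region with missing centroid coordinates", call. = FALSE)
    }
  } else {
    xyz <- NULL
  }
  parcel_atlas(df[, c("name", "hemisphere", "class")], xyz)
}

#' Write a parcellation atlas to a delimited file
#'
#' @param atlas a `parcel_atlas`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  df <- atlas$regions
  df$x <- df$y <- df$z <- NA_real_
  cort <- df$class == "cortical"
  if (any(cort)) {
    df[cort, c("x", "y", "z")] <- atlas$centroids
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Generate a synthetic bilateral spherical atlas
#'
#' Places `n_per_hemisphere` approximately evenly spaced centroids on the
#' left (x < 0) half of the unit sphere using a Fibonacci lattice, then
#' mirrors them through the x = 0 plane to form the right hemisphere. The
#' seed only rotates the lattice about the x axis, so atlases with the
#' same `n_per_hemisphere` differ between seeds but are always
#' mirror-symmetric and deterministic.
#'
#' @param n_per_hemisphere number of cortical parcels per hemisphere
#'   (at least 4); 34 mimics a standard whole-cortex parcellation.
#' @param seed integer seed for the deterministic lattice orientation.
#' @param subcortical optional character vector of subcortical region
#'   names to append (no geometry).
#' @return A bilateral [parcel_atlas()] with `2 * n_per_hemisphere`
#'   cortical regions.
#' @export
synthetic_sphere_atlas <- function(n_per_hemisphere, seed = 1L,
                                   subcortical = NULL) {
  if (n_per_hemisphere < 4) {
    stop("n_per_hemisphere must be >= 4", call. = FALSE)
  }
  n <- as.integer(n_per_hemisphere)
  golden <- pi * (3 - sqrt(5))
  offset <- local_seed_eval(seed, stats::runif(1, 0, 2 * pi))
  i <- seq_len(n)
  # lattice on the open x < 0 half-sphere
  x <- -(i - 0.5) / n
  rad <- sqrt(pmax(0, 1 - x^2))
  phi <- i * golden + offset
  left <- cbind(x = x, y = rad * cos(phi), z = rad * sin(phi))
  right <- left
  right[, 1] <- -right[, 1]

  fmt <- paste0("%0", max(2, nchar(n)), "d")
  names_l <- sprintf(paste0("L_region_", fmt), i)
  names_r <- sprintf(paste0("R_region_", fmt), i)
  regions <- data.frame(
    name = c(names_l, names_r),
    hemisphere = rep(c("left", "right"), each = n),
    class = "cortical",
    stringsAsFactors = FALSE
  )
  centroids <- rbind(left, right)
  if (!is.null(subcortical)) {
    regions <- rbind(regions, data.frame(
      name = as.character(subcortical),
      hemisphere = "none",
      class = "subcortical",
      stringsAsFactors = FALSE
    ))
  }
  parcel_atlas(regions, centroids)
}

#' Geodesic (great-circle) distance matrix between cortical centroids
#'
#' @param atlas a `parcel_atlas` with cortical centroids.
#' @return Symmetric matrix of arc lengths in radians, entry (i, j) =
#'   arccos of the (clamped) dot product of unit centroids i and j; zero
#'   diagonal. Rows/columns follow cortical atlas order.
#' @export
geodesic_distance_matrix <- function(atlas) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (is.null(atlas$centroids)) {
    stop("atlas has no cortical centroids; geodesic distances are undefined",
         call. = FALSE)
  }
  dots <- tcrossprod(atlas$centroids)
  dots <- pmin(pmax(dots, -1), 1)
  d <- acos(dots)
  diag(d) <- 0
  d
}

#' Construct an effect-size map aligned to an atlas
#'
#' @param atlas a `parcel_atlas`.
#' @param values numeric vector, one value per atlas region of the
#'   structure class implied by `modality`, in atlas order (or named by
#'   region, in which case it is reordered).
#' @param measure `"partial_r"` (values constrained to \[-1, 1\]) or
#'   `"cohens_d"`.
#' @param modality `"thickness"`, `"surface_area"` or
#'   `"subcortical_volume"`.
#' @return An object of class `effect_size_map`.
#' @export
effect_size_map <- function(atlas, values,
                            measure = c("partial_r", "cohens_d"),
                            modality = c("thickness", "surface_area",
                                         "subcortical_volume")) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  measure <- match.arg(measure)
  modality <- match.arg(modality)
  class_ <- modality_class(modality)
  regions <- atlas_regions(atlas, class_)
  if (!is.null(names(values))) {
    missing <- setdiff(regions, names(values))
    if (length(missing)) {
      stop("values missing for region(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    values <- values[regions]
  }
  values <- as.numeric(values)
  if (length(values) != length(regions)) {
    stop("expected ", length(regions), " values for ", class_,
         " regions, got ", length(values), call. = FALSE)
  }
  if (anyNA(values)) stop("effect-size map contains NA", call. = FALSE)
  if (measure == "partial_r" && any(abs(values) > 1)) {
    stop("partial_r values must lie in [-1, 1]", call. = FALSE)
  }
  names(values) <- regions
  structure(list(atlas = atlas, values = values, measure = measure,
                 modality = modality),
            class = "effect_size_map")
}

#' @export
print.effect_size_map <- function(x, ...) {
  cat("<effect_size_map> ", length(x$values), " regions, measure=",
      x$measure, ", modality=", x$modality,
      sprintf(", range [%.3f, %.3f]\n", min(x$values), max(x$values)),
      sep = "")
  invisible(x)
}

modality_class <- function(modality) {
  if (modality == "subcortical_volume") "subcortical" else "cortical"
}

#' Read / write effect-size map files
#'
#' Maps are stored as delimited text with columns `name,value` and joined
#' to the atlas by region name (order-insensitive).
#'
#' @param path file path.
#' @inheritParams effect_size_map
#' @return [read_effect_map()] returns an `effect_size_map`;
#'   [write_effect_map()] returns `path` invisibly.
#' @export
read_effect_map <- function(path, atlas,
                            measure = c("partial_r", "cohens_d"),
                            modality = c("thickness", "surface_area",
                                         "subcortical_volume")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(df))) {
    stop("effect map file must have columns name,value", call. = FALSE)
  }
  effect_size_map(atlas, stats::setNames(df$value, df$name),
                  measure = measure, modality = modality)
}

#' @rdname read_effect_map
#' @param map an `effect_size_map`.
#' @export
write_effect_map <- function(map, path) {
  stopifnot(inherits(map, "effect_size_map"))
  utils::write.csv(
    data.frame(name = names(map$values),
               value = sprintf("%.17g", unname(map$values))),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
local_seed_eval <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
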