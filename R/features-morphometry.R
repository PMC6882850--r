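#' Morphometric nuclear features (44 features)
#'
#' Seven summary statistics (mean, median, sd, min, max, skewness,
#' kurtosis) of six per-nucleus size/shape descriptors -- area, major axis
#' length, minor axis length, solidity, eccentricity and compactness
#' (perimeter^2 / (4 pi area)) -- plus the mean neighbourhood radius (half
#' the nearest-centroid distance) and the nucleus-to-cytoplasm total area
#' ratio: 7 x 6 + 1 + 1 = 44.
#'
#' Degenerate inputs are zero-filled with validity flags: no nuclei clears
#' the whole block, a single nucleus clears the spread statistics and the
#' neighbourhood radius, an empty cytoplasm mask clears the N:C ratio.
#'
#' @param records Per-nucleus tibble from [finalize_nuclei()].
#' @param cytoplasm Logical cytoplasm mask.
#' @return Tibble with 44 rows.
#' @export
morphometric_features <- function(records, cytoplasm) {
  assert_mask(cytoplasm)
  descriptors <- c("area", "major", "minor", "solidity", "eccentricity",
                   "compactness")
  stat_names <- c("mean", "median", "sd", "min", "max", "skewness", "kurtosis")
  nms <- c(
    paste0("morph_", rep(descriptors, each = 7), "_", rep(stat_names, 6)),
    "morph_neighborhood_radius",
    "morph_nc_ratio"
  )
  n <- nrow(records)
  if (n == 0L) {
    return(feature_row(nms, "morphometry", 0, valid = FALSE))
  }
  desc <- cbind(
    area = records$area,
    major = records$major,
    minor = records$minor,
    solidity = records$solidity,
    eccentricity = records$eccentricity,
    compactness = records$perimeter^2 / (4 * pi * records$area)
  )
  vals <- as.vector(apply(desc, 2, seven_stats))
  if (n >= 2L) {
    dm <- as.matrix(stats::dist(cbind(records$x, records$y)))
    diag(dm) <- Inf
    nn <- apply(dm, 1, min)
    radius <- mean(nn / 2)
    radius_valid <- TRUE
  } else {
    radius <- 0
    radius_valid <- FALSE
  }
  cyto_area <- sum(cytoplasm)
  nc <- if (cyto_area > 0) sum(records$area) / cyto_area else NA_real_
  out <- feature_row(
    nms, "morphometry",
    c(vals, radius, nc),
    valid = c(rep(TRUE, 42), radius_valid, cyto_area > 0)
  )
  finalize_block(out)
}

delaunay_triangles <- function(x, y) {
  tl <- tryCatch(
    deldir::triang.list(deldir::deldir(x, y, suppressMsge = TRUE)),
    error = function(e) list()
  )
  if (length(tl) == 0L) return(NULL)
  area <- vapply(tl, function(t) {
    abs(sum(t$x * (c(t$y[-1], t$y[1]) - c(t$y[3], t$y[-3])))) / 2
  }, numeric(1))
  perimeter <- vapply(tl, function(t) {
    sum(sqrt(diff(c(t$x, t$x[1]))^2 + diff(c(t$y, t$y[1]))^2))
  }, numeric(1))
  tibble::tibble(area = area, perimeter = perimeter)
}

#' Delaunay topology features of the nuclear architecture (8 features)
#'
#' Triangulates the nucleus centroids and summarises the Delaunay triangle
#' areas and perimeters by mean, maximum, minimum and disorder, where
#' disorder = 1 - 1 / (1 + sd/mean). Crowded, proliferating nuclei shrink
#' the mean triangle perimeter; regular arrangements drive disorder toward
#' zero.
#'
#' @param centroids Two-column matrix or data frame of (x, y) centroids.
#' @return Tibble with 8 rows; fewer than 3 non-collinear centroids give a
#'   zero-filled block with cleared flags.
#' @export
topology_features <- function(centroids) {
  nms <- paste0("topo_", rep(c("area", "perimeter"), each = 4), "_",
                rep(c("mean", "max", "min", "disorder"), 2))
  centroids <- as.matrix(centroids)
  tri <- if (nrow(centroids) >= 3L) {
    delaunay_triangles(centroids[, 1], centroids[, 2])
  } else {
    NULL
  }
  if (is.null(tri) || nrow(tri) == 0L) {
    return(feature_row(nms, "topology", 0, valid = FALSE))
  }
  four_stats <- function(v) {
    m <- mean(v)
    s <- if (length(v) > 1L) sd(v) else 0
    c(m, max(v), min(v), 1 - 1 / (1 + s / m))
  }
  finalize_block(
    feature_row(nms, "topology", c(four_stats(tri$area), four_stats(tri$perimeter)))
  )
}
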