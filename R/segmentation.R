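#' Segment the epithelial layer from an H&E crop
#'
#' The red channel gives the best epithelium/background contrast in H&E
#' tongue sections. The channel is smoothed with an edge-preserving median
#' filter, binarised with a global Otsu threshold (polarity such that the
#' darker, stained side is tissue), holes are filled, small spurious regions
#' are removed by morphological opening, and holes opened up by the opening
#' are re-filled so the returned mask is hole-free.
#'
#' @param rgb H x W x 3 array, 8-bit scale.
#' @param smooth_radius Median filter radius in pixels. The default is large
#'   enough to average isolated nuclei into the surrounding cytoplasm so that
#'   the band thresholds as one tissue region.
#' @param opening_radius Disc radius of the despeckling opening.
#'
#' @return Logical epithelium mask.
#' @export
segment_epithelium <- function(rgb, smooth_radius = 9L, opening_radius = 5L) {
  assert_rgb_image(rgb)
  red <- rgb[, , 1]
  if (diff(range(red)) < 1e-8) {
    warning("uniform image: threshold undefined, returning empty mask",
            call. = FALSE)
    return(matrix(FALSE, nrow(red), ncol(red)))
  }
  smoothed <- EBImage::medianFilter(red / 255, smooth_radius) * 255
  thr <- otsu_threshold(smoothed)
  mask <- smoothed <= thr            # stained tissue is the darker side
  mask <- fill_holes(mask)
  mask <- as_binary(EBImage::opening(mask * 1, disc_brush(opening_radius)) > 0)
  fill_holes(mask)
}

#' Blue-ratio transform
#'
#' Emphasises blue-dominant (nuclear) pixels:
#' `[B / (1 + R + G)] / (1 + R + G + B)` on 8-bit channel values. Used both
#' for assigning k-means clusters to roles and as the landscape for
#' watershed splitting of touching nuclei.
#'
#' @param rgb H x W x 3 array, 8-bit scale.
#' @return Non-negative numeric matrix.
#' @export
blue_ratio_image <- function(rgb) {
  assert_rgb_image(rgb)
  r <- rgb[, , 1]
  g <- rgb[, , 2]
  b <- rgb[, , 3]
  (b / (1 + r + g)) / (1 + r + g + b)
}

mean_red_blue_ratio <- function(rgb, idx) {
  r <- rgb[, , 1][idx]
  b <- pmax(rgb[, , 3][idx], 1)
  mean(r / b)
}

#' Partition the epithelium into nuclei, cytoplasm and background
#'
#' k-means (k = 3, Euclidean distance) on the RGB values of epithelial
#' pixels. Cluster-to-role assignment is by colour semantics, not cluster
#' index: nuclei is the cluster with the highest mean blue-ratio, background
#' the brightest remaining cluster, cytoplasm the rest. Initial centres are
#' the mean colours of the luminance terciles, which makes the clustering
#' deterministic. With fewer than three distinct colours the same role rules
#' are applied to however many clusters exist and missing roles come back
#' empty.
#'
#' @param rgb H x W x 3 array, 8-bit.
#' @param epithelium Logical mask from [segment_epithelium()].
#'
#' @return List of logical masks `nuclei`, `cytoplasm`, `background`.
#' @export
partition_epithelium <- function(rgb, epithelium) {
  assert_rgb_image(rgb)
  assert_mask(epithelium)
  idx <- which(epithelium)
  if (length(idx) == 0L) stop("epithelium mask is empty", call. = FALSE)
  pix <- cbind(rgb[, , 1][idx], rgb[, , 2][idx], rgb[, , 3][idx])
  distinct <- unique(round(pix))
  k <- min(3L, nrow(distinct))
  if (k < 3L) {
    assignment <- match(
      apply(round(pix), 1, paste, collapse = ","),
      apply(distinct, 1, paste, collapse = ",")
    )
    centers <- distinct
  } else {
    lum <- pix %*% c(0.299, 0.587, 0.114)
    qs <- quantile(lum, c(1 / 3, 2 / 3))
    groups <- 1L + (lum > qs[1]) + (lum > qs[2])
    init <- rbind(
      colMeans(pix[groups == 1L, , drop = FALSE]),
      colMeans(pix[groups == 2L, , drop = FALSE]),
      colMeans(pix[groups == 3L, , drop = FALSE])
    )
    if (anyNA(init) || any(duplicated(round(init, 6)))) {
      init <- distinct[round(seq(1, nrow(distinct), length.out = 3)), ]
    }
    # fit on a deterministic subsample for speed, then assign all pixels
    # to the nearest fitted centre
    fit_idx <- if (nrow(pix) > 20000L) {
      unique(round(seq(1, nrow(pix), length.out = 20000L)))
    } else {
      seq_len(nrow(pix))
    }
    km <- kmeans(pix[fit_idx, , drop = FALSE], centers = init, iter.max = 100L)
    centers <- km$centers
    d2 <- vapply(seq_len(nrow(centers)), function(k) {
      (pix[, 1] - centers[k, 1])^2 + (pix[, 2] - centers[k, 2])^2 +
        (pix[, 3] - centers[k, 3])^2
    }, numeric(nrow(pix)))
    assignment <- max.col(-d2, ties.method = "first")
  }
  br_center <- (centers[, 3] / (1 + centers[, 1] + centers[, 2])) /
    (1 + rowSums(centers))
  lum_center <- centers %*% c(0.299, 0.587, 0.114)
  roles <- rep(NA_character_, nrow(centers))
  nuc <- which.max(br_center)
  roles[nuc] <- "nuclei"
  rest <- setdiff(seq_len(nrow(centers)), nuc)
  if (length(rest) > 0L) {
    bg <- rest[which.max(lum_center[rest])]
    roles[bg] <- "background"
    roles[setdiff(rest, bg)] <- "cytoplasm"
  }
  make_mask <- function(role) {
    m <- matrix(FALSE, dim(rgb)[1], dim(rgb)[2])
    sel <- which(roles == role)
    if (length(sel) > 0L) m[idx[assignment %in% sel]] <- TRUE
    m
  }
  list(
    nuclei = make_mask("nuclei"),
    cytoplasm = make_mask("cytoplasm"),
    background = make_mask("background")
  )
}

#' Morphological cleanup of the raw nuclei mask
#'
#' In order: fill holes, dilate with a disc of radius 2, open with a disc of
#' radius 4, discard connected components with fewer than 50 pixels.
#'
#' @param mask Logical nuclei mask.
#' @param min_pixels Survival threshold (pixels).
#' @return Cleaned logical mask; every surviving component has at least
#'   `min_pixels` pixels.
#' @export
refine_nuclei_mask <- function(mask, min_pixels = 50L) {
  assert_mask(mask)
  m <- fill_holes(mask)
  m <- as_binary(EBImage::dilate(m * 1, disc_brush(2L)) > 0)
  m <- as_binary(EBImage::opening(m * 1, disc_brush(4L)) > 0)
  drop_small_components(m, min_pixels)
}

component_table <- function(labels, min_area_for_solidity = Inf) {
  n <- max(labels)
  if (n == 0L) {
    return(tibble::tibble(label = integer(0), area = integer(0),
                          solidity = numeric(0)))
  }
  area <- component_sizes(labels)
  sol <- rep(NA_real_, n)
  if (is.finite(min_area_for_solidity)) {
    big <- which(area > min_area_for_solidity)
    if (length(big) > 0L) {
      coords <- which(labels > 0L, arr.ind = TRUE)
      lab <- labels[labels > 0L]
      for (l in big) {
        sel <- lab == l
        sol[l] <- region_solidity(coords[sel, 1], coords[sel, 2])
      }
    }
  }
  tibble::tibble(label = seq_len(n), area = area, solidity = sol)
}

#' Split large nuclear clusters by repeated k-means
#'
#' Iteratively finds connected components with solidity below 0.9 and more
#' than 500 pixels, re-clusters each component's pixels into two RGB colour
#' groups (k-means, k = 2, deterministically initialised at the component's
#' least and most blue-ratio-extreme pixels) and removes the less
#' nuclear-looking (lower blue-ratio) group, which disconnects the darker
#' chromatin cores. The loop repeats until no trigger component remains or
#' an iteration cap is hit (warning; never loops forever). Afterwards,
#' components with mean red/blue ratio above 1.2 are removed as false
#' detections, holes are filled, and components below 25 pixels are
#' discarded.
#'
#' @param mask Logical nuclei mask.
#' @param rgb Aligned RGB array.
#' @param min_area Trigger area (pixels), default 500.
#' @param solidity_threshold Trigger solidity, default 0.9.
#' @param rb_cutoff False-detection red/blue cutoff, default 1.2.
#' @param min_pixels Final survival threshold, default 25.
#' @param max_iter Iteration cap.
#' @return Logical mask.
#' @export
split_large_clusters <- function(mask, rgb, min_area = 500L,
                                 solidity_threshold = 0.9,
                                 rb_cutoff = 1.2, min_pixels = 25L,
                                 max_iter = 20L) {
  assert_mask(mask)
  assert_rgb_image(rgb)
  m <- as_binary(mask)
  br <- blue_ratio_image(rgb)
  for (iter in seq_len(max_iter)) {
    labels <- label_components(m)
    comps <- component_table(labels, min_area_for_solidity = min_area)
    flagged <- comps$label[!is.na(comps$solidity) &
                             comps$solidity < solidity_threshold &
                             comps$area > min_area]
    if (length(flagged) == 0L) break
    changed <- FALSE
    for (l in flagged) {
      idx <- which(labels == l)
      pix <- cbind(rgb[, , 1][idx], rgb[, , 2][idx], rgb[, , 3][idx])
      if (nrow(unique(round(pix))) < 2L) next
      o_min <- which.min(br[idx])
      o_max <- which.max(br[idx])
      init <- pix[c(o_min, o_max), , drop = FALSE]
      if (all(init[1, ] == init[2, ])) next
      km <- kmeans(pix, centers = init, iter.max = 50L)
      br_c <- (km$centers[, 3] / (1 + km$centers[, 1] + km$centers[, 2])) /
        (1 + rowSums(km$centers))
      drop_cluster <- which.min(br_c)
      if (all(km$cluster == drop_cluster)) next
      m[idx[km$cluster == drop_cluster]] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
    if (iter == max_iter) {
      warning("split_large_clusters: iteration cap reached", call. = FALSE)
    }
  }
  labels <- label_components(m)
  if (max(labels) > 0L) {
    rb <- vapply(seq_len(max(labels)), function(l) {
      mean_red_blue_ratio(rgb, which(labels == l))
    }, numeric(1))
    m[labels %in% which(rb > rb_cutoff)] <- FALSE
  }
  m <- fill_holes(m)
  drop_small_components(m, min_pixels)
}

# Erase 1-px boundaries between distinct positive labels (4-connectivity)
# so that watershed regions become separate connected components.
cut_label_boundaries <- function(mask, labels) {
  H <- nrow(labels)
  W <- ncol(labels)
  cut <- matrix(FALSE, H, W)
  differs <- function(a, b) a > 0L & b > 0L & a != b
  cut[-H, ] <- cut[-H, ] | differs(labels[-H, ], labels[-1, ])
  cut[-1, ] <- cut[-1, ] | differs(labels[-1, ], labels[-H, ])
  cut[, -W] <- cut[, -W] | differs(labels[, -W], labels[, -1])
  cut[, -1] <- cut[, -1] | differs(labels[, -1], labels[, -W])
  mask & !cut
}

#' Split small nuclear clusters by marker-controlled watershed
#'
#' The five-step procedure, applied twice: (1) identify components with more
#' than 150 pixels and solidity below 0.9; (2) form the blue-ratio image;
#' (3) smooth it with an edge-preserving median filter; (4) run
#' marker-controlled watershed on the smoothed blue-ratio landscape inside
#' each flagged component (markers are the regional maxima of the landscape,
#' shallow maxima suppressed by `tolerance`), cutting the mask along
#' inter-region boundaries; (5) fill holes and discard fragments of split
#' components below 50 pixels.
#'
#' @param mask Logical nuclei mask.
#' @param rgb Aligned RGB array.
#' @param min_area Trigger area (pixels), default 150.
#' @param solidity_threshold Trigger solidity, default 0.9.
#' @param min_pixels Fragment survival threshold, default 50.
#' @param passes Number of repetitions of the procedure, default 2.
#' @param smooth_radius Median filter radius for the blue-ratio image.
#' @param tolerance Watershed tolerance on the [0, 1]-normalised landscape.
#' @return Logical mask.
#' @export
split_small_clusters <- function(mask, rgb, min_area = 150L,
                                 solidity_threshold = 0.9,
                                 min_pixels = 50L, passes = 2L,
                                 smooth_radius = 2L, tolerance = 0.05) {
  assert_mask(mask)
  assert_rgb_image(rgb)
  m <- as_binary(mask)
  br <- blue_ratio_image(rgb)
  brn <- br / max(br, 1e-12)
  smoothed <- EBImage::medianFilter(brn, smooth_radius)
  for (pass in seq_len(passes)) {
    labels <- label_components(m)
    comps <- component_table(labels, min_area_for_solidity = min_area)
    flagged <- comps$label[!is.na(comps$solidity) &
                             comps$solidity < solidity_threshold &
                             comps$area > min_area]
    if (length(flagged) == 0L) next
    for (l in flagged) {
      comp <- labels == l
      surface <- smoothed
      surface[!comp] <- 0
      ws <- EBImage::watershed(surface, tolerance = tolerance, ext = 1L)
      if (max(ws) < 2L) next
      new_mask <- cut_label_boundaries(comp, ws)
      new_mask <- fill_holes(new_mask)
      new_mask <- drop_small_components(new_mask, min_pixels)
      m[comp] <- new_mask[comp]
    }
  }
  m
}

fit_ellipse_moments <- function(rows, cols) {
  n <- length(rows)
  cx <- mean(cols)
  cy <- mean(rows)
  # second central moments with the 1/12 pixel-variance correction
  sxx <- var(cols) * (n - 1) / n + 1 / 12
  syy <- var(rows) * (n - 1) / n + 1 / 12
  sxy <- if (n > 1) cov(cols, rows) * (n - 1) / n else 0
  e <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  major <- 4 * sqrt(max(e$values[1], 0))
  minor <- 4 * sqrt(max(e$values[2], 0))
  orientation <- atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi
  list(cx = cx, cy = cy, major = major, minor = minor,
       orientation = orientation)
}

#' Finalise the nuclei mask into labelled nuclei with fitted ellipses
#'
#' Removes components whose mean red/blue ratio exceeds 1 (false
#' detections), labels the survivors, and records per-nucleus morphology: a
#' moment-based fitted ellipse (the smooth contour), area, perimeter,
#' solidity, eccentricity and mean red/blue ratio.
#'
#' @param mask Combined logical mask from the two splitting stages.
#' @param rgb Aligned RGB array.
#' @param rb_cutoff Removal cutoff on mean red/blue ratio, default 1.
#' @return List of class `nuclei_segmentation`: `labels` (integer matrix)
#'   and `records` (tibble, one row per nucleus). An empty mask is valid and
#'   yields zero nuclei.
#' @export
finalize_nuclei <- function(mask, rgb, rb_cutoff = 1) {
  assert_mask(mask)
  assert_rgb_image(rgb)
  labels <- label_components(mask)
  n <- max(labels)
  if (n > 0L) {
    rb <- vapply(seq_len(n), function(l) {
      mean_red_blue_ratio(rgb, which(labels == l))
    }, numeric(1))
    keep <- which(rb <= rb_cutoff)
    relabeled <- matrix(0L, nrow(labels), ncol(labels))
    coords_all <- which(labels > 0L, arr.ind = TRUE)
    lab_vals <- labels[labels > 0L]
    new_id <- match(lab_vals, keep)
    sel <- !is.na(new_id)
    relabeled[coords_all[sel, , drop = FALSE]] <- new_id[sel]
    labels <- relabeled
    rb <- rb[keep]
    n <- length(keep)
  }
  if (n == 0L) {
    return(structure(list(
      labels = labels,
      records = tibble::tibble(
        label = integer(0), x = numeric(0), y = numeric(0),
        major = numeric(0), minor = numeric(0), orientation = numeric(0),
        area = integer(0), perimeter = numeric(0), solidity = numeric(0),
        eccentricity = numeric(0), red_blue_ratio = numeric(0)
      )
    ), class = "nuclei_segmentation"))
  }
  perim <- EBImage::computeFeatures.shape(labels)[, "s.perimeter"]
  records <- purrr::map_dfr(seq_len(n), function(l) {
    coords <- which(labels == l, arr.ind = TRUE)
    fit <- fit_ellipse_moments(coords[, 1], coords[, 2])
    tibble::tibble(
      label = l,
      x = fit$cx, y = fit$cy,
      major = fit$major, minor = fit$minor,
      orientation = fit$orientation,
      area = nrow(coords),
      perimeter = unname(perim[l]),
      solidity = min(region_solidity(coords[, 1], coords[, 2]), 1),
      eccentricity = if (fit$major > 0) {
        sqrt(pmax(1 - (fit$minor / fit$major)^2, 0))
      } else 0,
      red_blue_ratio = rb[l]
    )
  })
  structure(list(labels = labels, records = records),
            class = "nuclei_segmentation")
}

#' Full tissue segmentation of one H&E crop
#'
#' Runs the whole cascade: epithelium segmentation, k-means partition into
#' nuclei/cytoplasm/background, morphological cleanup, large-cluster
#' splitting, small-cluster watershed splitting, and nucleus finalisation.
#' Nuclei are confined to the epithelium; within the epithelium the three
#' compartment masks form a partition.
#'
#' @param rgb H x W x 3 array, 8-bit.
#' @param params Optional list overriding stage parameters; see
#'   [segmentation_params()].
#' @return A `tissue_masks` list: `epithelium`, `nuclei_labels`,
#'   `nuclei` (records tibble), `cytoplasm`, `background`.
#' @export
segment_tissue <- function(rgb, params = segmentation_params()) {
  assert_rgb_image(rgb)
  p <- utils::modifyList(segmentation_params(), params)
  epi <- segment_epithelium(rgb, smooth_radius = p$epithelium_smooth_radius,
                            opening_radius = p$epithelium_opening_radius)
  if (!any(epi)) {
    empty <- matrix(FALSE, dim(rgb)[1], dim(rgb)[2])
    fin <- finalize_nuclei(empty, rgb, rb_cutoff = p$rb_final)
    return(structure(list(
      epithelium = epi, nuclei_labels = fin$labels, nuclei = fin$records,
      cytoplasm = empty, background = empty
    ), class = "tissue_masks"))
  }
  parts <- partition_epithelium(rgb, epi)
  m <- refine_nuclei_mask(parts$nuclei, min_pixels = p$refine_min_pixels)
  m <- split_large_clusters(
    m, rgb, min_area = p$large_min_area,
    solidity_threshold = p$solidity_threshold,
    rb_cutoff = p$rb_false_detection, min_pixels = p$large_min_pixels,
    max_iter = p$max_iter
  )
  m <- split_small_clusters(
    m, rgb, min_area = p$small_min_area,
    solidity_threshold = p$solidity_threshold,
    min_pixels = p$small_min_pixels, passes = p$small_passes,
    smooth_radius = p$blue_ratio_smooth_radius,
    tolerance = p$watershed_tolerance
  )
  m <- m & epi
  fin <- finalize_nuclei(m, rgb, rb_cutoff = p$rb_final)
  nuclei_mask <- fin$labels > 0L
  background <- parts$background & epi & !nuclei_mask
  cytoplasm <- epi & !nuclei_mask & !background
  structure(list(
    epithelium = epi,
    nuclei_labels = fin$labels,
    nuclei = fin$records,
    cytoplasm = cytoplasm,
    background = background
  ), class = "tissue_masks")
}

#' Default segmentation parameters
#'
#' All thresholds of the segmentation cascade in one place: the 0.9 solidity
#' trigger, the 500/150 px cluster triggers, the 50/25 px survival
#' thresholds, the 1.2 and 1.0 red/blue cutoffs, the disc radii 2 and 4,
#' and the smoothing/watershed settings.
#'
#' @return Named list of parameters.
#' @export
segmentation_params <- function() {
  list(
    epithelium_smooth_radius = 9L,
    epithelium_opening_radius = 5L,
    refine_min_pixels = 50L,
    large_min_area = 500L,
    large_min_pixels = 25L,
    small_min_area = 150L,
    small_min_pixels = 50L,
    small_passes = 2L,
    solidity_threshold = 0.9,
    rb_false_detection = 1.2,
    rb_final = 1,
    max_iter = 20L,
    blue_ratio_smooth_radius = 2L,
    watershed_tolerance = 0.05
  )
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat(sprintf("<tissue_masks> %d x %d, %d nuclei, epithelium %.1f%%\n",
              nrow(x$epithelium), ncol(x$epithelium),
              nrow(x$nuclei), 100 * mean(x$epithelium)))
  invisible(x)
}
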