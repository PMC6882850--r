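#' Box-counting fractal dimension of a binary image
#'
#' Counts, for each box size s on a geometric ladder of powers of three, the
#' minimal number N(s) of s x s boxes needed to cover the foreground
#' (minimised over grid offsets); the dimension is the least-squares slope
#' of log N(s) against log(1/s). A straight line has dimension ~1, a filled
#' square ~2, a depth-4 Sierpinski carpet ~log 8 / log 3. The triadic
#' ladder keeps box sizes commensurate with self-similar test patterns and
#' the offset minimisation follows the definition of the box dimension as a
#' minimal cover.
#'
#' @param bin Logical (or 0/1) matrix.
#' @return Scalar estimate; 0 (with attribute `valid = FALSE`) for an empty
#'   image.
#' @export
fractal_dimension <- function(bin) {
  assert_mask(bin)
  b <- as_binary(bin)
  if (!any(b)) {
    return(structure(0, valid = FALSE))
  }
  w <- which(b, arr.ind = TRUE)
  rows <- w[, 1] - min(w[, 1])
  cols <- w[, 2] - min(w[, 2])
  s_max <- max(min(dim(b)) / 3, 3)
  sizes <- 3^(0:floor(log(s_max) / log(3)))
  key <- max(rows, cols) + 1
  counts <- vapply(sizes, function(s) {
    offs <- unique(floor(c(0, s / 3, 2 * s / 3)))
    best <- Inf
    for (o1 in offs) {
      for (o2 in offs) {
        n <- length(unique(((rows + o1) %/% s) * key + (cols + o2) %/% s))
        best <- min(best, n)
      }
    }
    best
  }, numeric(1))
  keep <- counts > 0
  if (sum(keep) < 2L) return(structure(0, valid = FALSE))
  fit <- stats::lm.fit(cbind(1, log(1 / sizes[keep])), log(counts[keep]))
  structure(unname(fit$coefficients[2]), valid = TRUE)
}

# City-block distance to background; basis for boundary and skeleton.
cityblock_distmap <- function(bin) {
  d <- EBImage::distmap(as_binary(bin) * 1, metric = "manhattan")
  matrix(as.numeric(d), nrow(bin), ncol(bin))
}

# Region boundary: foreground pixels 4-adjacent to background (the region
# minus its erosion by the cross element).
region_boundary <- function(bin) {
  b <- as_binary(bin)
  if (!any(b)) return(b)
  cityblock_distmap(b) == 1
}

# Morphological skeleton for the cross structuring element. Equivalent to
# the classical union over k of erode_k(X) minus its opening, computed in
# closed form as the local (non-strict) maxima of the city-block distance
# transform.
region_skeleton <- function(bin) {
  b <- as_binary(bin)
  if (!any(b)) return(b)
  d <- cityblock_distmap(b)
  H <- nrow(d)
  W <- ncol(d)
  nb <- matrix(0, H, W)
  nb[-H, ] <- pmax(nb[-H, ], d[-1, ])
  nb[-1, ] <- pmax(nb[-1, ], d[-H, ])
  nb[, -W] <- pmax(nb[, -W], d[, -1])
  nb[, -1] <- pmax(nb[, -1], d[, -W])
  b & (d >= nb)
}

#' Segmentation-based fractal texture features (mSFTA, 64 features)
#'
#' Decomposes the masked grey-level content into binary images via
#' multi-level Otsu thresholds (n_t = 4): a first set \{I > t_i\} and a
#' second set of band images \{t_i < I <= t_{i+1}\} with the maximum grey
#' value closing the last band -- 2 n_t = 8 binary images. From each, the
#' boundary and the morphological skeleton are extracted (16 binary
#' images); each contributes its box-counting fractal dimension and pixel
#' count, plus the mean intensity and Shannon entropy of the grey image
#' under it (16 x 4 = 64 features). Empty decomposition images (e.g. when
#' duplicate thresholds collapse) give zeros with cleared validity flags.
#'
#' @param gray Numeric matrix on the 0-255 scale.
#' @param mask Logical mask.
#' @param n_thresholds Number of Otsu thresholds n_t, default 4.
#' @return Tibble with `16 * n_thresholds` rows.
#' @export
msfta_features <- function(gray, mask, n_thresholds = 4L) {
  assert_mask(mask)
  sets <- c("above", "band")
  derived <- c("boundary", "skeleton")
  measures <- c("fd", "pixels", "mean", "entropy")
  nms <- character(0)
  for (s in sets) {
    for (i in seq_len(n_thresholds)) {
      for (d in derived) {
        nms <- c(nms, sprintf("msfta_%s_t%d_%s_%s", s, i, d, measures))
      }
    }
  }

  idx <- which(mask)
  if (length(idx) < 2L || diff(range(gray[idx])) == 0) {
    return(feature_row(nms, "texture", 0, valid = FALSE))
  }
  thr <- multiotsu_thresholds(gray[idx], k = n_thresholds)
  t_max <- max(gray[idx])
  binaries <- list()
  for (s in sets) {
    for (i in seq_len(n_thresholds)) {
      if (i <= length(thr)) {
        if (s == "above") {
          b <- mask & gray > thr[i]
        } else {
          upper <- if (i < length(thr)) thr[i + 1] else t_max
          b <- mask & gray > thr[i] & gray <= upper
        }
      } else {
        b <- matrix(FALSE, nrow(gray), ncol(gray))   # collapsed threshold
      }
      binaries <- c(binaries, list(b))
    }
  }
  vals <- numeric(0)
  valid <- logical(0)
  for (b in binaries) {
    for (dfun in list(region_boundary, region_skeleton)) {
      db <- dfun(b)
      px <- gray[db]
      if (length(px) == 0L) {
        vals <- c(vals, 0, 0, 0, 0)
        valid <- c(valid, rep(FALSE, 4))
      } else {
        fd <- fractal_dimension(db)
        vals <- c(vals, as.numeric(fd), sum(db), mean(px), intensity_entropy(px))
        valid <- c(valid, isTRUE(attr(fd, "valid")), TRUE, TRUE, TRUE)
      }
    }
  }
  finalize_block(feature_row(nms, "texture", vals, valid = valid))
}
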