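# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators never disturb the session RNG.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_rgb_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 RGB array", arg), call. = FALSE)
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  invisible(mask)
}

as_binary <- function(mask) {
  storage.mode(mask) <- "logical"
  mask & !is.na(mask)
}

# ITU-R BT.601 luma, also the Y of YCbCr on full-range 8-bit channels.
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Euclidean disc structuring element: lattice points with x^2 + y^2 <= r^2
# (radius 4 has exactly 49 pixels, radius 2 has 13).
disc_brush <- function(radius) {
  r <- as.integer(radius)
  d <- seq(-r, r)
  (outer(d^2, d^2, `+`) <= radius^2) * 1
}

cross_kernel <- function() {
  matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
}

label_components <- function(mask) {
  m <- EBImage::bwlabel(as_binary(mask) * 1)
  storage.mode(m) <- "integer"
  m
}

component_sizes <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

drop_small_components <- function(mask, min_pixels) {
  labels <- label_components(mask)
  if (max(labels) == 0L) return(as_binary(mask))
  keep <- which(component_sizes(labels) >= min_pixels)
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  as_binary(EBImage::fillHull(as_binary(mask) * 1) > 0)
}

# Vectorised even-odd point-in-polygon (crossing number) test.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Convex-hull area of a pixel region, counted on the pixel grid so that it is
# commensurate with the plain pixel-count area (solidity <= 1 up to rounding).
convex_pixel_area <- function(rows, cols) {
  if (length(rows) < 3L) return(length(rows))
  h <- grDevices::chull(cols, rows)
  vx <- cols[h]
  vy <- rows[h]
  rr <- seq(min(rows), max(rows))
  cc <- seq(min(cols), max(cols))
  grid <- expand.grid(r = rr, c = cc)
  # dilate the hull by half a pixel via a small epsilon on the test point set
  inside <- points_in_polygon(grid$c, grid$r, vx, vy)
  on_vertex <- paste(grid$r, grid$c) %in% paste(rows, cols)
  max(sum(inside | on_vertex), length(rows))
}

region_solidity <- function(rows, cols) {
  length(rows) / convex_pixel_area(rows, cols)
}

# Otsu's threshold on 8-bit values; returns the threshold t maximising
# between-class variance, with classes {x <= t} and {x > t}.
otsu_threshold <- function(values) {
  values <- values[!is.na(values)]
  counts <- tabulate(pmin(pmax(floor(values), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w1 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  sigma_b <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L
}

# Multi-level Otsu by dynamic programming over the 256-bin histogram:
# maximises the between-class variance (equivalently sum of w * mu^2) for
# k thresholds / k + 1 classes. Returns the k thresholds (upper bounds of the
# first k classes, on the 0..255 scale).
multiotsu_thresholds <- function(values, k = 4L) {
  values <- values[!is.na(values)]
  counts <- tabulate(pmin(pmax(floor(values), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  cp <- c(0, cumsum(p))
  cip <- c(0, cumsum(p * levels))
  seg_score <- function(i, j) {
    # score of class spanning bins i..j (1-based over 256 bins)
    w <- cp[j + 1L] - cp[i]
    s <- cip[j + 1L] - cip[i]
    out <- ifelse(w > 0, s^2 / w, 0)
    out
  }
  n_class <- k + 1L
  neg <- -Inf
  f <- matrix(neg, n_class, 256L)
  arg <- matrix(0L, n_class, 256L)
  f[1, ] <- seg_score(1L, 1:256)
  for (cl in 2:n_class) {
    for (j in cl:256) {
      i <- cl:j                         # start bin of class `cl`
      cand <- f[cl - 1L, i - 1L] + seg_score(i, j)
      best <- which.max(cand)
      f[cl, j] <- cand[best]
      arg[cl, j] <- i[best]
    }
  }
  thr <- integer(k)
  j <- 256L
  for (cl in n_class:2) {
    i <- arg[cl, j]
    thr[cl - 1L] <- i - 2L              # upper bound of previous class, 0-based
    j <- i - 1L
  }
  unique(thr)
}

# Shannon entropy (base 2) of a 256-bin histogram of 8-bit intensities.
intensity_entropy <- function(values) {
  if (length(values) == 0L) return(0)
  counts <- tabulate(pmin(pmax(floor(values), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

moment_skewness <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (n < 2L || s == 0) return(NA_real_)
  mean((x - mean(x))^3) / (s * sqrt((n - 1) / n))^3
}

moment_kurtosis <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (n < 2L || s == 0) return(NA_real_)
  mean((x - mean(x))^4) / (s * sqrt((n - 1) / n))^4 - 3
}

# Seven summary statistics used throughout the feature bank. Degenerate
# spread statistics come back NA and are zero-filled (with validity flags)
# by the callers.
seven_stats <- function(x) {
  c(
    mean = mean(x),
    median = median(x),
    sd = if (length(x) > 1L) sd(x) else NA_real_,
    min = min(x),
    max = max(x),
    skewness = moment_skewness(x),
    kurtosis = moment_kurtosis(x)
  )
}

feature_row <- function(feature, family, value, valid = TRUE) {
  tibble::tibble(
    feature = feature,
    family = family,
    value = as.numeric(value),
    valid = valid
  )
}

# Zero-fill NA/NaN values, flagging them invalid; downstream consumers
# (selection, CV) must never see non-finite numbers.
finalize_block <- function(tbl) {
  bad <- !is.finite(tbl$value)
  tbl$valid[bad] <- FALSE
  tbl$value[bad] <- 0
  tbl
}
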