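#' Grey-level co-occurrence matrix for one offset
#'
#' Counts, over pairs of masked pixels separated by `offset = c(dr, dc)`, how
#' often level i is adjacent to level j, in both directions (symmetric), and
#' normalises by the number of comparisons so the entries are probabilities.
#' Pairs with either pixel outside the mask are dropped.
#'
#' @param levels Integer matrix of grey levels 1..n_levels, `NA` outside the
#'   mask.
#' @param offset Integer `c(dr, dc)` pixel displacement.
#' @param n_levels Number of grey levels.
#' @return `n_levels` x `n_levels` matrix summing to 1 (all-zero if no pairs).
#' @export
co_occurrence <- function(levels, offset, n_levels) {
  H <- nrow(levels)
  W <- ncol(levels)
  dr <- offset[1]
  dc <- offset[2]
  rows <- seq_len(H - abs(dr))
  cols <- seq_len(W - abs(dc))
  if (length(rows) == 0L || length(cols) == 0L) {
    return(matrix(0, n_levels, n_levels))
  }
  r0 <- if (dr >= 0) rows else rows + abs(dr)
  c0 <- if (dc >= 0) cols else cols + abs(dc)
  a <- levels[r0, c0, drop = FALSE]
  b <- levels[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  counts <- tabulate((a[ok] - 1L) * n_levels + b[ok], n_levels * n_levels)
  m <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

glcm_offsets <- function(distances = 1:4) {
  out <- list()
  for (d in distances) {
    out <- c(out, list(c(0L, d), c(d, 0L), c(d, d), c(d, -d)))
  }
  out
}

# The 13 Haralick statistics plus 6 further co-occurrence statistics, from a
# normalised (averaged) GLCM. Log base 2. Degenerate quantities are NA here
# and zero-filled with flags by the caller.
glcm_summary <- function(p) {
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(L) * px)
  mu_y <- sum(seq_len(L) * py)
  s_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  s_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))
  # distributions of i + j and i - j
  k_sum <- 2:(2 * L)
  p_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  k_diff <- 0:(L - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  hxy <- ent(p)
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)
  hx <- ent(px)
  hy <- ent(py)
  sum_avg <- sum(k_sum * p_sum)
  c(
    asm = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = if (s_x > 0 && s_y > 0) {
      (sum(i * j * p) - mu_x * mu_y) / (s_x * s_y)
    } else NA_real_,
    variance = sum((i - mu_x)^2 * p),
    idm = sum(p / (1 + (i - j)^2)),
    sum_average = sum_avg,
    sum_variance = sum((k_sum - sum_avg)^2 * p_sum),
    sum_entropy = ent(p_sum),
    entropy = hxy,
    difference_variance = sum((k_diff - sum(k_diff * p_diff))^2 * p_diff),
    difference_entropy = ent(p_diff),
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_,
    imc2 = sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    autocorrelation = sum(i * j * p),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    dissimilarity = sum(abs(i - j) * p),
    inverse_difference = sum(p / (1 + abs(i - j))),
    max_probability = max(p)
  )
}

#' GLCM texture features (19 features)
#'
#' Masked intensities are min-max rescaled to 64 grey levels; 16
#' co-occurrence matrices (four directions: horizontal, vertical, both
#' diagonals; four distances 1-4) are computed as symmetric probability
#' matrices and averaged; the 13 Haralick statistics and 6 further
#' statistics (autocorrelation, cluster prominence, cluster shade,
#' dissimilarity, inverse difference, maximum probability) are extracted
#' from the averaged matrix.
#'
#' A constant region yields angular second moment 1 and contrast 0, with
#' correlation flagged invalid.
#'
#' @param gray Numeric matrix of intensities (any range).
#' @param mask Logical mask.
#' @param n_levels Grey levels after rescaling, default 64.
#' @param distances Offset distances, default 1:4.
#' @return Tibble with 19 rows: `feature`, `family`, `value`, `valid`.
#' @export
glcm_features <- function(gray, mask, n_levels = 64L, distances = 1:4) {
  assert_mask(mask)
  nms <- paste0("glcm_", names(glcm_summary(diag(2) / 2)))
  idx <- which(mask)
  if (length(idx) < 2L) {
    return(feature_row(nms, "texture", 0, valid = FALSE))
  }
  x <- gray[idx]
  rng <- range(x)
  levels <- matrix(NA_integer_, nrow(gray), ncol(gray))
  if (diff(rng) == 0) {
    levels[idx] <- 1L
  } else {
    levels[idx] <- pmin(
      1L + as.integer(floor((x - rng[1]) / diff(rng) * n_levels)), n_levels
    )
  }
  mats <- lapply(glcm_offsets(distances), co_occurrence,
                 levels = levels, n_levels = n_levels)
  total <- vapply(mats, sum, numeric(1))
  if (all(total == 0)) {
    return(feature_row(nms, "texture", 0, valid = FALSE))
  }
  p <- Reduce(`+`, mats) / sum(total > 0)
  finalize_block(feature_row(nms, "texture", glcm_summary(p)))
}

# Frequency-domain Gabor transfer functions: a Gaussian blob centred at
# radial frequency f0 (cycles/pixel) and orientation theta, circular in the
# rotated frequency frame, sigma_f = f0 / 3 (~1 octave half-response
# bandwidth). Single-sided, so the spatial response is complex (analytic).
gabor_transfer <- function(H, W, f0, theta, bandwidth_ratio = 3) {
  fu <- (seq_len(W) - 1) / W
  fu[fu >= 0.5] <- fu[fu >= 0.5] - 1
  fv <- (seq_len(H) - 1) / H
  fv[fv >= 0.5] <- fv[fv >= 0.5] - 1
  FX <- matrix(fu, H, W, byrow = TRUE)
  FY <- matrix(fv, H, W)
  ur <- FX * cos(theta) + FY * sin(theta)
  vr <- -FX * sin(theta) + FY * cos(theta)
  s <- f0 / bandwidth_ratio
  exp(-((ur - f0)^2 + vr^2) / (2 * s^2))
}

#' Gabor filter-bank texture features (56 features)
#'
#' A bank of 28 Gabor filters: orientations \{0, pi/4, pi/2, 3pi/4\} crossed
#' with radial frequencies \{2\eqn{\sqrt2}, 4\eqn{\sqrt2}, ...,
#' 128\eqn{\sqrt2}\} cycles per image width (seven doublings). Filtering is
#' done in the frequency domain (single-sided Gaussian transfer, ~1-octave
#' bandwidth); for each filter the magnitude response over the mask is
#' summarised by its entropy (256-bin Shannon entropy of the magnitude
#' image normalised to its maximum) and energy (mean squared magnitude).
#'
#' @param gray Numeric matrix of intensities.
#' @param mask Logical mask; pixels outside are replaced by the masked mean
#'   before filtering and excluded from the summaries.
#' @return Tibble with 56 rows (28 filters x entropy, energy).
#' @export
gabor_features <- function(gray, mask) {
  assert_mask(mask)
  orientations <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  freqs <- 2^(1:7) * sqrt(2)
  grid <- expand.grid(freq = seq_along(freqs), theta = seq_along(orientations))
  nms <- as.vector(t(outer(
    sprintf("gabor_o%d_f%d", grid$theta, grid$freq),
    c("entropy", "energy"), paste, sep = "_"
  )))
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(feature_row(nms, "texture", 0, valid = FALSE))
  }
  H <- nrow(gray)
  W <- ncol(gray)
  img <- gray
  img[!mask] <- mean(gray[idx])
  FT <- stats::fft(img)
  vals <- numeric(0)
  for (k in seq_len(nrow(grid))) {
    f0 <- freqs[grid$freq[k]] / W          # cycles/px from cycles/image-width
    G <- gabor_transfer(H, W, f0, orientations[grid$theta[k]])
    mag <- Mod(stats::fft(FT * G, inverse = TRUE)) / (H * W)
    m <- mag[idx]
    mx <- max(m)
    entropy <- if (mx > 0) intensity_entropy(m / mx * 255) else 0
    energy <- mean(m^2)
    vals <- c(vals, entropy, energy)
  }
  finalize_block(feature_row(nms, "texture", vals))
}

#' Rotation-invariant uniform LBP histogram (10 features)
#'
#' Local binary patterns over the 8-pixel neighbourhood ring (P = 8, R = 1):
#' each interior masked pixel is encoded by thresholding its ring at the
#' centre value; uniform patterns (at most two 0/1 transitions around the
#' ring) map to their number of set bits (9 rotation classes), all other
#' patterns to a tenth bin. The normalised histogram is returned.
#'
#' @param gray Numeric matrix of intensities.
#' @param mask Logical mask; only interior pixels (full ring inside the
#'   image) contribute.
#' @return Tibble with 10 rows.
#' @export
lbp_features <- function(gray, mask) {
  assert_mask(mask)
  nms <- c(paste0("lbp_uniform", 0:8), "lbp_nonuniform")
  H <- nrow(gray)
  W <- ncol(gray)
  if (H < 3L || W < 3L || !any(mask[2:(H - 1), 2:(W - 1)])) {
    return(feature_row(nms, "texture", 0, valid = FALSE))
  }
  # ring in circular order: E, NE, N, NW, W, SW, S, SE
  shifts <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                 c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  rows <- 2:(H - 1)
  cols <- 2:(W - 1)
  center <- gray[rows, cols]
  bits <- lapply(shifts, function(s) {
    (gray[rows + s[1], cols + s[2]] >= center) * 1L
  })
  ones <- Reduce(`+`, bits)
  transitions <- Reduce(`+`, lapply(seq_along(bits), function(k) {
    nxt <- if (k == length(bits)) 1L else k + 1L
    (bits[[k]] != bits[[nxt]]) * 1L
  }))
  bin <- ifelse(transitions <= 2L, ones + 1L, 10L)
  sel <- mask[rows, cols]
  h <- tabulate(bin[sel], 10L)
  finalize_block(feature_row(nms, "texture", h / sum(h)))
}
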