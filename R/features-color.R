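#' Colour features of a masked compartment (71 features)
#'
#' After removing white pixels (luminance Y > 180 in YCbCr), three blocks are
#' computed over the remaining masked pixels:
#' \itemize{
#'   \item Transformed-RGB histogram (48): each channel standardised as
#'     `(X - mu_X) / sigma_X`, then a 16-bin proportion histogram per channel
#'     over the fixed range \[-3, 3\]. Standardisation makes the block
#'     invariant to global intensity scaling and shifts.
#'   \item Red-blue difference histogram (16): 16-bin proportion histogram of
#'     `R - B` over \[-255, 255\].
#'   \item Red-blue difference statistics (7): mean, median, sd, min, max,
#'     skewness, kurtosis.
#' }
#' Degenerate inputs (empty mask after white removal, zero-variance channel)
#' yield zero-filled entries with the validity flag cleared, never `NaN`.
#'
#' @param rgb H x W x 3 array, 8-bit scale.
#' @param mask Logical compartment mask.
#' @param luminance_cutoff White-pixel removal threshold on Y, default 180.
#' @return Tibble with 71 rows: `feature`, `family`, `value`, `valid`.
#' @export
color_features <- function(rgb, mask, luminance_cutoff = 180) {
  assert_rgb_image(rgb)
  assert_mask(mask)
  channels <- c("r", "g", "b")
  trgb_names <- paste0("trgb_", rep(channels, each = 16), "_bin",
                       sprintf("%02d", rep(1:16, 3)))
  rb_bin_names <- paste0("rbdiff_bin", sprintf("%02d", 1:16))
  rb_stat_names <- paste0("rbdiff_", c("mean", "median", "sd", "min", "max",
                                       "skewness", "kurtosis"))
  all_names <- c(trgb_names, rb_bin_names, rb_stat_names)

  y <- luminance(rgb)
  keep <- mask & y <= luminance_cutoff
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(feature_row(all_names, "color", 0, valid = FALSE))
  }
  r <- rgb[, , 1][idx]
  g <- rgb[, , 2][idx]
  b <- rgb[, , 3][idx]

  hist16 <- function(x, lo, hi) {
    edges <- seq(lo, hi, length.out = 17L)
    bin <- findInterval(x, edges, rightmost.closed = TRUE)
    bin <- pmin(pmax(bin, 1L), 16L)
    tabulate(bin, 16L) / length(x)
  }

  trgb_vals <- numeric(0)
  trgb_valid <- logical(0)
  for (x in list(r, g, b)) {
    s <- sd(x)
    if (is.na(s) || s == 0) {
      z <- rep(0, length(x))      # all mass in the central bin, flagged
      ok <- FALSE
    } else {
      z <- (x - mean(x)) / s
      ok <- TRUE
    }
    trgb_vals <- c(trgb_vals, hist16(z, -3, 3))
    trgb_valid <- c(trgb_valid, rep(ok, 16))
  }

  d <- r - b
  rb_bins <- hist16(d, -255, 255)
  st <- seven_stats(d)
  out <- feature_row(
    all_names, "color",
    c(trgb_vals, rb_bins, st),
    valid = c(trgb_valid, rep(TRUE, 16), rep(TRUE, 7))
  )
  finalize_block(out)
}
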