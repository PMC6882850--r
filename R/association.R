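#' Spearman association between histology features and spectra
#'
#' For every (feature, wavelength) pair, computes Spearman's rank
#' correlation (Pearson correlation of average ranks, tie-safe) across the
#' aligned samples, with a two-sided p-value. By default the p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`; for small
#' samples an exact null distribution is available. Cells with `p <= alpha`
#' form the significance mask; per-feature row summaries (mean and sd of
#' rho across wavelengths) are attached, mirroring the usual heatmap margin
#' annotation. No multiple-testing correction is applied by default (each
#' cell is tested at `alpha`); Benjamini-Hochberg adjustment is available.
#'
#' @param features Samples x features data frame (numeric columns).
#' @param signatures Samples x wavelengths data frame, rows aligned with
#'   `features`; column names are taken as the wavelength axis.
#' @param alpha Per-cell significance level, default 0.05.
#' @param p_method `"t"` (default) or `"exact"` (exact Spearman null via
#'   [stats::cor.test()], small n, no ties).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An `association_report`: list with matrices `rho`, `p`, `valid`,
#'   `significant`, the row `summary` tibble, `n`, and `alpha`. Constant
#'   columns give invalid (flagged) cells, not zeros.
#' @export
spearman_matrix <- function(features, signatures, alpha = 0.05,
                            p_method = c("t", "exact"),
                            adjust = c("none", "BH")) {
  p_method <- match.arg(p_method)
  adjust <- match.arg(adjust)
  Fm <- as.matrix(as.data.frame(features))
  Sm <- as.matrix(as.data.frame(signatures))
  if (nrow(Fm) != nrow(Sm)) {
    stop("features and signatures must have aligned samples", call. = FALSE)
  }
  n <- nrow(Fm)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  f_const <- apply(Fm, 2, function(x) diff(range(x)) == 0)
  s_const <- apply(Sm, 2, function(x) diff(range(x)) == 0)
  rho <- suppressWarnings(cor(Fm, Sm, method = "spearman"))
  valid <- outer(!f_const, !s_const, `&`)
  rho[!valid] <- NA_real_
  p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  if (p_method == "t") {
    r <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p[] <- 2 * pt(-abs(tval), df = n - 2)
    p[rho^2 == 1] <- 0
  } else {
    for (i in seq_len(nrow(rho))) {
      for (j in seq_len(ncol(rho))) {
        if (!valid[i, j]) next
        p[i, j] <- suppressWarnings(
          stats::cor.test(Fm[, i], Sm[, j], method = "spearman",
                          exact = TRUE)$p.value
        )
      }
    }
  }
  if (adjust == "BH") {
    p[valid] <- stats::p.adjust(p[valid], method = "BH")
  }
  significant <- !is.na(p) & p <= alpha
  summary <- tibble::tibble(
    feature = rownames(rho),
    mean_rho = rowMeans(rho, na.rm = TRUE),
    sd_rho = apply(rho, 1, sd, na.rm = TRUE),
    prop_significant = rowMeans(significant)
  )
  structure(list(
    rho = rho, p = p, valid = valid, significant = significant,
    summary = summary, n = n, alpha = alpha
  ), class = "association_report")
}

#' Categorise an association report for heatmap rendering
#'
#' Each cell becomes `positive-significant` (green), `negative-significant`
#' (red) or `nonsignificant` (white); row means and standard deviations are
#' appended, and features with `|mean rho| >= threshold` are flagged strong.
#'
#' @param report An [spearman_matrix()] result.
#' @param strong_threshold Flagging threshold on |mean rho|, default 0.5.
#' @return Tibble with one row per cell plus row-summary columns.
#' @export
summarize_heatmap <- function(report, strong_threshold = 0.5) {
  stopifnot(inherits(report, "association_report"))
  long <- tidy.association_report(report)
  long$category <- dplyr::case_when(
    !long$significant ~ "nonsignificant",
    long$rho >= 0 ~ "positive-significant",
    TRUE ~ "negative-significant"
  )
  summary <- report$summary
  summary$strong <- abs(summary$mean_rho) >= strong_threshold
  dplyr::left_join(long, summary, by = "feature")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf(
    "<association_report> %d features x %d wavelengths, n = %d, alpha = %g\n",
    nrow(x$rho), ncol(x$rho), x$n, x$alpha
  ))
  cat(sprintf("significant cells: %.1f%%\n", 100 * mean(x$significant)))
  invisible(x)
}

#' Tidy an association report into a long tibble
#'
#' @param x An `association_report`.
#' @param ... Unused.
#' @return Tibble with `feature`, `wavelength`, `rho`, `p`, `valid`,
#'   `significant`.
#' @method tidy association_report
#' @export
tidy.association_report <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$rho), times = ncol(x$rho)),
    wavelength = rep(suppressWarnings(as.numeric(colnames(x$rho))),
                     each = nrow(x$rho)),
    rho = as.vector(x$rho),
    p = as.vector(x$p),
    valid = as.vector(x$valid),
    significant = as.vector(x$significant)
  )
}

#' Heatmap of a feature-by-wavelength association report
#'
#' Positive significant correlations render green, negative significant
#' red, nonsignificant cells white.
#'
#' @param object An `association_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot association_report
#' @export
autoplot.association_report <- function(object, ...) {
  long <- tidy.association_report(object)
  long$rho_masked <- ifelse(long$significant, long$rho, NA_real_)
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$feature,
                                     fill = .data$rho_masked)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "red3", mid = "white", high = "green4",
      limits = c(-1, 1), na.value = "white", name = "Spearman rho"
    ) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}
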