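#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a nested-CV report into per-fold rows
#'
#' @param x A `cv_report` from [nested_cv()].
#' @param ... Unused.
#' @return Tibble with one row per outer fold: held-out subject, chosen
#'   (m, cost, gamma), inner-CV accuracy, and the selected feature names as
#'   a list-column.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  x$folds
}

#' One-row summary of a nested-CV report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with pooled accuracy, sensitivity, specificity and the
#'   confusion-matrix cells (neoplastic positive).
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    accuracy = x$accuracy,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    tp = cm[1, 1], fn = cm[1, 2], fp = cm[2, 1], tn = cm[2, 2],
    n = nrow(x$predictions)
  )
}

#' One-row summary of an association report
#'
#' @param x An `association_report`.
#' @param ... Unused.
#' @return Tibble with dimensions, sample size and the share of
#'   significant cells.
#' @method glance association_report
#' @export
glance.association_report <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$rho),
    n_wavelengths = ncol(x$rho),
    n = x$n,
    alpha = x$alpha,
    prop_significant = mean(x$significant)
  )
}
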