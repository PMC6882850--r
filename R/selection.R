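# Discretise a numeric vector by equal-frequency binning into
# min(max_bins, ceiling(sqrt(n))) bins; ties collapse duplicate bin edges.
# Already-discrete inputs (factors, characters, few unique values) are kept.
discretize_feature <- function(x, max_bins = 10L) {
  if (is.factor(x) || is.character(x) || is.logical(x)) {
    return(as.integer(as.factor(x)))
  }
  ux <- unique(x)
  n_bins <- min(max_bins, ceiling(sqrt(length(x))))
  if (length(ux) <= n_bins) {
    return(match(x, sort(ux)))
  }
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE, type = 7))
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(bin)
}

# Plug-in mutual information (bits) between two integer code vectors.
mi_codes <- function(xi, yi, nx = max(xi), ny = max(yi)) {
  n <- length(xi)
  joint <- tabulate((xi - 1L) * ny + yi, nx * ny)
  px <- tabulate(xi, nx) / n
  py <- tabulate(yi, ny) / n
  pj <- joint / n
  denom <- as.vector(outer(py, px))   # column-major over (y within x)
  pos <- pj > 0
  sum(pj[pos] * log2(pj[pos] / denom[pos]))
}

#' Mutual information between two variables (bits)
#'
#' Plug-in estimator on the joint histogram. Continuous variables are
#' discretised by equal-frequency binning into `min(10, ceiling(sqrt(n)))`
#' bins; discrete variables (factors, characters, or numerics with few
#' unique values) are used as-is. The estimate is non-negative and
#' symmetric; a constant variable has zero mutual information with
#' anything.
#'
#' @param x,y Vectors of equal length (>= 2); numeric or discrete.
#' @param max_bins Cap on the number of bins for continuous variables.
#' @return Scalar mutual information in bits.
#' @export
mutual_information <- function(x, y, max_bins = 10L) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  xi <- discretize_feature(x, max_bins)
  yi <- discretize_feature(y, max_bins)
  max(mi_codes(xi, yi), 0)
}

#' Greedy mRMR feature ranking
#'
#' Minimal-redundancy maximal-relevance selection: the first feature
#' maximises the mutual information I(x; c) with the class label; each
#' subsequent feature maximises
#' \deqn{I(\lambda_i; c) - \frac{1}{|S|} \sum_{\lambda_j \in S} I(\lambda_i; \lambda_j)}
#' over the unselected features (the difference form of the criterion).
#' Ties break toward the lowest column index. Mutual information uses the
#' histogram plug-in of [mutual_information()].
#'
#' @param features Data frame or matrix, samples x features, no `NA`.
#' @param labels Class label vector (length = rows of `features`).
#' @param m Number of features to rank; truncated with a warning if it
#'   exceeds the number of available features.
#' @param max_bins Discretisation cap passed to the MI estimator.
#' @return Tibble of class `ranked_features`: `rank`, `feature`, `index`,
#'   `relevance` (I with the label), `redundancy` (mean I with the selected
#'   set at selection time), `score` (relevance - redundancy).
#' @export
mrmr_rank <- function(features, labels, m, max_bins = 10L) {
  X <- as.data.frame(features)
  if (anyNA(X)) stop("features must not contain NA", call. = FALSE)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  p <- ncol(X)
  if (m > p) {
    warning(sprintf("m = %d exceeds %d available features; truncating", m, p),
            call. = FALSE)
    m <- p
  }
  codes <- lapply(X, discretize_feature, max_bins = max_bins)
  n_codes <- vapply(codes, max, integer(1))
  ci <- discretize_feature(labels, max_bins)
  nc <- max(ci)
  # MI(a; b) = H(a) + H(b) - H(a, b) with marginal entropies precomputed
  ent <- function(counts, n) {
    q <- counts[counts > 0] / n
    -sum(q * log2(q))
  }
  n_obs <- length(ci)
  h_feat <- vapply(seq_len(p), function(j) {
    ent(tabulate(codes[[j]], n_codes[j]), n_obs)
  }, numeric(1))
  h_class <- ent(tabulate(ci, nc), n_obs)
  joint_ent <- function(xi, yi, ny) {
    ent(tabulate((xi - 1L) * ny + yi, max(xi) * ny), n_obs)
  }
  relevance <- vapply(seq_len(p), function(j) {
    max(h_feat[j] + h_class - joint_ent(codes[[j]], ci, nc), 0)
  }, numeric(1))

  selected <- integer(0)
  red_sum <- rep(0, p)
  out_rel <- numeric(m)
  out_red <- numeric(m)
  remaining <- seq_len(p)
  for (step in seq_len(m)) {
    red <- if (step == 1L) rep(0, p) else red_sum / (step - 1L)
    score <- relevance - red
    pick <- remaining[which.max(score[remaining])]   # which.max = lowest index tie-break
    selected <- c(selected, pick)
    out_rel[step] <- relevance[pick]
    out_red[step] <- red[pick]
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0L) break
    cp <- codes[[pick]]
    np <- n_codes[pick]
    hp <- h_feat[pick]
    for (j in remaining) {
      mi_j <- h_feat[j] + hp - joint_ent(codes[[j]], cp, np)
      red_sum[j] <- red_sum[j] + max(mi_j, 0)
    }
  }
  structure(tibble::tibble(
    rank = seq_along(selected),
    feature = colnames(X)[selected],
    index = selected,
    relevance = out_rel[seq_along(selected)],
    redundancy = out_red[seq_along(selected)],
    score = out_rel[seq_along(selected)] - out_red[seq_along(selected)]
  ), class = c("ranked_features", class(tibble::tibble())))
}
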