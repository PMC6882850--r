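#' Hyperparameter grid for nested cross-validation
#'
#' Defaults are the canonical grid: feature dimension m in
#' \{1, 5, 10, 30, 50, 70, 90, 100, 200, 300, 342\}, SVM cost and RBF
#' gamma in 2^\{-5, -3, -1, 1, 3, 5\}. `m` values above the number of
#' available features are capped at run time.
#'
#' @param m Feature-dimension grid.
#' @param cost SVM cost grid.
#' @param gamma RBF kernel parameter grid.
#' @return Named list.
#' @export
cv_grid <- function(m = c(1, 5, 10, 30, 50, 70, 90, 100, 200, 300, 342),
                    cost = 2^seq(-5, 5, by = 2),
                    gamma = 2^seq(-5, 5, by = 2)) {
  list(m = sort(unique(m)), cost = cost, gamma = gamma)
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma == 0] <- 1
  list(mu = mu, sigma = sigma)
}

scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sigma, "/")
}

svm_accuracy <- function(Xtr, ytr, Xte, yte, cost, gamma) {
  fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  mean(as.character(predict(fit, Xte)) == as.character(yte))
}

#' Nested leave-one-subject-out cross-validation
#'
#' Outer loop: each subject is held out once; inner loop: each remaining
#' subject is held out once to score every (m, cost, gamma) combination.
#' mRMR feature ranking and z-score standardisation are fitted on
#' inner-training data only (no leakage); the combination with the best
#' mean inner accuracy (ties toward smaller m, then cost, then gamma) is
#' refit on the full outer-training set, ranked and standardised afresh,
#' and used to predict the held-out subject. Predictions are pooled into a
#' confusion matrix with the neoplastic class positive.
#'
#' Zero-variance features of an outer-training set are dropped before
#' ranking; inner folds whose training set contains a single class are
#' skipped with a warning.
#'
#' @param features Samples x features data frame / matrix (finite values).
#' @param labels Binary labels, `"normal"` / `"neoplastic"` (or any two
#'   levels; `positive` selects the positive class).
#' @param subjects Subject identifier per sample.
#' @param grid A [cv_grid()].
#' @param positive Positive class, default `"neoplastic"`.
#' @return A `cv_report`: list with `folds` (per-fold tibble of chosen
#'   hyperparameters and selected features), `predictions` (per-sample
#'   tibble), `confusion` (2 x 2 table), and pooled `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
nested_cv <- function(features, labels, subjects, grid = cv_grid(),
                      positive = "neoplastic") {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  subjects <- as.character(subjects)
  subj_ids <- unique(subjects)
  if (length(subj_ids) < 2L) stop("need at least 2 subjects", call. = FALSE)

  folds <- list()
  predictions <- list()
  for (held in subj_ids) {
    test_idx <- which(subjects == held)
    train_idx <- which(subjects != held)
    Xtr_all <- X[train_idx, , drop = FALSE]
    keep_cols <- which(apply(Xtr_all, 2, sd) > 0)
    inner_subjects <- unique(subjects[train_idx])
    m_grid <- unique(pmin(grid$m, length(keep_cols)))

    # score[(m, cost, gamma)] accumulated over inner folds
    combos <- expand.grid(m = m_grid, cost = grid$cost, gamma = grid$gamma,
                          KEEP.OUT.ATTRS = FALSE)
    acc_sum <- rep(0, nrow(combos))
    n_folds_used <- 0L
    for (inner_held in inner_subjects) {
      val_idx <- train_idx[subjects[train_idx] == inner_held]
      fit_idx <- setdiff(train_idx, val_idx)
      if (length(unique(labels[fit_idx])) < 2L) {
        warning(sprintf(
          "inner fold (outer %s, inner %s) has a single training class; skipped",
          held, inner_held), call. = FALSE)
        next
      }
      Xfit <- X[fit_idx, keep_cols, drop = FALSE]
      sc <- scale_fit(Xfit)
      Xfit_s <- scale_apply(Xfit, sc)
      Xval_s <- scale_apply(X[val_idx, keep_cols, drop = FALSE], sc)
      ranking <- mrmr_rank(Xfit, labels[fit_idx], m = max(m_grid))
      for (ci in seq_len(nrow(combos))) {
        sel <- ranking$index[seq_len(combos$m[ci])]
        acc_sum[ci] <- acc_sum[ci] + svm_accuracy(
          Xfit_s[, sel, drop = FALSE], factor(labels[fit_idx]),
          Xval_s[, sel, drop = FALSE], labels[val_idx],
          combos$cost[ci], combos$gamma[ci]
        )
      }
      n_folds_used <- n_folds_used + 1L
    }
    if (n_folds_used == 0L) {
      warning(sprintf("outer fold %s has no usable inner folds; skipped", held),
              call. = FALSE)
      next
    }
    mean_acc <- acc_sum / n_folds_used
    # parsimony tie-break: smaller m, then cost, then gamma
    ord <- order(-mean_acc, combos$m, combos$cost, combos$gamma)
    best <- combos[ord[1], ]

    sc <- scale_fit(Xtr_all[, keep_cols, drop = FALSE])
    Xtr_s <- scale_apply(Xtr_all[, keep_cols, drop = FALSE], sc)
    Xte_s <- scale_apply(X[test_idx, keep_cols, drop = FALSE], sc)
    ranking <- mrmr_rank(Xtr_all[, keep_cols, drop = FALSE],
                         labels[train_idx], m = best$m)
    sel <- ranking$index[seq_len(best$m)]
    fit <- e1071::svm(Xtr_s[, sel, drop = FALSE], factor(labels[train_idx]),
                      kernel = "radial", cost = best$cost, gamma = best$gamma,
                      scale = FALSE)
    pred <- as.character(predict(fit, Xte_s[, sel, drop = FALSE]))
    sel_names <- colnames(X)[keep_cols][sel]
    folds[[held]] <- tibble::tibble(
      subject = held, m = best$m, cost = best$cost, gamma = best$gamma,
      inner_accuracy = max(mean_acc),
      features = list(sel_names)
    )
    predictions[[held]] <- tibble::tibble(
      sample = test_idx, subject = held,
      truth = labels[test_idx], predicted = pred
    )
  }
  folds <- dplyr::bind_rows(folds)
  predictions <- dplyr::bind_rows(predictions)
  metrics <- confusion_metrics(predictions$predicted, predictions$truth,
                               positive = positive)
  structure(c(list(folds = folds, predictions = predictions), metrics),
            class = "cv_report")
}

#' Confusion matrix and derived metrics
#'
#' Pools predictions against truth with the given positive class
#' (neoplastic by default): accuracy = (TP + TN) / n, sensitivity =
#' TP / (TP + FN), specificity = TN / (TN + FP). A metric whose denominator
#' is empty (single-class ground truth) is returned as `NA` with a warning,
#' never silently propagated as `NaN` downstream.
#'
#' @param predicted,truth Character/factor vectors of equal length.
#' @param positive Positive class label.
#' @return List with `confusion` (table), `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(predicted, truth, positive = "neoplastic") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  is_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(is_pos & pred_pos)
  fn <- sum(is_pos & !pred_pos)
  tn <- sum(!is_pos & !pred_pos)
  fp <- sum(!is_pos & pred_pos)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                      dimnames = list(
                        truth = c(positive, paste0("not_", positive)),
                        predicted = c(positive, paste0("not_", positive))
                      ))
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive ground truth; sensitivity undefined", call. = FALSE)
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative ground truth; specificity undefined", call. = FALSE)
    NA_real_
  }
  list(
    confusion = confusion,
    accuracy = (tp + tn) / length(truth),
    sensitivity = sens,
    specificity = spec
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d folds, %d samples\naccuracy %.3f, sensitivity %.3f, specificity %.3f\n",
    nrow(x$folds), nrow(x$predictions),
    x$accuracy, x$sensitivity, x$specificity
  ))
  invisible(x)
}
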