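## Two-step outcome classification: elastic-net feature selection, then a
## class-weighted linear SVM, evaluated by leave-one-out cross-validation
## over a (lambda, rho) regularisation grid.

#' Assemble a cohort feature matrix from per-subject change metrics
#'
#' Columns are ordered deterministically: the connection block (strict upper
#' triangle in row-major order), then region strength, then region volume.
#' Connection columns keep connections whose pre-operative count is nonzero
#' in every subject and whose change ratio is < 1 in at least one subject;
#' region-strength columns keep regions whose strength ratio is < 1 in
#' every subject; region-volume columns keep regions intersected by at
#' least one subject's mask (volume ratio < 1 somewhere).
#'
#' @param changes list of [change_metrics()] objects, one per subject, on a
#'   common region set.
#' @param outcomes vector in \{+1 seizure-free, -1 not\}, one per subject.
#' @param weights optional per-sample weights (default 1).
#' @return an object of class `cohort_features`: list with `A` (n x m),
#'   `block` (factor: connection_strength / region_strength / region_volume),
#'   `y`, `weights`.
#' @export
assemble_features <- function(changes, outcomes, weights = NULL) {
  n <- length(changes)
  if (n < 1L) stopf("need at least one subject")
  if (length(outcomes) != n) stopf("one outcome per subject required")
  ids <- changes[[1]]$region_ids
  for (ch in changes) {
    if (!inherits(ch, "change_metrics")) {
      stopf("changes must be change_metrics objects")
    }
    if (!identical(ch$region_ids, ids)) {
      stopf("subjects have inconsistent region sets")
    }
  }
  R <- length(ids)
  ut <- upper_triangle_order(R)
  # explicit n x k shape: vapply+t collapses wrongly when k == 1
  stack <- function(get, k) {
    matrix(unlist(lapply(changes, get)), nrow = n, ncol = k, byrow = TRUE)
  }
  conn_ratio <- stack(function(ch) ch$connection_ratio[ut], nrow(ut))
  conn_pre <- stack(function(ch) ch$pre_connection[ut], nrow(ut))
  keep_conn <- apply(conn_pre > 0, 2L, all) & apply(conn_ratio < 1, 2L, any)
  str_ratio <- stack(function(ch) ch$strength_ratio, R)
  keep_str <- apply(str_ratio < 1, 2L, all)
  have_vol <- !vapply(changes, function(ch) is.null(ch$volume_ratio), TRUE)
  if (any(have_vol) && !all(have_vol)) {
    stopf("volume ratios present for only some subjects")
  }
  if (all(have_vol)) {
    vol_ratio <- stack(function(ch) as.numeric(ch$volume_ratio), R)
    keep_vol <- apply(vol_ratio < 1, 2L, any)
  } else {
    vol_ratio <- matrix(numeric(0), n, 0)
    keep_vol <- logical(0)
  }
  blocks <- list(
    connection_strength = conn_ratio[, keep_conn, drop = FALSE],
    region_strength = str_ratio[, keep_str, drop = FALSE],
    region_volume = vol_ratio[, keep_vol, drop = FALSE]
  )
  if (ncol(blocks$connection_strength)) {
    colnames(blocks$connection_strength) <-
      paste0("conn_", ids[ut[keep_conn, 1]], "_", ids[ut[keep_conn, 2]])
  }
  if (ncol(blocks$region_strength)) {
    colnames(blocks$region_strength) <- paste0("strength_", ids[keep_str])
  }
  if (ncol(blocks$region_volume)) {
    colnames(blocks$region_volume) <- paste0("volume_", ids[keep_vol])
  }
  A <- do.call(cbind, blocks)
  block <- factor(rep(names(blocks), vapply(blocks, ncol, 0L)),
                  levels = names(blocks))
  cohort_features(A, block, outcomes, weights)
}

#' Construct a cohort feature object
#'
#' @param A n x m numeric feature matrix (rows = subjects).
#' @param block factor/character of length m tagging each column as
#'   connection_strength, region_strength or region_volume.
#' @param y outcomes in \{+1, -1\}; both classes must be present for fitting.
#' @param weights optional per-sample weights (default 1).
#' @return an object of class `cohort_features`.
#' @export
cohort_features <- function(A, block, y, weights = NULL) {
  A <- as.matrix(A)
  block <- factor(block, levels = c("connection_strength", "region_strength",
                                    "region_volume"))
  if (length(block) != ncol(A)) stopf("one block tag per column required")
  if (length(y) != nrow(A)) stopf("one outcome per row required")
  if (!all(y %in% c(-1, 1))) stopf("outcomes must be coded +1 / -1")
  if (is.null(weights)) weights <- rep(1, nrow(A))
  structure(list(A = A, block = block, y = as.numeric(y),
                 weights = as.numeric(weights)),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  bs <- table(x$block)
  cat(sprintf(
    "Cohort features: %d subjects x %d features (%s); %d / %d outcomes +1\n",
    nrow(x$A), ncol(x$A),
    paste(sprintf("%s %d", names(bs), bs), collapse = ", "),
    sum(x$y > 0), length(x$y)))
  invisible(x)
}

#' Fit a class-weighted linear SVM
#'
#' Soft-margin linear SVM (C-classification) in which the misclassification
#' cost of class k is scaled by n / (2 n_k) — the uniform-prior reweighting
#' that stops an imbalanced cohort from dominating the decision boundary.
#'
#' Features are standardised on the training data by default. Change-ratio
#' features concentrate near 1 with small spread; without kernel scaling the
#' margin term swamps w and the fit degenerates to an intercept-only rule
#' decided by the class weights, which under leave-one-out makes every fold
#' predict the held-out subject's own class (the held-out class is always
#' the training minority).
#'
#' @param A n x m feature matrix.
#' @param y outcomes in \{+1, -1\}, both classes present.
#' @param cost base regularisation constant C (default 1).
#' @param scale standardise columns on the training data (default TRUE).
#'   With `scale = FALSE` the class weighting is exactly equivalent to
#'   duplicating minority samples.
#' @return an object of class `weighted_svm`.
#' @export
fit_weighted_svm <- function(A, y, cost = 1, scale = TRUE) {
  A <- as.matrix(A)
  y <- check_labels(y)
  if (ncol(A) < 1L) stopf("at least one selected feature is required")
  n <- length(y)
  cw <- c("-1" = n / (2 * sum(y < 0)), "1" = n / (2 * sum(y > 0)))
  # constant columns cannot be standardised; e1071 warns and drops the scale
  scale_cols <- if (isTRUE(scale)) apply(A, 2L, function(v) {
    stats::var(v) > .Machine$double.eps
  }) else FALSE
  fit <- e1071::svm(A, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = cost, class.weights = cw, scale = scale_cols)
  structure(list(model = fit, cost = cost, class_weights = cw),
            class = "weighted_svm")
}

#' @export
print.weighted_svm <- function(x, ...) {
  cat(sprintf(
    "Class-weighted linear SVM: C = %g, class costs (-1: %.3f, +1: %.3f), %d SVs\n",
    x$cost, x$class_weights[["-1"]], x$class_weights[["1"]],
    x$model$tot.nSV))
  invisible(x)
}

#' @export
predict.weighted_svm <- function(object, newdata, ...) {
  as.numeric(as.character(predict(object$model, as.matrix(newdata))))
}

#' Confusion counts and derived rates
#'
#' Positive class is seizure-free (+1).
#'
#' @param tp,fp,fn,tn non-negative confusion counts; both actual classes
#'   must be non-empty.
#' @return an object of class `classifier_evaluation` with counts, accuracy,
#'   sensitivity (TPR), specificity (TNR), false-positive and false-negative
#'   rates.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stopf("empty confusion matrix")
  if (tp + fn == 0 || tn + fp == 0) {
    stopf("an actual class is empty; rates undefined")
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
         accuracy = (tp + tn) / n,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         false_positive_rate = fp / (tn + fp),
         false_negative_rate = fn / (tp + fn)),
    class = "classifier_evaluation"
  )
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("Confusion: TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  cat(sprintf(
    "  accuracy %.3f  sensitivity %.3f  specificity %.3f  FPR %.3f  FNR %.3f\n",
    x$accuracy, x$sensitivity, x$specificity,
    x$false_positive_rate, x$false_negative_rate))
  if (!is.null(x$selected_per_fold)) {
    cat(sprintf("  mean features selected per fold: %.1f\n",
                mean(x$selected_per_fold)))
  }
  invisible(x)
}

#' Leave-one-out cross-validated evaluation at one grid point
#'
#' For each subject, elastic-net selection (inside the training fold when
#' `selection_scope = "per_fold"`, once on the whole cohort when
#' `"full_cohort"` — the latter leaks the held-out label into selection and
#' is provided for comparison only) is followed by a class-weighted linear
#' SVM fit on the remaining n - 1 subjects and a prediction for the held-out
#' one. When a fold selects no feature, the fold falls back to predicting
#' seizure-free (the tie-break of the uniform-prior "majority" — both priors
#' are 0.5) and is flagged. A training fold with a single class predicts
#' that class and is flagged.
#'
#' @param features a [cohort_features()] object (n >= 2).
#' @param lambda,rho elastic-net penalties.
#' @param selection_scope "per_fold" (default) or "full_cohort".
#' @param cost SVM regularisation constant.
#' @return a `classifier_evaluation` with extra fields `predictions`,
#'   `selected_per_fold`, `fallback_folds`, `lambda`, `rho`,
#'   `selection_scope`.
#' @export
loocv_evaluate <- function(features, lambda, rho,
                           selection_scope = c("per_fold", "full_cohort"),
                           cost = 1) {
  selection_scope <- match.arg(selection_scope)
  if (!inherits(features, "cohort_features")) {
    stopf("features must be a cohort_features object")
  }
  A <- features$A; y <- features$y; w <- features$weights
  n <- nrow(A)
  if (n < 2L) stopf("LOOCV needs at least 2 subjects")
  full_mask <- NULL
  if (selection_scope == "full_cohort") {
    full_mask <- select_features(fit_elastic_net(A, y, lambda, rho, w))
  }
  pred <- numeric(n)
  nsel <- integer(n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    At <- A[-i, , drop = FALSE]; yt <- y[-i]; wt <- w[-i]
    if (length(unique(yt)) < 2L) {
      pred[i] <- yt[1]
      fallback[i] <- TRUE
      next
    }
    mask <- if (is.null(full_mask)) {
      select_features(fit_elastic_net(At, yt, lambda, rho, wt))
    } else full_mask
    nsel[i] <- sum(mask)
    if (nsel[i] == 0L) {
      pred[i] <- 1
      fallback[i] <- TRUE
      next
    }
    svm_fit <- fit_weighted_svm(At[, mask, drop = FALSE], yt, cost)
    pred[i] <- predict(svm_fit, A[i, mask, drop = FALSE])
  }
  out <- confusion_metrics(
    tp = sum(pred > 0 & y > 0), fp = sum(pred > 0 & y < 0),
    fn = sum(pred < 0 & y > 0), tn = sum(pred < 0 & y < 0)
  )
  out$predictions <- pred
  out$selected_per_fold <- nsel
  out$fallback_folds <- which(fallback)
  out$lambda <- lambda
  out$rho <- rho
  out$selection_scope <- selection_scope
  out
}

#' Default (lambda, rho) regularisation grid
#'
#' lambda from 0.01 to 0.96 and rho from 0.01 to 1.96, both in steps of
#' 0.05 (20 x 40 grid points).
#'
#' @return list with numeric `lambda` and `rho` ladders.
#' @export
default_regularisation_grid <- function() {
  list(lambda = seq(0.01, 0.96, by = 0.05),
       rho = seq(0.01, 1.96, by = 0.05))
}

#' LOOCV grid search over elastic-net penalties
#'
#' Evaluates [loocv_evaluate()] at every (lambda, rho) grid point and
#' returns the point maximising accuracy; ties are broken by fewer mean
#' selected features per fold, then by larger lambda (preferring the minimum
#' feature set that separates the classes most accurately). The selection
#' mask refitted on the full cohort at the winning point is reported as the
#' selected feature set.
#'
#' @param features a [cohort_features()] object.
#' @param grid list with `lambda` and `rho` vectors (default
#'   [default_regularisation_grid()]).
#' @inheritParams loocv_evaluate
#' @return an object of class `grid_search` with `best_lambda`, `best_rho`,
#'   `best_evaluation`, `selected_features` (character), and `results`
#'   (one row per grid point).
#' @export
grid_search <- function(features, grid = default_regularisation_grid(),
                        selection_scope = c("per_fold", "full_cohort"),
                        cost = 1) {
  selection_scope <- match.arg(selection_scope)
  if (!length(grid$lambda) || !length(grid$rho)) stopf("empty grid")
  pts <- expand.grid(lambda = grid$lambda, rho = grid$rho,
                     KEEP.OUT.ATTRS = FALSE)
  evals <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    evals[[k]] <- loocv_evaluate(features, pts$lambda[k], pts$rho[k],
                                 selection_scope, cost)
  }
  results <- data.frame(
    lambda = pts$lambda,
    rho = pts$rho,
    accuracy = vapply(evals, function(e) e$accuracy, 0),
    sensitivity = vapply(evals, function(e) e$sensitivity, 0),
    specificity = vapply(evals, function(e) e$specificity, 0),
    mean_selected = vapply(evals, function(e) mean(e$selected_per_fold), 0)
  )
  ord <- order(-results$accuracy, results$mean_selected, -results$lambda,
               results$rho)
  best <- ord[1]
  final_fit <- fit_elastic_net(features$A, features$y, pts$lambda[best],
                               pts$rho[best], features$weights)
  mask <- select_features(final_fit)
  structure(
    list(best_lambda = pts$lambda[best], best_rho = pts$rho[best],
         best_evaluation = evals[[best]],
         selected_features = colnames(features$A)[mask],
         final_fit = final_fit,
         results = results),
    class = "grid_search"
  )
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf(
    "LOOCV grid search over %d points: best lambda = %g, rho = %g\n",
    nrow(x$results), x$best_lambda, x$best_rho))
  print(x$best_evaluation)
  cat(sprintf("  %d feature(s) selected on the full cohort: %s\n",
              length(x$selected_features),
              paste(head(x$selected_features, 8), collapse = ", ")))
  invisible(x)
}
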