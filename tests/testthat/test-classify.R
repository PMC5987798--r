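test_that("feature assembly orders blocks deterministically and applies the
           eligibility rules", {
  changes <- toy_assembly_changes()
  feats <- assemble_features(changes, c(1, -1))
  expect_equal(ncol(feats$A), 6)
  expect_equal(as.integer(table(feats$block)), c(3L, 2L, 1L))
  expect_equal(colnames(feats$A),
               c("conn_1_2", "conn_1_3", "conn_2_3",
                 "strength_1", "strength_2", "volume_1"))
  # subject 1 halves connection 1-2 and keeps the others
  expect_equal(unname(feats$A[1, 1:3]), c(0.5, 1, 1))
  # region 3's strength is untouched in subject 1, so it is not a feature
  expect_false("strength_3" %in% colnames(feats$A))
})

test_that("feature assembly degrades gracefully when no connection is eligible", {
  pre <- connectivity_matrix(matrix(c(0, 4, 4, 0), 2), 1:2)
  post <- connectivity_matrix(matrix(c(0, 4, 4, 0), 2), 1:2)
  unchanged <- change_metrics(pre, post, volume_remaining = c(0.9, 1))
  feats <- assemble_features(list(unchanged, unchanged), c(1, -1))
  expect_equal(sum(feats$block == "connection_strength"), 0)
  expect_equal(sum(feats$block == "region_strength"), 0)
  expect_equal(sum(feats$block == "region_volume"), 1)
  expect_error(assemble_features(list(unchanged), c(1, -1)), "one outcome")
})

test_that("the class-weighted SVM separates a separable toy and shifts the
           boundary toward the minority class", {
  # balanced, separable in 1-D
  xb <- matrix(c(-3, -2, -1.5, 1.5, 2, 3), ncol = 1)
  yb <- c(-1, -1, -1, 1, 1, 1)
  fit <- fit_weighted_svm(xb, yb)
  expect_equal(predict(fit, xb), yb)

  # imbalanced 10 vs 2 with genuine class overlap; the weighted boundary
  # must sit closer to the majority-class mean than the unweighted one
  set.seed(71)
  xmaj <- rnorm(10, 0, 1)
  xmin <- c(1.2, 2.2)
  Xi <- matrix(c(xmaj, xmin), ncol = 1)
  yi <- c(rep(-1, 10), rep(1, 2))
  boundary <- function(model) {
    # linear decision function f(x) = w x + b; boundary at -b / w
    grid <- matrix(seq(-6, 8, by = 0.001), ncol = 1)
    f <- attr(predict(model, grid, decision.values = TRUE), "decision.values")
    grid[which.min(abs(f))]
  }
  weighted <- fit_weighted_svm(Xi, yi)
  unweighted <- e1071::svm(Xi, factor(yi, levels = c(-1, 1)),
                           kernel = "linear", cost = 1, scale = FALSE)
  b_w <- boundary(weighted$model)
  b_u <- boundary(unweighted)
  expect_lt(abs(b_w - mean(xmaj)), abs(b_u - mean(xmaj)))

  # duplicating every minority sample to reach balance reproduces the
  # uniform-prior weighting's boundary exactly in the unscaled regime
  # (identical QPs; with standardisation the two data sets scale differently)
  Xd <- matrix(c(xmaj, rep(xmin, 5)), ncol = 1)
  yd <- c(rep(-1, 10), rep(1, 10))
  dup <- e1071::svm(Xd, factor(yd, levels = c(-1, 1)), kernel = "linear",
                    cost = 1, scale = FALSE)
  w_unscaled <- fit_weighted_svm(Xi, yi, scale = FALSE)
  expect_equal(boundary(w_unscaled$model), boundary(dup), tolerance = 1e-3)
})

test_that("confusion metrics reproduce their defining identities", {
  ev <- confusion_metrics(31, 6, 5, 11)
  expect_equal(ev$n, 53)
  expect_equal(ev$accuracy, 42 / 53)
  expect_equal(ev$sensitivity, 31 / 36)
  expect_equal(ev$specificity, 11 / 17)
  expect_equal(ev$false_positive_rate, 1 - ev$specificity)
  expect_equal(ev$false_negative_rate, 1 - ev$sensitivity)

  perfect <- confusion_metrics(10, 0, 0, 5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$false_positive_rate, 0)
  expect_equal(perfect$false_negative_rate, 0)

  # predicting everyone seizure-free in a 36/17 cohort
  naive <- confusion_metrics(36, 17, 0, 0)
  expect_equal(naive$accuracy, 36 / 53, tolerance = 1e-12)
  expect_equal(naive$specificity, 0)

  expect_error(confusion_metrics(3, 0, 0, 0), "empty")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("LOOCV produces one prediction per subject and perfect accuracy on
           a separable cohort", {
  set.seed(81)
  n <- 16
  y <- rep(c(1, -1), each = n / 2)
  A <- cbind(sep = ifelse(y > 0, 0.2, 0.9) + rnorm(n, 0, 0.02),
             matrix(runif(n * 5, 0.5, 1), n, 5))
  colnames(A) <- paste0("f", 1:6)
  feats <- cohort_features(A, rep("connection_strength", 6), y)
  ev <- loocv_evaluate(feats, lambda = 0.05, rho = 0.11)
  expect_length(ev$predictions, n)
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, n)
  expect_equal(ev$accuracy, 1.0)
  expect_true(all(ev$selected_per_fold >= 1))
})

test_that("LOOCV accuracy sits at chance on a label-permuted null cohort", {
  # delta = 0: no feature carries class structure, so permuted labels are a
  # clean null (with planted structure a random permutation still overlaps
  # the true labels by sampling noise and the classifier can exploit it)
  co <- make_cohort(n_per_class = 14,
                    block_sizes = c(connection_strength = 30),
                    n_informative = 4, delta = 0, seed = 83)
  feats <- co$features
  set.seed(84)
  accs <- vapply(1:5, function(k) {
    feats$y <- sample(feats$y) # break the feature-label link
    loocv_evaluate(feats, lambda = 0.11, rho = 0.51)$accuracy
  }, 0)
  # 140 null predictions in total; allow 2.5 sigma since LOOCV folds are
  # weakly correlated
  n_tot <- 5 * length(feats$y)
  band <- 2.5 * sqrt(0.25 / n_tot)
  expect_gte(mean(accs), 0.5 - band - 1 / length(feats$y))
  expect_lte(mean(accs), 0.5 + band + 1 / length(feats$y))
})

test_that("per-fold selection never uses the held-out subject: flipping its
           label leaves its prediction unchanged", {
  co <- make_cohort(n_per_class = 10,
                    block_sizes = c(connection_strength = 25),
                    n_informative = 3, seed = 85)
  feats <- co$features
  i <- 7L
  ev1 <- loocv_evaluate(feats, lambda = 0.21, rho = 0.51)
  flipped <- feats
  flipped$y[i] <- -flipped$y[i]
  ev2 <- loocv_evaluate(flipped, lambda = 0.21, rho = 0.51)
  expect_identical(ev1$predictions[i], ev2$predictions[i])
})

test_that("folds with no selected feature fall back and are flagged", {
  set.seed(86)
  n <- 10
  A <- matrix(runif(n * 4), n, 4)
  feats <- cohort_features(A, rep("connection_strength", 4),
                           rep(c(1, -1), each = n / 2))
  ev <- loocv_evaluate(feats, lambda = 50, rho = 0.5) # far above critical
  expect_length(ev$fallback_folds, n)
  expect_true(all(ev$predictions == 1)) # uniform-prior tie-break
})

test_that("the default grid has the stated ladders and the search returns a
           single-point grid unchanged", {
  grid <- default_regularisation_grid()
  expect_length(grid$lambda, 20)
  expect_length(grid$rho, 40)
  expect_equal(grid$lambda[1:3], c(0.01, 0.06, 0.11))
  expect_equal(max(grid$lambda), 0.96)
  expect_equal(max(grid$rho), 1.96)
  expect_equal(nrow(expand.grid(grid$lambda, grid$rho)), 800)

  co <- make_cohort(n_per_class = 8,
                    block_sizes = c(connection_strength = 12),
                    n_informative = 3, seed = 87)
  gs <- grid_search(co$features, grid = list(lambda = 0.21, rho = 0.51))
  expect_equal(gs$best_lambda, 0.21)
  expect_equal(gs$best_rho, 0.51)
  expect_equal(nrow(gs$results), 1)
})

test_that("grid search recovers a planted feature at moderate lambda and
           breaks ties toward sparser, more regularised fits", {
  co <- make_cohort(n_per_class = 12,
                    block_sizes = c(connection_strength = 20),
                    n_informative = 2, delta = 0.45, seed = 88)
  gs <- grid_search(co$features,
                    grid = list(lambda = c(0.01, 0.21, 0.41),
                                rho = c(0.01, 0.51)))
  expect_true(any(co$truth$informative %in% gs$selected_features))
  acc <- gs$best_evaluation$accuracy
  # no other grid point beats the winner; ties go to fewer mean features
  expect_true(all(gs$results$accuracy <= acc))
  top <- gs$results[gs$results$accuracy == acc, ]
  expect_equal(min(top$mean_selected),
               top$mean_selected[top$lambda == gs$best_lambda &
                                   top$rho == gs$best_rho])
})
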