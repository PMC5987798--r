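#' Two-sided permutation test for a difference of means
#'
#' Group labels are shuffled `n_perm` times with a seeded generator; the
#' two-sided p-value uses the small-sample +1 correction
#' p = (1 + #\{|T_perm| >= |T_obs|\}) / (n_perm + 1), which guarantees
#' p in \[1/(n_perm + 1), 1\].
#'
#' @param group1,group2 numeric samples (non-empty).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return an object of class `permutation_test` with `observed`, `n_perm`,
#'   `p_value`, `seed`.
#' @export
permutation_test_mean_diff <- function(group1, group2, n_perm = 10000,
                                       seed = NULL) {
  if (!length(group1) || !length(group2)) stopf("both groups must be non-empty")
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be a positive count")
  n1 <- length(group1)
  pooled <- c(group1, group2)
  observed <- mean(group1) - mean(group2)
  eps <- 1e-12 * max(1, abs(observed))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(length(pooled), n1)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, 0) >= abs(observed) - eps)
  })
  structure(
    list(observed = observed, n_perm = as.integer(n_perm),
         p_value = (1 + exceed) / (n_perm + 1), seed = seed),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (difference of means): observed %.4g, p = %.4g (%d permutations)\n",
    x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Pearson chi-squared test on a 2 x 2 table, without continuity correction
#'
#' The uncorrected statistic sum (O - E)^2 / E with expectations from the
#' row/column marginals, referred to a chi-squared distribution with 1
#' degree of freedom. No Yates correction is applied.
#'
#' @param table 2 x 2 matrix of non-negative counts with all marginals > 0.
#' @return an object of class `chi_square_2x2` with `table`, `statistic`,
#'   `p_value`, `expected`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("table must be 2 x 2")
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("zero marginal; chi-squared undefined")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  structure(
    list(table = table, statistic = unname(res$statistic),
         p_value = unname(res$p.value), expected = res$expected),
    class = "chi_square_2x2"
  )
}

#' @export
print.chi_square_2x2 <- function(x, ...) {
  cat(sprintf("Pearson chi-squared (2x2, uncorrected): X2 = %.4f, p = %.4f\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic referred to a chi-squared distribution with
#' (number of groups - 1) degrees of freedom. When every value in every
#' group is identical the test degenerates to H = 0, p = 1 rather than an
#' error.
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("groups must be a list of at least 2 samples")
  }
  if (any(!vapply(groups, length, 0L))) stopf("groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = df))
  }
  g <- factor(rep.int(seq_along(groups), vapply(groups, length, 0L)))
  res <- kruskal.test(values, g)
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter))
}
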