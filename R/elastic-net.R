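## Elastic-net regularised logistic regression, fitted by accelerated
## proximal gradient (FISTA) with backtracking and soft-thresholding.
## The objective is
##   sum_i w_i log(1 + exp(-y_i (x'a_i + c))) + rho/2 ||x||_2^2 + lambda ||x||_1
## with the intercept c unpenalised.

# overflow-safe log(1 + exp(z))
log1pexp <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

#' Elastic-net logistic objective
#'
#' Weighted logistic loss plus ridge (rho/2 ||x||^2) and lasso (lambda
#' ||x||_1) penalties; the intercept is unpenalised. Computed overflow-safely.
#'
#' @param x numeric weight vector (length m).
#' @param intercept scalar intercept.
#' @param A n x m feature matrix (rows = subjects).
#' @param y outcome vector in \{+1, -1\}.
#' @param lambda l1 penalty (>= 0).
#' @param rho l2 penalty (>= 0).
#' @param weights per-sample weights (default 1).
#' @return scalar objective value.
#' @export
elastic_net_objective <- function(x, intercept, A, y, lambda, rho,
                                  weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  f <- as.numeric(A %*% x) + intercept
  sum(weights * log1pexp(-y * f)) +
    rho / 2 * sum(x^2) + lambda * sum(abs(x))
}

check_labels <- function(y) {
  if (!all(y %in% c(-1, 1))) stopf("outcomes must be coded +1 / -1")
  if (length(unique(y)) < 2L) stopf("both outcome classes must be present")
  as.numeric(y)
}

# optimal intercept of the weighted logistic loss at x = 0:
# c* = log(sum of positive weights / sum of negative weights)
null_intercept <- function(y, weights) {
  log(sum(weights[y > 0]) / sum(weights[y < 0]))
}

#' Fit elastic-net regularised logistic regression
#'
#' Minimises the objective of [elastic_net_objective()] by accelerated
#' proximal gradient descent (FISTA) with backtracking line search, adaptive
#' restart and soft-thresholding for the l1 term. Iteration starts from
#' x = 0 with the closed-form null intercept, so that for lambda at or above
#' the critical value (the max absolute smooth gradient at that point) the
#' exact all-zero solution is returned.
#'
#' @inheritParams elastic_net_objective
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return an object of class `elastic_net_fit` with elements `x`,
#'   `intercept`, `lambda`, `rho`, `objective_value`, `converged`,
#'   `iterations`.
#' @export
fit_elastic_net <- function(A, y, lambda, rho, weights = NULL,
                            tol = 1e-8, max_iter = 1e5) {
  A <- as.matrix(A)
  y <- check_labels(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (lambda < 0 || rho < 0) stopf("penalties must be non-negative")
  m <- ncol(A)
  wy <- weights * y

  smooth_value <- function(x, c0, f) {
    sum(weights * log1pexp(-y * f)) + rho / 2 * sum(x^2)
  }
  smooth_grad <- function(x, c0, f) {
    s <- wy / (1 + exp(y * f)) # w_i y_i sigma(-y_i f_i)
    list(gx = -as.numeric(crossprod(A, s)) + rho * x, gc = -sum(s))
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  x <- numeric(m)
  c0 <- null_intercept(y, weights)
  f <- rep(c0, length(y))
  g <- smooth_grad(x, c0, f)
  # exact null solution above the critical lambda
  if (m == 0L || max(abs(g$gx)) <= lambda + 1e-12) {
    obj <- elastic_net_objective(x, c0, A, y, lambda, rho, weights)
    return(new_elastic_net_fit(x, c0, lambda, rho, obj, TRUE, 0L, colnames(A)))
  }

  L <- 1
  zx <- x; zc <- c0      # extrapolated point
  tk <- 1
  obj <- elastic_net_objective(x, c0, A, y, lambda, rho, weights)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fz <- as.numeric(A %*% zx) + zc
    gz <- smooth_grad(zx, zc, fz)
    hz <- smooth_value(zx, zc, fz)
    repeat {
      nx <- soft(zx - gz$gx / L, lambda / L)
      nc <- zc - gz$gc / L
      fn <- as.numeric(A %*% nx) + nc
      hn <- smooth_value(nx, nc, fn)
      dx <- nx - zx; dc <- nc - zc
      quad <- hz + sum(gz$gx * dx) + gz$gc * dc +
        L / 2 * (sum(dx^2) + dc^2)
      if (hn <= quad + 1e-12 * abs(quad)) break
      L <- 2 * L
    }
    new_obj <- hn + lambda * sum(abs(nx))
    if (new_obj > obj) {
      # adaptive restart: drop momentum, retry from the last iterate
      zx <- x; zc <- c0; tk <- 1
      if (iter > 1L && abs(new_obj - obj) <= tol * max(1, abs(obj))) {
        converged <- TRUE
        break
      }
      next
    }
    tnext <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zx <- nx + (tk - 1) / tnext * (nx - x)
    zc <- nc + (tk - 1) / tnext * (nc - c0)
    tk <- tnext
    rel <- abs(obj - new_obj) / max(1, abs(obj))
    x <- nx; c0 <- nc; obj <- new_obj
    L <- max(L / 2, 1e-3) # allow the step size to grow again
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  new_elastic_net_fit(x, c0, lambda, rho, obj, converged, iter, colnames(A))
}

new_elastic_net_fit <- function(x, intercept, lambda, rho, obj, converged,
                                iterations, feature_names = NULL) {
  if (!is.null(feature_names)) names(x) <- feature_names
  structure(
    list(x = x, intercept = intercept, lambda = lambda, rho = rho,
         objective_value = obj, converged = converged,
         iterations = iterations),
    class = "elastic_net_fit"
  )
}

#' @export
print.elastic_net_fit <- function(x, ...) {
  cat(sprintf(
    "Elastic-net logistic fit: lambda = %g, rho = %g, %d/%d features selected\n",
    x$lambda, x$rho, sum(abs(x$x) > 1e-8), length(x$x)))
  cat(sprintf("  objective %.6g after %d iterations%s\n", x$objective_value,
              x$iterations, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.elastic_net_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$x)
}

#' Predict from an elastic-net logistic fit
#'
#' @param object an `elastic_net_fit`.
#' @param newdata n x m feature matrix.
#' @param type "link" (x'a + c), "response" (P(y = +1)), or "class" (+1/-1).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.elastic_net_fit <- function(object, newdata,
                                    type = c("link", "response", "class"),
                                    ...) {
  type <- match.arg(type)
  f <- as.numeric(as.matrix(newdata) %*% object$x) + object$intercept
  switch(type,
         link = f,
         response = 1 / (1 + exp(-f)),
         class = ifelse(f >= 0, 1, -1))
}

#' Binary feature-selection mask from a fitted elastic net
#'
#' Features with |weight| above the zero threshold are marked selected.
#'
#' @param fit an `elastic_net_fit`.
#' @param zero_threshold magnitude below which a weight counts as zero.
#' @return logical vector (named like the features) with attribute `count`.
#' @export
select_features <- function(fit, zero_threshold = 1e-8) {
  mask <- abs(fit$x) > zero_threshold
  attr(mask, "count") <- sum(mask)
  mask
}
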