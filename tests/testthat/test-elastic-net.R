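test_that("objective matches closed forms and a term-by-term oracle", {
  set.seed(61)
  n <- 9; m <- 4
  A <- matrix(rnorm(n * m), n, m)
  y <- sign(rnorm(n))
  # x = 0, c = 0: every sample contributes log 2
  expect_equal(elastic_net_objective(numeric(m), 0, A, y, 0.3, 0.7),
               n * log(2))
  # lambda = rho = 0 reduces to the plain logistic loss
  x <- rnorm(m); c0 <- rnorm(1)
  f <- as.numeric(A %*% x) + c0
  expect_equal(elastic_net_objective(x, c0, A, y, 0, 0),
               sum(log(1 + exp(-y * f))))
  # random instance vs naive summation
  w <- runif(n, 0.5, 2)
  naive <- 0
  for (i in seq_len(n)) {
    naive <- naive + w[i] * log(1 + exp(-y[i] * (sum(x * A[i, ]) + c0)))
  }
  naive <- naive + 0.7 / 2 * sum(x^2) + 0.3 * sum(abs(x))
  expect_equal(elastic_net_objective(x, c0, A, y, 0.3, 0.7, w), naive,
               tolerance = 1e-12)
  # no overflow for extreme margins
  expect_true(is.finite(elastic_net_objective(rep(1e3, m), 0, A, y, 1, 1)))
})

test_that("above the critical lambda the fit is exactly zero with the
           weighted log-odds intercept", {
  set.seed(62)
  n_pos <- 36; n_neg <- 17
  y <- c(rep(1, n_pos), rep(-1, n_neg))
  A <- matrix(rnorm((n_pos + n_neg) * 5), ncol = 5)
  g0 <- abs(crossprod(A, y * (1 / (1 + exp(y * log(n_pos / n_neg))))))
  fit <- fit_elastic_net(A, y, lambda = max(g0) * 1.01, rho = 0.2)
  expect_identical(unname(fit$x), numeric(5))
  expect_equal(fit$intercept, log(36 / 17), tolerance = 1e-9)
  expect_equal(fit$intercept, 0.7503, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("the fit matches dense grid minimisation on a small problem", {
  set.seed(63)
  A <- matrix(rnorm(12), 6, 2)
  y <- c(1, 1, 1, -1, -1, -1)
  fit <- fit_elastic_net(A, y, lambda = 0.1, rho = 0.5)
  oracle <- bf_elastic_net_grid(A, y, lambda = 0.1, rho = 0.5)
  expect_lte(fit$objective_value, oracle$value + 1e-9)
  expect_equal(fit$objective_value, oracle$value, tolerance = 1e-6)
  expect_equal(unname(fit$x), c(oracle$best$x1, oracle$best$x2),
               tolerance = 5e-3)
  # stored objective is consistent with re-evaluation
  expect_equal(fit$objective_value,
               elastic_net_objective(fit$x, fit$intercept, A, y, 0.1, 0.5),
               tolerance = 1e-12)
})

test_that("the fitted objective never exceeds the objective at random points
           (convexity sanity)", {
  set.seed(64)
  for (trial in 1:10) {
    n <- sample(6:15, 1); m <- sample(2:5, 1)
    A <- matrix(rnorm(n * m), n, m)
    y <- c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))
    lambda <- runif(1, 0.01, 1); rho <- runif(1, 0.01, 1)
    fit <- fit_elastic_net(A, y, lambda, rho)
    for (k in 1:20) {
      xr <- rnorm(m); cr <- rnorm(1)
      expect_lte(fit$objective_value,
                 elastic_net_objective(xr, cr, A, y, lambda, rho) + 1e-9)
    }
  }
})

test_that("the fit agrees with glmnet under its reparameterisation", {
  skip_if_not_installed("glmnet")
  set.seed(65)
  n <- 50; m <- 12
  A <- matrix(rnorm(n * m), n, m)
  beta_true <- c(1.5, -2, rep(0, m - 2))
  y <- ifelse(A %*% beta_true + rnorm(n) > 0, 1, -1)
  for (pen in list(c(0.2, 0.4), c(0.05, 1.0), c(0.5, 0.1))) {
    lambda <- pen[1]; rho <- pen[2]
    fit <- fit_elastic_net(A, y, lambda, rho)
    g <- glmnet::glmnet(A, factor(y), family = "binomial",
                        alpha = lambda / (lambda + rho),
                        lambda = (lambda + rho) / n,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e6)
    obj_g <- elastic_net_objective(as.numeric(g$beta), as.numeric(g$a0),
                                   A, y, lambda, rho)
    expect_lte(fit$objective_value, obj_g + 1e-7)
    expect_equal(fit$objective_value, obj_g, tolerance = 1e-4)
    expect_equal(unname(fit$x), as.numeric(g$beta), tolerance = 5e-3)
  }
})

test_that("selection masks use the zero threshold", {
  fit <- netresect:::new_elastic_net_fit(c(0.3, 0, -0.2), 0, 0.1, 0.1,
                                         0, TRUE, 1L)
  mask <- select_features(fit)
  expect_equal(unname(as.logical(mask)), c(TRUE, FALSE, TRUE))
  expect_equal(attr(mask, "count"), 2)
  tiny <- netresect:::new_elastic_net_fit(c(1e-12, 0, 1e-7), 0, 0.1, 0.1,
                                          0, TRUE, 1L)
  expect_equal(unname(as.logical(select_features(tiny))),
               c(FALSE, FALSE, TRUE))
  zero <- netresect:::new_elastic_net_fit(numeric(3), 0, 0.1, 0.1, 0, TRUE, 1L)
  expect_equal(attr(select_features(zero), "count"), 0)
})

test_that("selected-feature count is non-increasing in lambda at fixed rho", {
  co <- make_cohort(n_per_class = 15,
                    block_sizes = c(connection_strength = 40,
                                    region_strength = 5, region_volume = 5),
                    n_informative = 5, seed = 99)
  A <- co$features$A; y <- co$features$y
  ladder <- seq(0.01, 0.96, by = 0.05)
  nsel <- vapply(ladder, function(lam) {
    sum(select_features(fit_elastic_net(A, y, lam, 0.51)))
  }, 0L)
  expect_true(all(diff(nsel) <= 0))
  expect_gte(nsel[1], 5) # the loosest fit keeps at least the planted features
  # and selection vanishes exactly once lambda clears the critical value
  c0 <- log(sum(y > 0) / sum(y < 0))
  crit <- max(abs(crossprod(A, y / (1 + exp(y * c0)))))
  expect_equal(sum(select_features(fit_elastic_net(A, y, crit * 1.01, 0.51))),
               0)
})
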