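test_that("the one-point worked example reproduces exact arithmetic", {
  X <- matrix(c(1, 0), nrow = 1)
  spec <- kernel_spec("linear", variance = 1)
  m <- gp_regression_model(X, 2, spec, sigma_n2 = 1, center = FALSE)
  pr <- predict(m, X)
  expect_equal(pr$.pred, 1.0, tolerance = 1e-7)
  expect_equal(pr$.pred_var, 0.5, tolerance = 1e-7)
  expect_equal(log_marginal_likelihood(m),
               -1 - 0.5 * log(2) - 0.5 * log(2 * pi),
               tolerance = 1e-7)
  expect_equal(log_marginal_likelihood(m), -2.2655, tolerance = 1e-4)
})

test_that("predictions match a dense-inverse oracle on random toys", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(2:20, 1); p <- sample(3:12, 1)
    X <- matrix(rbinom(n * p, 1, 0.5), n)
    y <- rnorm(n)
    form <- sample(c("linear", "squared_exponential", "matern52"), 1)
    spec <- kernel_spec(form, variance = runif(1, 0.5, 3),
                        lengthscale = runif(1, 1, 6))
    sn2 <- runif(1, 0.05, 1)
    m <- gp_regression_model(X, y, spec, sigma_n2 = sn2, center = FALSE)
    xs <- rbinom(p, 1, 0.5)
    pr <- predict(m, matrix(xs, 1))
    K <- kernel_matrix(spec, X)
    ks <- kernel_matrix(spec, X, matrix(xs, 1))
    oracle <- gp_oracle(K, ks, kernel_value(spec, xs, xs), y, sn2)
    expect_equal(pr$.pred, oracle$mean, tolerance = 1e-8)
    expect_equal(pr$.pred_var, oracle$var, tolerance = 1e-8)
    expect_equal(m$lml, oracle$lml, tolerance = 1e-8)
  }
})

test_that("degenerate cases: prior, interpolation, zero response", {
  spec <- kernel_spec("squared_exponential", variance = 2, lengthscale = 3)
  # empty training set: prior mean 0 and variance k(x, x)
  m0 <- gp_regression_model(NULL, numeric(0), spec)
  pr <- predict(m0, matrix(c(1, 0, 1), 1))
  expect_equal(pr$.pred, 0)
  expect_equal(pr$.pred_var, 2)
  # noiseless model interpolates its training points
  set.seed(3)
  X <- matrix(rbinom(5 * 6, 1, 0.5), 5)
  X <- X[!duplicated(X), , drop = FALSE]
  y <- rnorm(nrow(X))
  mi <- gp_regression_model(X, y, spec, sigma_n2 = 0, center = FALSE)
  expect_equal(predict(mi, X)$.pred, y, tolerance = 1e-3)
  # y = 0: the quadratic term vanishes from the marginal likelihood
  yz <- rep(0, nrow(X))
  mz <- gp_regression_model(X, yz, spec, sigma_n2 = 0.5, center = FALSE)
  K <- kernel_matrix(spec, X)
  expect_equal(mz$lml,
               -0.5 * determinant(K + diag(0.5, nrow(X)))$modulus[1] -
                 nrow(X) / 2 * log(2 * pi),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("an added duplicate contributes exactly its conditional density", {
  set.seed(4)
  X <- matrix(rbinom(6 * 5, 1, 0.5), 6)
  y <- rnorm(6)
  spec <- kernel_spec("linear", variance = 1.2)
  m1 <- gp_regression_model(X, y, spec, sigma_n2 = 0.4, center = FALSE)
  m2 <- gp_regression_model(rbind(X, X[1, ]), c(y, y[1]), spec,
                            sigma_n2 = 0.4, center = FALSE)
  # chain rule: lml grows by log N(y_new; pred mean, pred var + noise)
  pr <- predict(m1, X[1, , drop = FALSE])
  expect_equal(m2$lml - m1$lml,
               dnorm(y[1], pr$.pred, sqrt(pr$.pred_var + 0.4), log = TRUE),
               tolerance = 1e-6)
  # and with this noise level the conditional density is < 1, so total
  # log marginal likelihood drops
  expect_lt(m2$lml, m1$lml)
})

test_that("fitted hyperparameters reach the grid-search optimum", {
  # data generated from a known linear-kernel GP
  set.seed(20)
  n <- 40; p <- 10
  X <- matrix(rbinom(n * p, 1, 0.5), n)
  w <- rnorm(p, 0, sqrt(0.8))
  y <- drop(X %*% w) + rnorm(n, 0, sqrt(0.1))
  fit <- fit_gp_regression(X, y, kernel = "linear", n_restarts = 5)
  # dense grid oracle over the 2 log-hyperparameters
  grid <- expand.grid(lv = seq(log(1e-2), log(1e2), length.out = 41),
                      ln = seq(log(1e-3), log(1e1), length.out = 41))
  grid_lml <- vapply(seq_len(nrow(grid)), function(i) {
    gp_regression_model(X, y, kernel_spec("linear", variance = exp(grid$lv[i])),
                        sigma_n2 = exp(grid$ln[i]))$lml
  }, numeric(1))
  expect_gte(fit$lml, max(grid_lml) - 1e-3)
  best <- grid[which.max(grid_lml), ]
  expect_equal(log(fit$spec$variance), best$lv, tolerance = 0.3)
  expect_equal(log(fit$sigma_n2), best$ln, tolerance = 0.3)
})

test_that("conflicting duplicates force noise; constant y flattens signal", {
  X <- matrix(rep(c(1, 0, 1, 1), 4), 4, byrow = TRUE)
  y <- c(1, -1, 1, -1)  # identical inputs, conflicting outputs
  fit <- fit_gp_regression(X, y, kernel = "linear", n_restarts = 4)
  expect_gt(fit$sigma_n2, 1e-6)
  m0 <- gp_regression_model(X, y, fit$spec, sigma_n2 = 1e-8)
  expect_gt(fit$lml, m0$lml)
  # constant responses: variance driven down, predictions ~ constant
  set.seed(6)
  Xc <- matrix(rbinom(6 * 5, 1, 0.5), 6)
  fitc <- fit_gp_regression(Xc, rep(3, 6), kernel = "linear", n_restarts = 4)
  expect_equal(predict(fitc, Xc)$.pred, rep(3, 6), tolerance = 1e-3)
})

test_that("hyperparameter fitting is invariant to observation order", {
  set.seed(8)
  n <- 20; p <- 6
  X <- matrix(rbinom(n * p, 1, 0.5), n)
  y <- rnorm(n)
  f1 <- fit_gp_regression(X, y, kernel = "squared_exponential", n_restarts = 4)
  perm <- sample(n)
  f2 <- fit_gp_regression(X[perm, ], y[perm], kernel = "squared_exponential",
                          n_restarts = 4)
  expect_equal(f1$lml, f2$lml, tolerance = 1e-5)
  expect_equal(f1$spec$variance, f2$spec$variance, tolerance = 1e-3)
  expect_equal(f1$spec$lengthscale, f2$spec$lengthscale, tolerance = 1e-3)
})

test_that("posterior variance never increases as data accumulate", {
  set.seed(12)
  p <- 8
  X <- matrix(rbinom(15 * p, 1, 0.5), 15)
  y <- rnorm(15)
  spec <- kernel_spec("matern52", variance = 1.5, lengthscale = 4)
  xs <- matrix(rbinom(3 * p, 1, 0.5), 3)
  prev <- rep(Inf, 3)
  for (n in c(2, 5, 10, 15)) {
    m <- gp_regression_model(X[1:n, ], y[1:n], spec, sigma_n2 = 0.2)
    v <- predict(m, xs)$.pred_var
    expect_true(all(v <= prev + 1e-8))
    prev <- v
  }
})

test_that("linear-kernel GP equals closed-form Bayesian ridge regression", {
  set.seed(14)
  n <- 18; p <- 5
  X <- matrix(rbinom(n * p, 1, 0.5), n)
  y <- rnorm(n)
  sp2 <- 1.3; sn2 <- 0.4
  m <- gp_regression_model(X, y, kernel_spec("linear", variance = sp2),
                           sigma_n2 = sn2, center = FALSE)
  # weight-space view: w ~ N(0, sp2 I); posterior mean X* A^-1 X' y * sp2...
  A <- crossprod(X) + diag(sn2 / sp2, p)
  w_post <- solve(A, crossprod(X, y))
  xs <- matrix(rbinom(4 * p, 1, 0.5), 4)
  expect_equal(predict(m, xs)$.pred, drop(xs %*% w_post), tolerance = 1e-6)
})

test_that("kernlab agrees with fixed-hyperparameter SE predictions", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  n <- 15; p <- 6
  X <- matrix(rbinom(n * p, 1, 0.5), n)
  y <- rnorm(n)
  l <- 4; sn2 <- 0.3
  spec <- kernel_spec("squared_exponential", variance = 1, lengthscale = l)
  m <- gp_regression_model(X, y, spec, sigma_n2 = sn2, center = FALSE)
  Xs <- matrix(rbinom(10 * p, 1, 0.5), 10)
  theirs <- as.numeric(kernlab::predict(
    kernlab::gausspr(X, y, type = "regression", kernel = "rbfdot",
                     kpar = list(sigma = 1 / (2 * l)), var = sn2,
                     scaled = FALSE),
    Xs))
  expect_equal(predict(m, Xs)$.pred, theirs, tolerance = 1e-6)
})

test_that("LOO equals refitting without each point, and scores signal", {
  set.seed(16)
  n <- 15; p <- 6
  # a constant-one feature mirrors the conserved-position columns every
  # real encoding carries
  X <- cbind(1, matrix(rbinom(n * p, 1, 0.5), n))
  w <- rnorm(p + 1)
  y <- drop(X %*% w) + rnorm(n, 0, 0.1)
  fit <- fit_gp_regression(X, y, kernel = "linear", n_restarts = 4)
  loo <- loo_cv(X, y, model = fit)
  for (i in seq_len(n)) {
    refit <- gp_regression_model(X[-i, , drop = FALSE], y[-i], fit$spec,
                                 sigma_n2 = fit$sigma_n2,
                                 center = fit$y_mean)
    pr <- predict(refit, X[i, , drop = FALSE])
    expect_equal(loo$predictions$.pred[i], pr$.pred, tolerance = 1e-6)
    expect_equal(loo$predictions$.pred_var[i], pr$.pred_var + fit$sigma_n2,
                 tolerance = 1e-6)
  }
  # noiseless linear data in feature space: R ~ 1
  # (noiseless data drives sigma_n^2 to its bound; the optimizer warning
  # about formal convergence there is expected)
  y0 <- drop(X %*% w)
  loo0 <- suppressWarnings(loo_cv(X, y0, kernel = "linear", n_restarts = 4))
  expect_gt(loo0$r_pearson, 0.999)
})

test_that("LOO finds no positive signal in shuffled responses", {
  set.seed(18)
  n <- 50; p <- 10
  X <- cbind(1, matrix(rbinom(n * p, 1, 0.5), n))
  y <- drop(X %*% rnorm(p + 1)) + rnorm(n, 0, 0.2)
  r_signal <- loo_cv(X, y, kernel = "linear", n_restarts = 2)$r_pearson
  expect_gt(r_signal, 0.9)
  rs <- vapply(1:20, function(k) {
    ys <- sample(y)
    loo_cv(X, ys, kernel = "linear", n_restarts = 2)$r_pearson
  }, numeric(1))
  # under the null the LOO correlation is centred at or below zero (the
  # sum-zero residual constraint makes it mildly anti-correlated), far
  # from the signal case
  expect_lt(mean(rs), 0.1)
  expect_true(all(rs < r_signal - 0.2))
})
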