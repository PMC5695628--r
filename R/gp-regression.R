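#' Gaussian process regression model at fixed hyperparameters
#'
#' Builds the GP posterior for given kernel and noise variance without any
#' hyperparameter optimization. The posterior predictive at a new input
#' \eqn{x_*} is Gaussian with mean
#' \eqn{\bar f_* = k_*^T (K + \sigma_n^2 I)^{-1} y} and variance
#' \eqn{v_* = k(x_*, x_*) - k_*^T (K + \sigma_n^2 I)^{-1} k_*},
#' computed through a cached Cholesky factorization (never an explicit
#' inverse). Responses are centred by their training mean (added back at
#' prediction); with zero training rows the model is the GP prior.
#'
#' @param X Training feature matrix (rows = variants); may be `NULL` or have
#'   zero rows for a prior model.
#' @param y Numeric response vector (modeled scale, typically log2).
#' @param spec A [kernel_spec()].
#' @param sigma_n2 Observation noise variance \eqn{\sigma_n^2 \ge 0}.
#' @param center Either `TRUE` (centre by the training mean), `FALSE`
#'   (assume zero mean), or a number to use as the fixed mean.
#' @return An object of class `gp_regression`.
#' @export
gp_regression_model <- function(X, y, spec, sigma_n2 = 0, center = TRUE) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (sigma_n2 < 0) abort("`sigma_n2` must be nonnegative.", class = "chimeraGP_error")
  n <- if (is.null(X)) 0L else nrow(X)
  if (n == 0L) {
    return(structure(
      list(spec = spec, sigma_n2 = sigma_n2, X = NULL, y = numeric(0),
           y_mean = if (is.numeric(center)) center else 0,
           L = NULL, alpha = numeric(0), lml = NA_real_, n = 0L),
      class = "gp_regression"
    ))
  }
  if (length(y) != n) abort("length(y) must equal nrow(X).", class = "chimeraGP_error")
  if (any(!is.finite(y))) abort("Non-finite responses.", class = "chimeraGP_error")
  y_mean <- if (isTRUE(center)) mean(y) else if (is.numeric(center)) center else 0
  yc <- y - y_mean
  K <- kernel_matrix(spec, X)
  L <- chol_jitter(K + diag(sigma_n2, n))
  alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
  lml <- -0.5 * sum(yc * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  structure(
    list(spec = spec, sigma_n2 = sigma_n2, X = X, y = y, y_mean = y_mean,
         L = L, alpha = alpha, lml = lml, n = n),
    class = "gp_regression"
  )
}

#' @export
print.gp_regression <- function(x, ...) {
  cat(sprintf(
    "<gp_regression> %s kernel, n = %d, sigma_n^2 = %.4g, log marginal likelihood = %.4f\n",
    x$spec$form, x$n, x$sigma_n2, x$lml))
  invisible(x)
}

#' Log marginal likelihood of a GP regression model
#'
#' \eqn{\log p(y \mid X) = -\tfrac12 y^T (K+\sigma_n^2 I)^{-1} y -
#' \tfrac12 \log |K+\sigma_n^2 I| - \tfrac n2 \log 2\pi}, with `n` the number
#' of training observations.
#'
#' @param model A `gp_regression` model.
#' @export
log_marginal_likelihood <- function(model) model$lml

#' @export
predict.gp_regression <- function(object, newdata, ...) {
  Xnew <- newdata
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  kss <- kernel_diag(object$spec, Xnew)
  if (object$n == 0L) {
    return(tibble(.pred = rep(object$y_mean, nrow(Xnew)),
                  .pred_var = kss, .pred_sd = sqrt(kss)))
  }
  Kstar <- kernel_matrix(object$spec, object$X, Xnew)  # n x m
  mean <- drop(crossprod(Kstar, object$alpha)) + object$y_mean
  v <- backsolve(object$L, Kstar, transpose = TRUE)
  var <- pmax(kss - colSums(v^2), 0)
  tibble(.pred = mean, .pred_var = var, .pred_sd = sqrt(var))
}

# ---- hyperparameter optimization -------------------------------------------

# theta layout: linear -> (log sigma_p2, log sigma_n2)
#               nonlinear -> (log sigma_p2, log lengthscale, log sigma_n2)
theta_to_spec <- function(theta, form, base_spec = NULL) {
  if (form == "linear") {
    list(spec = kernel_spec("linear", variance = exp(theta[1]),
                            feature_subset = base_spec$feature_subset),
         sigma_n2 = exp(theta[2]))
  } else {
    list(spec = kernel_spec(form, variance = exp(theta[1]),
                            lengthscale = exp(theta[2]),
                            feature_subset = base_spec$feature_subset),
         sigma_n2 = exp(theta[3]))
  }
}

# negative log marginal likelihood and its gradient in log-hyperparameter
# space; D2/cross precomputed once per dataset.
make_reg_objective <- function(X, yc, form, feature_subset = NULL) {
  Xs <- if (is.null(feature_subset)) X else X[, feature_subset, drop = FALSE]
  extra <- attr(X, "extra_active")
  cross <- as.matrix(Xs %*% Matrix::t(Xs))
  if (!is.null(extra)) cross <- cross + diag(as.numeric(extra), nrow(cross))
  D2 <- NULL
  if (form != "linear") {
    D2 <- outer(diag(cross), diag(cross), "+") - 2 * cross
    D2 <- pmax(D2, 0)
  }
  n <- nrow(cross)
  function(theta) {
    sp2 <- exp(theta[1])
    if (form == "linear") {
      l <- NULL; sn2 <- exp(theta[2])
      Kf <- sp2 * cross
      dK_dl <- NULL
    } else {
      l <- exp(theta[2]); sn2 <- exp(theta[3])
      if (form == "squared_exponential") {
        Kf <- sp2 * exp(-D2 / (2 * l))
        dK_dl <- Kf * D2 / (2 * l)
      } else {
        a <- sqrt(5 * D2) / l
        E <- exp(-a)
        Kf <- sp2 * (1 + a + a^2 / 3) * E
        dK_dl <- sp2 * (a^2 / 3) * (1 + a) * E
      }
    }
    C <- Kf + diag(sn2, n)
    L <- tryCatch(chol_jitter(C), error = function(e) NULL)
    if (is.null(L)) {
      return(list(value = 1e10, gradient = rep(0, length(theta))))
    }
    alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
    nll <- 0.5 * sum(yc * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
    Cinv <- chol2inv(L)
    A <- tcrossprod(alpha) - Cinv  # d lml / dC = A / 2
    g_sp2 <- 0.5 * sum(A * Kf)
    g_sn2 <- 0.5 * sn2 * sum(diag(A))
    grad <- if (form == "linear") c(g_sp2, g_sn2)
            else c(g_sp2, 0.5 * sum(A * dK_dl), g_sn2)
    list(value = nll, gradient = -grad)
  }
}

restart_inits <- function(form, n_restarts, seed, y_var, D2_med) {
  k <- if (form == "linear") 2L else 3L
  # heuristic first start, then seeded log-uniform draws over [1e-3, 1e3]
  first <- if (form == "linear") {
    c(log(max(y_var, 1e-3)), log(max(y_var / 10, 1e-3)))
  } else {
    c(log(max(y_var, 1e-3)), log(max(D2_med, 1)), log(max(y_var / 10, 1e-3)))
  }
  inits <- list(first)
  if (n_restarts > 1) {
    draws <- with_seed(seed, matrix(runif((n_restarts - 1) * k,
                                          log(1e-3), log(1e3)),
                                    ncol = k))
    inits <- c(inits, lapply(seq_len(nrow(draws)), function(i) draws[i, ]))
  }
  inits
}

#' Fit a GP regression model by marginal-likelihood maximization
#'
#' Hyperparameters (\eqn{\sigma_p^2}, lengthscale where applicable, and
#' \eqn{\sigma_n^2}) are optimized in log-space by multi-start L-BFGS with
#' analytic gradients; the best restart is kept and all restarts are
#' recorded. With `kernel = "auto"` all three kernel forms are fitted and
#' the one with the highest log marginal likelihood is returned.
#'
#' @param X Training feature matrix.
#' @param y Numeric responses (modeled scale, typically log2).
#' @param kernel Kernel form: `"linear"`, `"squared_exponential"`,
#'   `"matern52"`, or `"auto"`.
#' @param feature_subset Optional integer vector restricting the kernel to a
#'   subset of feature columns (e.g. the L1-selected features).
#' @param n_restarts Number of optimizer starts (default 10).
#' @param seed Seed for the restart draws (default 0).
#' @return A `gp_regression` model with elements `restarts` (tibble of all
#'   starts) and, for `"auto"`, `form_selection` (per-form best lml).
#' @export
fit_gp_regression <- function(X, y, kernel = "linear", feature_subset = NULL,
                              n_restarts = 10, seed = 0) {
  if (nrow(X) < 2) abort("Need at least 2 observations.", class = "chimeraGP_error")
  if (identical(kernel, "auto")) {
    forms <- c("linear", "squared_exponential", "matern52")
    fits <- lapply(forms, function(f) {
      fit_gp_regression(X, y, kernel = f, feature_subset = feature_subset,
                        n_restarts = n_restarts, seed = seed)
    })
    lmls <- map_dbl(fits, "lml")
    best <- fits[[which.max(lmls)]]
    best$form_selection <- tibble(form = forms, lml = lmls)
    return(best)
  }
  form <- kernel_spec(kernel)$form
  y_mean <- mean(y)
  yc <- y - y_mean
  obj <- make_reg_objective(X, yc, form, feature_subset)
  D2_med <- 1
  if (form != "linear") {
    Xs <- if (is.null(feature_subset)) X else X[, feature_subset, drop = FALSE]
    cross <- as.matrix(Xs %*% Matrix::t(Xs))
    D2 <- pmax(outer(diag(cross), diag(cross), "+") - 2 * cross, 0)
    D2_med <- stats::median(D2[upper.tri(D2)])
  }
  inits <- restart_inits(form, n_restarts, seed, stats::var(yc), D2_med)
  lower <- c(log(1e-6), if (form != "linear") log(1e-6), log(1e-8))
  upper <- rep(log(1e6), length(inits[[1]]))
  runs <- lapply(seq_along(inits), function(i) {
    res <- tryCatch(
      optim(inits[[i]], fn = function(t) obj(t)$value,
            gr = function(t) obj(t)$gradient,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) list(par = inits[[i]], value = Inf, convergence = 99)
    )
    list(start = i, par = res$par, value = res$value,
         convergence = res$convergence)
  })
  values <- map_dbl(runs, "value")
  if (all(!is.finite(values))) {
    abort("Hyperparameter optimization failed for every restart.",
          class = "chimeraGP_numeric_error")
  }
  best <- runs[[which.min(values)]]
  if (best$convergence != 0) {
    warn("Optimizer did not formally converge; best value found is used.")
  }
  par <- theta_to_spec(best$par, form, list(feature_subset = feature_subset))
  model <- gp_regression_model(X, y, par$spec, sigma_n2 = par$sigma_n2)
  model$restarts <- tibble(
    start = map_int(runs, "start"),
    nll = values,
    convergence = map_int(runs, ~ as.integer(.x$convergence))
  )
  model$seed <- seed
  model
}

#' Leave-one-out cross-validation for GP regression
#'
#' For each observation, the posterior trained on all other observations
#' (at the hyperparameters of the full fit) predicts the held-out response.
#' The LOO means and variances are obtained exactly from the full
#' factorization via the standard identities
#' \eqn{\mu_i = y_i - [C^{-1} y]_i / [C^{-1}]_{ii}} and
#' \eqn{v_i = 1 / [C^{-1}]_{ii}} with \eqn{C = K + \sigma_n^2 I}.
#'
#' @inheritParams fit_gp_regression
#' @param model Optionally a prefitted `gp_regression` model on (X, y);
#'   if omitted one is fitted first.
#' @param ... Passed to [fit_gp_regression()].
#' @return An object of class `gp_loo`: list with `predictions` (tibble with
#'   `y`, `.pred`, `.pred_sd`), `r_pearson`, `r_spearman`, `model`.
#' @export
loo_cv <- function(X, y, kernel = "linear", model = NULL, ...) {
  if (length(y) < 3) abort("LOO needs n >= 3.", class = "chimeraGP_error")
  if (is.null(model)) model <- fit_gp_regression(X, y, kernel = kernel, ...)
  Cinv <- chol2inv(model$L)
  d <- diag(Cinv)
  yc <- y - model$y_mean
  alpha <- model$alpha
  mu <- y - alpha / d
  v <- 1 / d
  preds <- tibble(obs = seq_along(y), y = y, .pred = mu,
                  .pred_var = v, .pred_sd = sqrt(v))
  structure(
    list(predictions = preds,
         r_pearson = cor(y, mu),
         r_spearman = cor(y, mu, method = "spearman"),
         model = model),
    class = "gp_loo"
  )
}

#' @export
print.gp_loo <- function(x, ...) {
  cat(sprintf("<gp_loo> n = %d, Pearson R = %.3f (Spearman %.3f)\n",
              nrow(x$predictions), x$r_pearson, x$r_spearman))
  invisible(x)
}
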