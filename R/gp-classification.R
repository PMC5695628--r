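sigmoid <- function(z) 1 / (1 + exp(-z))

# Gauss-Hermite average of the logistic sigmoid under N(mu, v)
gh_cache <- new.env(parent = emptyenv())
logistic_gauss_integral <- function(mu, v, nodes = 40) {
  key <- as.character(nodes)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(nodes)
  gh <- gh_cache[[key]]
  s <- sqrt(2 * pmax(v, 0))
  vapply(seq_along(mu), function(i) {
    sum(gh$w * sigmoid(mu[i] + s[i] * gh$x)) / sqrt(pi)
  }, numeric(1))
}

#' Threshold measurements into 'high'/'low' classes
#'
#' The class threshold for a property is the measured value of the
#' lowest-performing parent (ties at the threshold are 'high'): a variant is
#' a 'high' performer if it does at least as well as the worst parent.
#' Below-detection (`NA`) measurements are labeled 'low'.
#'
#' @param measurements Measurements tibble.
#' @param property Name of the numeric column to threshold (e.g.
#'   `"GFP_mean"`).
#' @param parent_names Names of the parent rows, matched against `name_col`.
#' @param name_col Column holding variant names (default `"chimera_name"`).
#' @return An object of class `class_labeling`: list with `threshold`,
#'   `lowest_parent`, and `data` (the measurements plus `.label` in
#'   \{"high","low"\} and `.y` in \{+1,-1\}).
#' @export
make_labels <- function(measurements, property, parent_names,
                        name_col = "chimera_name") {
  vals <- measurements[[property]]
  nm <- measurements[[name_col]]
  pv <- vapply(parent_names, function(p) {
    rows <- which(nm == p)
    if (!length(rows)) return(NA_real_)
    mean(vals[rows], na.rm = TRUE)
  }, numeric(1))
  if (anyNA(pv)) {
    abort(sprintf("Missing parent measurement(s): %s",
                  paste(parent_names[is.na(pv)], collapse = ", ")),
          class = "chimeraGP_error")
  }
  threshold <- min(pv)
  label <- ifelse(!is.na(vals) & vals >= threshold, "high", "low")
  data <- measurements
  data$.label <- label
  data$.y <- ifelse(label == "high", 1, -1)
  structure(
    list(threshold = threshold,
         lowest_parent = names(pv)[which.min(pv)],
         property = property, data = data),
    class = "class_labeling"
  )
}

#' @export
print.class_labeling <- function(x, ...) {
  cat(sprintf(
    "<class_labeling> '%s': threshold %.4g (lowest parent: %s); %d high / %d low\n",
    x$property, x$threshold, x$lowest_parent,
    sum(x$data$.label == "high"), sum(x$data$.label == "low")))
  invisible(x)
}

as_pm1 <- function(labels) {
  if (inherits(labels, "class_labeling")) labels <- labels$data$.label
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("high", "low"))) {
      abort("Character labels must be 'high'/'low'.", class = "chimeraGP_error")
    }
    return(ifelse(labels == "high", 1, -1))
  }
  if (is.logical(labels)) return(ifelse(labels, 1, -1))
  if (all(labels %in% c(-1, 1))) return(as.numeric(labels))
  if (all(labels %in% c(0, 1))) return(ifelse(labels == 1, 1, -1))
  abort("Cannot interpret class labels.", class = "chimeraGP_error")
}

# Laplace mode finding for logistic likelihood (damped Newton on the
# stable parameterization B = I + W^1/2 K W^1/2). Returns the mode,
# its derivative quantities and the Laplace-approximate log marginal
# likelihood.
laplace_mode <- function(K, y, tol = 1e-6, max_iter = 100) {
  n <- length(y)
  t_vec <- (y + 1) / 2
  f <- rep(0, n)
  a <- rep(0, n)
  obj_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pi_f <- sigmoid(f)
    W <- pmax(pi_f * (1 - pi_f), 1e-12)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    U <- chol_jitter(B, jitter = 0)
    b <- W * f + (t_vec - pi_f)
    KB <- K %*% b
    a_new <- b - sW * backsolve(U, backsolve(U, sW * KB, transpose = TRUE))
    # damped step in a-space
    step <- 1
    repeat {
      a_try <- a + step * (a_new - a)
      f_try <- drop(K %*% a_try)
      obj <- -0.5 * sum(a_try * f_try) - sum(log1p(exp(-y * f_try)))
      if (obj >= obj_old - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    a <- a + step * (a_new - a)
    f <- drop(K %*% a)
    grad <- (t_vec - sigmoid(f)) - a
    obj_old <- -0.5 * sum(a * f) - sum(log1p(exp(-y * f)))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf(
      "Laplace Newton iteration did not reach gradient tolerance (max |grad| = %.2e).",
      max(abs(grad))))
  }
  pi_f <- sigmoid(f)
  W <- pmax(pi_f * (1 - pi_f), 1e-12)
  sW <- sqrt(W)
  U <- chol_jitter(diag(n) + (sW %o% sW) * K, jitter = 0)
  lml <- -0.5 * sum(a * f) - sum(log1p(exp(-y * f))) - sum(log(diag(U)))
  list(f = f, a = a, W = W, sW = sW, U = U, lml = lml,
       grad_resid = t_vec - pi_f, converged = converged)
}

#' Fit a GP binary classifier with the Laplace approximation
#'
#' Class labels are \eqn{y_i \in \{+1, -1\}} with a logistic likelihood; the
#' latent posterior mode is found by damped Newton iteration to gradient
#' norm below 1e-6, and the Laplace-approximate marginal likelihood is
#' maximized over the kernel hyperparameters by multi-start optimization in
#' log-space. There is no noise hyperparameter. With `kernel = "auto"` all
#' three kernel forms are fitted and the best by approximate marginal
#' likelihood is kept.
#'
#' @inheritParams fit_gp_regression
#' @param labels Class labels: a [make_labels()] result, `"high"`/`"low"`
#'   strings, logicals, or ±1.
#' @return An object of class `gp_classifier`.
#' @export
fit_gp_classifier <- function(X, labels, kernel = "linear",
                              feature_subset = NULL, n_restarts = 10,
                              seed = 0) {
  y <- as_pm1(labels)
  if (length(unique(y)) < 2) {
    abort("Both classes must be present to fit a classifier.",
          class = "chimeraGP_error")
  }
  if (identical(kernel, "auto")) {
    forms <- c("linear", "squared_exponential", "matern52")
    fits <- lapply(forms, function(f) {
      fit_gp_classifier(X, y, kernel = f, feature_subset = feature_subset,
                        n_restarts = n_restarts, seed = seed)
    })
    lmls <- map_dbl(fits, "lml")
    best <- fits[[which.max(lmls)]]
    best$form_selection <- tibble(form = forms, lml = lmls)
    return(best)
  }
  form <- kernel_spec(kernel)$form
  Xs <- if (is.null(feature_subset)) X else X[, feature_subset, drop = FALSE]
  cross <- as.matrix(Xs %*% Matrix::t(Xs))
  D2 <- NULL
  if (form != "linear") {
    D2 <- pmax(outer(diag(cross), diag(cross), "+") - 2 * cross, 0)
  }
  kern_of <- function(theta) {
    sp2 <- exp(theta[1])
    if (form == "linear") return(sp2 * cross)
    l <- exp(theta[2])
    if (form == "squared_exponential") return(sp2 * exp(-D2 / (2 * l)))
    a <- sqrt(5 * D2) / l
    sp2 * (1 + a + a^2 / 3) * exp(-a)
  }
  nll <- function(theta) {
    K <- kern_of(theta)
    res <- tryCatch(
      suppressWarnings(laplace_mode(K, y)),
      error = function(e) NULL
    )
    if (is.null(res)) return(1e10)
    -res$lml
  }
  k <- if (form == "linear") 1L else 2L
  D2_med <- if (is.null(D2)) 1 else stats::median(D2[upper.tri(D2)])
  first <- if (form == "linear") 0 else c(0, log(max(D2_med, 1)))
  inits <- list(first)
  if (n_restarts > 1) {
    draws <- with_seed(seed, matrix(runif((n_restarts - 1) * k,
                                          log(1e-3), log(1e3)), ncol = k))
    inits <- c(inits, lapply(seq_len(nrow(draws)), function(i) draws[i, ]))
  }
  runs <- lapply(inits, function(init) {
    tryCatch(
      optim(init, nll, method = "L-BFGS-B",
            lower = rep(log(1e-6), k), upper = rep(log(1e6), k),
            control = list(maxit = 100)),
      error = function(e) list(par = init, value = Inf, convergence = 99)
    )
  })
  values <- map_dbl(runs, "value")
  best <- runs[[which.min(values)]]
  spec <- if (form == "linear") {
    kernel_spec("linear", variance = exp(best$par[1]),
                feature_subset = feature_subset)
  } else {
    kernel_spec(form, variance = exp(best$par[1]),
                lengthscale = exp(best$par[2]),
                feature_subset = feature_subset)
  }
  K <- kernel_matrix(spec, X)
  lap <- laplace_mode(K, y)
  structure(
    list(spec = spec, X = X, y = y, link = "logistic",
         f_hat = lap$f, grad_resid = lap$grad_resid,
         sW = lap$sW, U = lap$U, lml = lap$lml,
         converged = lap$converged,
         restarts = tibble(nll = values),
         seed = seed, n = length(y)),
    class = "gp_classifier"
  )
}

#' GP classifier at fixed hyperparameters
#'
#' Runs the Laplace approximation for a given kernel without hyperparameter
#' optimization (useful for oracle comparisons and library scans with a
#' frozen model).
#'
#' @inheritParams gp_regression_model
#' @param labels Class labels (see [fit_gp_classifier()]).
#' @export
gp_classifier_model <- function(X, labels, spec) {
  y <- as_pm1(labels)
  K <- kernel_matrix(spec, X)
  lap <- laplace_mode(K, y)
  structure(
    list(spec = spec, X = X, y = y, link = "logistic",
         f_hat = lap$f, grad_resid = lap$grad_resid,
         sW = lap$sW, U = lap$U, lml = lap$lml,
         converged = lap$converged, n = length(y)),
    class = "gp_classifier"
  )
}

#' @export
print.gp_classifier <- function(x, ...) {
  cat(sprintf(
    "<gp_classifier> %s kernel (logistic link), n = %d (%d high / %d low), Laplace lml = %.4f\n",
    x$spec$form, x$n, sum(x$y == 1), sum(x$y == -1), x$lml))
  invisible(x)
}

#' @export
predict.gp_classifier <- function(object, newdata, ...) {
  Xnew <- newdata
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Kstar <- kernel_matrix(object$spec, object$X, Xnew)  # n x m
  mu <- drop(crossprod(Kstar, object$grad_resid))
  v <- backsolve(object$U, object$sW * Kstar, transpose = TRUE)
  var <- pmax(kernel_diag(object$spec, Xnew) - colSums(v^2), 0)
  prob <- logistic_gauss_integral(mu, var)
  tibble(.latent_mean = mu, .latent_var = var, .prob = prob)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores count one half. 1.0 means the
#' scores perfectly separate the classes; 0.5 is chance level.
#'
#' @param labels Class labels (positives = 'high' / `TRUE` / +1).
#' @param scores Numeric scores, higher = more likely positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  y <- as_pm1(labels)
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to compute AUC.",
          class = "chimeraGP_error")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' True/false positive rates at every distinct score threshold (no binning).
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered for plotting; the
#'   trapezoidal integral of this curve equals [roc_auc()].
#' @export
roc_points <- function(labels, scores) {
  y <- as_pm1(labels)
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present.", class = "chimeraGP_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  tp <- cumsum(yy == 1); fp <- cumsum(yy == -1)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tibble(
    threshold = c(Inf, s[last_of_tie]),
    tpr = c(0, tp[last_of_tie] / n1),
    fpr = c(0, fp[last_of_tie] / n0)
  )
}

#' Scan a recombination library with a classifier
#'
#' Streams over every chimera of the given designs in fixed-size chunks,
#' predicting the probability of the 'high' class, and reports the fraction
#' of the library above a probability threshold.
#'
#' @param model A fitted `gp_classifier`.
#' @param parents,designs Library definition (see [enumerate_chimeras()]).
#' @param encoding The [build_encoding()] the model was trained in.
#' @param threshold Probability cutoff for the summary fraction
#'   (default 0.5).
#' @param chunk_size Chimeras per chunk (default 5000).
#' @return A tibble (`id`, `.prob`) with attributes `fraction_above` and
#'   `threshold`.
#' @export
classify_library <- function(model, parents, designs, encoding,
                             threshold = 0.5, chunk_size = 5000) {
  scan <- scan_designs(parents, designs, encoding, chunk_size,
                       function(X) predict(model, X)$.prob)
  out <- tibble(id = scan$id, .prob = scan$value)
  attr(out, "fraction_above") <- mean(out$.prob > threshold)
  attr(out, "threshold") <- threshold
  out
}

# shared chunked library scanner: fun(X_chunk) -> numeric vector or data
# frame of per-chimera values
scan_designs <- function(parents, designs, encoding, chunk_size, fun) {
  designs <- as_design_list(designs)
  ids <- character(0)
  vals <- list()
  for (d in designs) {
    check_design(d, parents)
    n <- parents$n_parents^d$n_blocks
    starts <- seq(0, n - 1, by = chunk_size)
    for (s in starts) {
      idx <- s:min(s + chunk_size - 1, n - 1)
      A <- assignment_chunk(idx, d$n_blocks, parents$n_parents)
      X <- encode_assignments(A, d, encoding)
      digits <- matrix(as.character(A - 1L), nrow = nrow(A))
      ids <- c(ids, paste0(d$library_id,
                           apply(digits, 1, paste, collapse = "")))
      vals[[length(vals) + 1L]] <- fun(X)
    }
  }
  if (is.data.frame(vals[[1]])) {
    list(id = ids, value = dplyr::bind_rows(vals))
  } else {
    list(id = ids, value = unlist(vals))
  }
}
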