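#' Kernel specification
#'
#' Covariance functions over binary sequence/structure feature vectors.
#' Three forms are supported:
#' \describe{
#'   \item{linear}{\eqn{k(x, x') = \sigma_p^2 \, x^T x'} — an additive
#'     landscape with no epistasis.}
#'   \item{squared exponential}{\eqn{k(x, x') = \sigma_p^2
#'     \exp(-d^2 / (2 l))} with \eqn{d = \lVert x - x' \rVert_2}; the
#'     lengthscale scales the squared distance.}
#'   \item{Matérn 5/2}{\eqn{k(x, x') = \sigma_p^2 (1 + \sqrt{5} d / l +
#'     5 d^2 / (3 l^2)) \exp(-\sqrt{5} d / l)} (standard form; the variance
#'     prefactor can be disabled).}
#' }
#' The nonlinear forms represent rugged landscapes where sequence effects
#' interact; they are bounded by \eqn{\sigma_p^2} and decay to zero with
#' distance.
#'
#' @param form One of `"linear"`, `"squared_exponential"` (alias `"se"`),
#'   `"matern52"`.
#' @param variance Prior variance \eqn{\sigma_p^2} (> 0).
#' @param lengthscale Lengthscale \eqn{l} (> 0; nonlinear forms only).
#' @param feature_subset Optional integer vector of feature columns the
#'   kernel is restricted to.
#' @param include_variance If `FALSE`, the Matérn form omits the
#'   \eqn{\sigma_p^2} prefactor.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(form = c("linear", "squared_exponential", "matern52", "se"),
                        variance = 1, lengthscale = NULL,
                        feature_subset = NULL, include_variance = TRUE) {
  form <- match.arg(form)
  if (form == "se") form <- "squared_exponential"
  check_scalar_number(variance, "variance", positive = TRUE)
  if (form != "linear") {
    lengthscale <- lengthscale %||% 1
    check_scalar_number(lengthscale, "lengthscale", positive = TRUE)
  } else {
    lengthscale <- NULL
  }
  structure(
    list(form = form, variance = variance, lengthscale = lengthscale,
         feature_subset = feature_subset, include_variance = include_variance),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s: variance = %.4g%s\n", x$form, x$variance,
              if (!is.null(x$lengthscale))
                sprintf(", lengthscale = %.4g", x$lengthscale) else ""))
  invisible(x)
}

n_hyper <- function(spec) if (spec$form == "linear") 1L else 2L

apply_subset <- function(spec, X) {
  if (is.null(spec$feature_subset)) X
  else X[, spec$feature_subset, drop = FALSE]
}

# Pairwise squared Euclidean distances between rows of X and Y.
# `extra_x`/`extra_y` are per-row counts of active features outside the
# shared column space (they inflate the squared norms but never the cross
# products).
sq_dists <- function(X, Y, extra_x = NULL, extra_y = NULL) {
  nx <- Matrix::rowSums(X^2) + (extra_x %||% 0)
  ny <- Matrix::rowSums(Y^2) + (extra_y %||% 0)
  D2 <- outer(as.numeric(nx), as.numeric(ny), "+") -
    2 * as.matrix(X %*% Matrix::t(Y))
  pmax(D2, 0)
}

kernel_from_parts <- function(spec, cross, D2) {
  switch(spec$form,
    linear = spec$variance * cross,
    squared_exponential = spec$variance * exp(-D2 / (2 * spec$lengthscale)),
    matern52 = {
      a <- sqrt(5 * D2) / spec$lengthscale
      pref <- if (spec$include_variance) spec$variance else 1
      pref * (1 + a + a^2 / 3) * exp(-a)
    }
  )
}

#' Evaluate a kernel between two feature vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,y Equal-length numeric (binary) vectors.
#' @return A single covariance value.
#' @export
kernel_value <- function(spec, x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "chimeraGP_error")
  }
  drop(kernel_matrix(spec, matrix(x, nrow = 1), matrix(y, nrow = 1)))
}

#' Kernel (cross-)covariance matrix
#'
#' Computes \eqn{K_{ij} = k(x_i, y_j)} for the rows of `X` and `Y`. With
#' `Y = NULL` the symmetric training covariance matrix is returned.
#'
#' @param spec A [kernel_spec()].
#' @param X,Y Feature matrices (base or sparse `Matrix`). Rows of `Y` may
#'   have more columns than `X` (extra trailing feature columns unseen in
#'   training); extra active features are also picked up from each matrix's
#'   `extra_active` attribute.
#' @return A dense numeric matrix.
#' @export
kernel_matrix <- function(spec, X, Y = NULL) {
  symmetric <- is.null(Y)
  if (symmetric) Y <- X
  extra_x <- attr(X, "extra_active")
  extra_y <- attr(Y, "extra_active")
  p <- ncol(X)
  if (ncol(Y) > p) {
    # trailing columns of Y are features unseen by X's column space
    extra_y <- (extra_y %||% 0) +
      as.numeric(Matrix::rowSums(Y[, -seq_len(p), drop = FALSE]^2))
    Y <- Y[, seq_len(p), drop = FALSE]
  } else if (ncol(Y) < p) {
    abort("`Y` has fewer feature columns than `X`.", class = "chimeraGP_error")
  }
  Xs <- apply_subset(spec, X)
  Ys <- apply_subset(spec, Y)
  cross <- as.matrix(Xs %*% Matrix::t(Ys))
  D2 <- if (spec$form == "linear") NULL
        else sq_dists(Xs, Ys, extra_x, extra_y)
  if (spec$form == "linear" && (!is.null(extra_x) || !is.null(extra_y)) &&
      symmetric) {
    # self-covariances include unseen active features
    cross <- cross + diag(as.numeric(extra_x %||% 0), nrow(cross))
  }
  K <- kernel_from_parts(spec, cross, D2)
  if (symmetric) K <- (K + t(K)) / 2
  K
}

#' Kernel self-variances k(x, x) for each row
#'
#' @inheritParams kernel_matrix
#' @export
kernel_diag <- function(spec, X) {
  extra <- attr(X, "extra_active") %||% 0
  Xs <- apply_subset(spec, X)
  switch(spec$form,
    linear = spec$variance * (as.numeric(Matrix::rowSums(Xs^2)) + extra),
    squared_exponential = rep(spec$variance, nrow(X)),
    matern52 = rep(if (spec$include_variance) spec$variance else 1, nrow(X))
  )
}

# Cholesky of K + jitter. Jitter is fixed at 1e-8 on the diagonal: binary
# encodings routinely yield duplicated rows, which make K numerically
# singular.
chol_jitter <- function(K, jitter = 1e-8) {
  n <- nrow(K)
  tryCatch(
    chol(K + diag(jitter, n)),
    error = function(e) {
      tryCatch(
        chol(K + diag(jitter * 1e4 + 1e-10 * mean(diag(K)), n)),
        error = function(e2) {
          abort("Covariance matrix is singular even after adding jitter.",
                class = "chimeraGP_numeric_error")
        }
      )
    }
  )
}
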