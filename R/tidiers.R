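#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' @export
tidy.gp_regression <- function(x, ...) {
  tibble(
    term = c("sigma_p2",
             if (!is.null(x$spec$lengthscale)) "lengthscale",
             "sigma_n2"),
    estimate = c(x$spec$variance,
                 if (!is.null(x$spec$lengthscale)) x$spec$lengthscale,
                 x$sigma_n2)
  )
}

#' @export
glance.gp_regression <- function(x, ...) {
  tibble(kernel = x$spec$form, n = x$n,
         log_marginal_likelihood = x$lml,
         sigma_n2 = x$sigma_n2)
}

#' @export
augment.gp_regression <- function(x, newdata = NULL, ...) {
  X <- newdata %||% x$X
  dplyr::bind_cols(
    tibble(.row = seq_len(nrow(X))),
    predict(x, X)
  )
}

#' @export
tidy.gp_classifier <- function(x, ...) {
  tibble(
    term = c("sigma_p2", if (!is.null(x$spec$lengthscale)) "lengthscale"),
    estimate = c(x$spec$variance,
                 if (!is.null(x$spec$lengthscale)) x$spec$lengthscale)
  )
}

#' @export
glance.gp_classifier <- function(x, ...) {
  tibble(kernel = x$spec$form, link = x$link, n = x$n,
         n_high = sum(x$y == 1), n_low = sum(x$y == -1),
         laplace_lml = x$lml)
}

#' @export
tidy.bayes_ridge <- function(x, ...) {
  tibble(term = paste0("x", seq_along(x$coefficients)),
         estimate = x$coefficients)
}

#' @export
glance.bayes_ridge <- function(x, ...) {
  tibble(alpha = x$alpha, lambda = x$lambda,
         n_iter = x$n_iter, converged = x$converged)
}

#' @export
tidy.weight_report <- function(x, ...) {
  dplyr::select(x$weights, "group", "weight", "representative", "n_members")
}

#' @export
tidy.gp_loo <- function(x, ...) x$predictions

#' @export
glance.gp_loo <- function(x, ...) {
  tibble(n = nrow(x$predictions),
         r_pearson = x$r_pearson, r_spearman = x$r_spearman,
         kernel = x$model$spec$form)
}

#' @export
tidy.learning_curve <- function(x, ...) x$summary
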