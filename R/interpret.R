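#' L1 feature selection with leave-one-out regularization choice
#'
#' Fits a lasso path over 100 log-spaced regularization values between
#' \eqn{\lambda_{max}} (the smallest \eqn{\lambda} giving the empty model)
#' and \eqn{\lambda_{max} \cdot 10^{-4}}, chooses the \eqn{\lambda}
#' minimizing leave-one-out squared error, and returns the columns with
#' non-zero coefficients at that \eqn{\lambda}. Intended to be run on the
#' covarying-collapsed feature matrix (see [collapse_covarying()]).
#'
#' @param X Numeric feature matrix (rows = observations; typically the
#'   `reduced` matrix of [collapse_covarying()]).
#' @param y Responses on the modeling (log2) scale.
#' @param nlambda Number of path values (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest \eqn{\lambda}
#'   (default 1e-4).
#' @return An object of class `l1_selection`: list with `selected` (integer
#'   column indices), `lambda` (chosen value), `coefficients` (at the chosen
#'   \eqn{\lambda}), and `cv` (tibble of \eqn{\lambda} vs LOO mean squared
#'   error).
#' @export
l1_select <- function(X, y, nlambda = 100, lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) abort("L1 selection needs n >= 3.", class = "chimeraGP_error")
  padded <- FALSE
  if (ncol(X) < 2) {  # glmnet needs >= 2 columns; pad with an inert zero
    X <- cbind(X, 0)
    padded <- TRUE
  }
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(xc, yc))) / n
  if (lmax <= 0) lmax <- 1e-3
  path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  cv <- glmnet::cv.glmnet(X, y, lambda = path, alpha = 1,
                          standardize = FALSE, intercept = TRUE,
                          foldid = seq_len(n), grouped = FALSE,
                          type.measure = "mse")
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  if (padded) beta <- beta[-length(beta)]
  selected <- which(beta != 0)
  if (!length(selected)) {
    warn("L1 selection returned an empty model at the optimal regularization.")
  }
  structure(
    list(selected = selected, lambda = cv$lambda.min,
         coefficients = beta,
         cv = tibble(lambda = cv$lambda, loo_mse = cv$cvm),
         fit = cv),
    class = "l1_selection"
  )
}

#' @export
print.l1_selection <- function(x, ...) {
  cat(sprintf("<l1_selection> %d features selected at lambda = %.4g\n",
              length(x$selected), x$lambda))
  invisible(x)
}

#' Evidence-maximizing Bayesian ridge regression
#'
#' Linear regression with a zero-mean Gaussian prior on the weights, where
#' the weight precision `lambda` and noise precision `alpha` are updated by
#' the standard evidence (type-II maximum likelihood) iterations under
#' Gamma(1e-6, 1e-6) hyperpriors. Data are centred (an intercept is fitted).
#'
#' @param X Feature matrix of the selected columns.
#' @param y Responses.
#' @param max_iter Maximum evidence iterations (default 300).
#' @param tol Convergence tolerance on the weight change (default 1e-3).
#' @param prior Shape/rate of the Gamma hyperpriors (default `1e-6`).
#' @return An object of class `bayes_ridge` with `coefficients`,
#'   `intercept`, `alpha` (noise precision), `lambda` (weight precision),
#'   `n_iter`, `converged`.
#' @export
bayesian_ridge <- function(X, y, max_iter = 300, tol = 1e-3, prior = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 1) abort("Need at least one column.", class = "chimeraGP_error")
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  sv <- svd(Xc)
  s2 <- sv$d^2
  Uty <- crossprod(sv$u, yc)
  alpha <- 1 / max(stats::var(yc), 1e-10)  # noise precision
  lambda <- 1                              # weight precision
  w <- rep(0, p)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    # posterior mean in the SVD basis
    d_post <- sv$d * drop(Uty) / (s2 + lambda / alpha)
    w_new <- drop(sv$v %*% d_post)
    gamma <- sum(s2 / (s2 + lambda / alpha))
    rss <- sum((yc - Xc %*% w_new)^2)
    lambda <- (gamma + 2 * prior) / (sum(w_new^2) + 2 * prior)
    alpha <- (n - gamma + 2 * prior) / (rss + 2 * prior)
    if (sum(abs(w_new - w)) < tol) {
      w <- w_new; converged <- TRUE; break
    }
    w <- w_new
  }
  if (!converged) {
    warn(sprintf("Bayesian ridge did not converge in %d iterations.", max_iter))
  }
  structure(
    list(coefficients = w,
         intercept = y_mean - sum(x_mean * w),
         alpha = alpha, lambda = lambda,
         n_iter = it, converged = converged),
    class = "bayes_ridge"
  )
}

#' @export
print.bayes_ridge <- function(x, ...) {
  cat(sprintf(
    "<bayes_ridge> %d weights; noise precision %.4g, weight precision %.4g (%d iterations)\n",
    length(x$coefficients), x$alpha, x$lambda, x$n_iter))
  invisible(x)
}

#' @export
predict.bayes_ridge <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

#' Feature-weight interpretation pipeline
#'
#' The full interpretation pipeline for one measured property: collapse
#' covarying feature columns into groups, select predictive groups by
#' L1-regularized regression (regularization chosen by LOO), then re-weight
#' the selected groups by evidence-maximizing Bayesian ridge regression.
#' The same pipeline serves any property (localization, expression,
#' efficiency) — only the response column changes.
#'
#' @param X Binary feature matrix over the training variants (uncollapsed;
#'   e.g. from [encode_sequences()]).
#' @param y Responses on the modeling (log2) scale.
#' @param ... Passed to [l1_select()].
#' @return An object of class `weight_report`: list with `weights` (tibble:
#'   `group`, `weight`, `representative`, `n_members`, `members` list
#'   column), plus the `groups` tibble, the `l1` and `ridge` fits.
#' @export
feature_weights <- function(X, y, ...) {
  cc <- collapse_covarying(X)
  # columns of `reduced` are indexed by group id; drop constant groups
  group_ids <- sort(unique(cc$groups$group))
  keep <- group_ids[vapply(group_ids, function(g) {
    is.na(cc$groups$constant[match(g, cc$groups$group)])
  }, logical(1))]
  Xr <- cc$reduced[, keep, drop = FALSE]
  sel <- l1_select(Xr, y, ...)
  if (!length(sel$selected)) {
    weights <- tibble(group = integer(0), weight = numeric(0),
                      representative = integer(0), n_members = integer(0),
                      members = list())
    return(structure(list(weights = weights, groups = cc$groups,
                          l1 = sel, ridge = NULL),
                     class = "weight_report"))
  }
  sel_groups <- keep[sel$selected]
  ridge <- bayesian_ridge(Xr[, sel$selected, drop = FALSE], y)
  members <- lapply(sel_groups, function(g) cc$groups$column[cc$groups$group == g])
  weights <- tibble(
    group = sel_groups,
    weight = ridge$coefficients,
    representative = cc$groups$representative[match(sel_groups, cc$groups$group)],
    n_members = lengths(members),
    members = members
  )
  structure(
    list(weights = weights, groups = cc$groups, l1 = sel, ridge = ridge),
    class = "weight_report"
  )
}

#' @export
print.weight_report <- function(x, ...) {
  cat(sprintf("<weight_report> %d selected feature groups (of %d)\n",
              nrow(x$weights), max(x$groups$group)))
  invisible(x)
}

pick_priority <- function(carriers, priority) {
  ps <- strsplit(carriers, ",", fixed = TRUE)[[1]]
  hit <- priority[priority %in% ps]
  if (length(hit)) hit[1] else NA_character_
}

#' Map feature-group weights back to residues and contacts
#'
#' Expands every selected group into its member features and annotates each
#' with its alignment position(s), residue(s), and parent of origin. When a
#' feature is carried by several parents the annotation uses the first
#' carrier in `priority` order. The group weight is attributed equally to
#' all members, marked `shared` for groups with more than one member. The
#' output is suitable for export to structure-viewer attribute scripts.
#'
#' @param report A [feature_weights()] result.
#' @param encoding The [build_encoding()] the feature matrix came from.
#' @param priority Parent names in decreasing annotation priority (default:
#'   the parent-set order).
#' @return Tibble with `type`, `pos_i`, `pos_j`, `aa_i`, `aa_j`, `parent`,
#'   `parent_i`, `parent_j`, `weight`, `rank`, `group`, `shared`.
#' @export
map_weights <- function(report, encoding, priority = NULL) {
  priority <- priority %||% encoding$parents$names
  if (!nrow(report$weights)) {
    return(tibble(type = character(0), pos_i = integer(0), pos_j = integer(0),
                  aa_i = character(0), aa_j = character(0),
                  parent = character(0), parent_i = character(0),
                  parent_j = character(0), weight = numeric(0),
                  rank = integer(0), group = integer(0), shared = logical(0)))
  }
  rows <- purrr::map_dfr(seq_len(nrow(report$weights)), function(r) {
    cols <- report$weights$members[[r]]
    feat <- encoding$index[cols, ]
    if (nrow(feat) < length(cols)) {
      abort("Weight report refers to feature columns outside the encoding.",
            class = "chimeraGP_error")
    }
    feat |>
      dplyr::mutate(
        weight = report$weights$weight[r],
        group = report$weights$group[r],
        shared = report$weights$n_members[r] > 1L
      )
  })
  ann <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    carriers <- rows$parents[i]
    if (rows$type[i] == "contact") {
      ends <- strsplit(carriers, "|", fixed = TRUE)[[1]]
      if (length(ends) < 2) ends <- c(ends, "")
      pi_ <- pick_priority(ends[1], priority)
      pj_ <- pick_priority(ends[2], priority)
      both <- intersect(strsplit(ends[1], ",")[[1]], strsplit(ends[2], ",")[[1]])
      parent <- if (length(both)) pick_priority(paste(both, collapse = ","), priority)
                else paste(pi_, pj_, sep = "/")
      tibble(parent = parent, parent_i = pi_, parent_j = pj_)
    } else {
      p <- pick_priority(carriers, priority)
      tibble(parent = p, parent_i = p, parent_j = NA_character_)
    }
  })
  out <- dplyr::bind_cols(
    rows[, c("type", "pos_i", "pos_j", "aa_i", "aa_j")], ann,
    rows[, c("weight", "group", "shared")]
  )
  out$rank <- dplyr::dense_rank(dplyr::desc(abs(out$weight)))
  dplyr::arrange(out, .data$rank, .data$pos_i)
}
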