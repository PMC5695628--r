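# Small fixture builders and independent oracles shared across tests.
# Oracles are deliberately naive (dense inverses, grids, brute force) and
# never call the code paths they are checking.

toy_parents2 <- function() parent_set(c(A = "AAAA", B = "CCCC"))

toy_system <- function(length = 40, n_blocks = 4, seed = 1,
                       contacts_per_residue = 2) {
  parents <- generate_parents(3, length, 0.5, seed = seed)
  designs <- list(
    generate_block_design(length, n_blocks, "c"),
    generate_block_design(length, n_blocks, "n", contiguous = FALSE,
                          seed = seed + 1)
  )
  contacts <- generate_contacts(length, contacts_per_residue, seed = seed + 2)
  list(parents = parents, designs = designs, contacts = contacts,
       encoding = build_encoding(parents, contacts))
}

# dense-inverse GP regression oracle (no Cholesky reuse, explicit solve);
# includes the model's fixed 1e-8 diagonal jitter
gp_oracle <- function(K, kstar, kss, y, sigma_n2) {
  C <- K + diag(sigma_n2 + 1e-8, nrow(K))
  Ci <- solve(C)
  list(mean = drop(t(kstar) %*% Ci %*% y),
       var = kss - drop(t(kstar) %*% Ci %*% kstar),
       lml = drop(-0.5 * t(y) %*% Ci %*% y) -
         0.5 * determinant(C, logarithm = TRUE)$modulus[1] -
         length(y) / 2 * log(2 * pi))
}

# Gaussian expectation of the logistic sigmoid by fine Riemann sum
# (independent of the package's Gauss-Hermite path)
sigmoid_gauss_riemann <- function(mu, v, z = seq(-8, 8, by = 0.005)) {
  w <- stats::dnorm(z) * 0.005
  vapply(seq_along(mu), function(i) {
    sum(w * stats::plogis(mu[i] + sqrt(max(v[i], 0)) * z))
  }, numeric(1))
}

# exact predictive class probability for n <= 2 training points by grid
# integration over the latent posterior
exact_class_prob <- function(X, y, xstar, spec, grid_sd = 8, n_grid = 161) {
  Xall <- rbind(X, matrix(xstar, nrow = 1))
  Kall <- kernel_matrix(spec, Xall)
  n <- nrow(X)
  K <- Kall[1:n, 1:n, drop = FALSE] + diag(1e-10, n)
  ks <- Kall[1:n, n + 1, drop = FALSE]
  kss <- Kall[n + 1, n + 1]
  Ki <- solve(K)
  cond_var <- max(kss - drop(t(ks) %*% Ki %*% ks), 0)
  if (n == 1) {
    f1 <- seq(-grid_sd, grid_sd, length.out = 4001) * sqrt(K[1, 1])
    prior <- stats::dnorm(f1, 0, sqrt(K[1, 1]))
    lik <- stats::plogis(y[1] * f1)
    mu_star <- drop(ks) / K[1, 1] * f1
    inner <- sigmoid_gauss_riemann(mu_star, rep(cond_var, length(f1)))
    sum(prior * lik * inner) / sum(prior * lik)
  } else {
    s1 <- sqrt(K[1, 1]); s2 <- sqrt(K[2, 2])
    g <- seq(-grid_sd, grid_sd, length.out = n_grid)
    f1 <- rep(g * s1, times = n_grid)
    f2 <- rep(g * s2, each = n_grid)
    Fm <- cbind(f1, f2)
    q <- rowSums((Fm %*% Ki) * Fm)
    prior <- exp(-0.5 * q)
    lik <- stats::plogis(y[1] * f1) * stats::plogis(y[2] * f2)
    mu_star <- drop(Fm %*% Ki %*% ks)
    inner <- sigmoid_gauss_riemann(mu_star, rep(cond_var, length(mu_star)))
    sum(prior * lik * inner) / sum(prior * lik)
  }
}

# long-run importance-sampled posterior predictive probability for n <= 8
mc_class_prob <- function(X, y, xstar, spec, n_samp = 2e5, seed = 42) {
  Xall <- rbind(X, matrix(xstar, nrow = 1))
  Kall <- kernel_matrix(spec, Xall)
  n <- nrow(X)
  K <- Kall[1:n, 1:n, drop = FALSE] + diag(1e-9, n)
  ks <- Kall[1:n, n + 1, drop = FALSE]
  kss <- Kall[n + 1, n + 1]
  Ki <- solve(K)
  cv <- max(kss - drop(t(ks) %*% Ki %*% ks), 0)
  set.seed(seed)
  Z <- matrix(rnorm(n_samp * n), n_samp, n) %*% chol(K)
  logw <- rowSums(stats::plogis(sweep(Z, 2, y, "*"), log.p = TRUE))
  w <- exp(logw - max(logw))
  mu <- drop(Z %*% Ki %*% ks)
  fstar <- mu + sqrt(cv) * rnorm(n_samp)
  sum(w * stats::plogis(fstar)) / sum(w)
}
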