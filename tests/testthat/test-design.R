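test_that("acquisition arithmetic and guards", {
  expect_equal(acquisition(5, 1, "lcb"), 4)
  expect_equal(acquisition(5, 1, "ucb", kappa = 2), 7)
  expect_equal(acquisition(5, 0, "lcb"), acquisition(5, 0, "ucb"))
  expect_equal(acquisition(c(1, 2), c(0.5, 1), "mean"), c(1, 2))
  expect_error(acquisition(1, -0.1, "lcb"), class = "chimeraGP_error")
  # lcb <= mean <= ucb pointwise, equality iff sd = 0
  set.seed(40)
  mu <- rnorm(20); sd <- c(0, runif(19))
  expect_true(all(acquisition(mu, sd, "lcb") <= mu))
  expect_true(all(mu <= acquisition(mu, sd, "ucb")))
  eq <- acquisition(mu, sd, "lcb") == acquisition(mu, sd, "ucb")
  expect_equal(eq, sd == 0)
})

test_that("library ranking matches per-item scoring and is deterministic", {
  sys <- toy_system(length = 24, n_blocks = 3)
  sl <- simulate_landscape(sys$parents, sys$designs, sys$contacts,
                           landscape_spec(seed = 6), n_multi = 20)
  y <- log2_response(sl$measurements$GFP_mean)
  m <- fit_gp_regression(as.matrix(sl$X), y, kernel = "linear", n_restarts = 3)
  rk <- rank_library(m, sys$parents, sys$designs, sys$encoding,
                     mode = "lcb", chunk_size = 13)
  expect_equal(nrow(rk), n_chimeras(sys$parents, sys$designs))
  # brute force: predict every chimera individually
  chim <- enumerate_chimeras(sys$parents, sys$designs, sequences = TRUE)
  X <- encode_sequences(chim$sequence, sys$encoding)
  pr <- predict(m, X)
  acq <- pr$.pred - pr$.pred_sd
  muts <- mutation_count(chim$sequence, sys$parents)
  # per-id agreement with the brute-force scores
  at <- match(chim$id, rk$id)
  expect_equal(rk$acquisition[at], acq, tolerance = 1e-8)
  expect_equal(rk$n_mutations[at], muts)
  # ranking is sorted by acquisition (up to float ties)
  expect_true(all(diff(rk$acquisition) <= 1e-9))
  # ids agree with the oracle sort wherever scores are not tied
  ord <- order(-acq, muts, chim$id, method = "radix")
  clear <- which(abs(rk$acquisition - acq[ord]) < 1e-9 &
                   c(Inf, -diff(acq[ord])) > 1e-9 &
                   c(-diff(acq[ord]), Inf) > 1e-9)
  expect_equal(rk$id[clear], chim$id[ord][clear])
  # chunk size must not matter
  rk2 <- rank_library(m, sys$parents, sys$designs, sys$encoding,
                      mode = "lcb", chunk_size = 100)
  expect_equal(rk$acquisition, rk2$acquisition, tolerance = 1e-10)
  expect_setequal(rk$id, rk2$id)
  # top-fraction keeps floor(fraction * size)
  rk3 <- rank_library(m, sys$parents, sys$designs, sys$encoding,
                      top_fraction = 0.1)
  expect_equal(nrow(rk3), floor(0.1 * nrow(chim)))
  expect_equal(rk3$id, rk$id[seq_len(nrow(rk3))])
})

test_that("greedy mutual-information selection is exhaustively optimal for sizes 1-2", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- 10 + (seed %% 3)  # pools of 10-12 candidates
    X <- matrix(rbinom(m * 8, 1, 0.5), m)
    spec <- kernel_spec("squared_exponential", variance = 1, lengthscale = 3)
    K <- kernel_matrix(spec, X)
    sel1 <- select_training_set(X, spec, n_select = 1)
    mis1 <- vapply(seq_len(m), function(i) subset_mutual_information(K, i),
                   numeric(1))
    expect_equal(subset_mutual_information(K, sel1$index), max(mis1),
                 tolerance = 1e-6)
    sel2 <- select_training_set(X, spec, n_select = 2)
    combs <- utils::combn(m, 2)
    mis2 <- apply(combs, 2, function(s) subset_mutual_information(K, s))
    expect_equal(subset_mutual_information(K, sel2$index), max(mis2),
                 tolerance = 1e-6)
  }
})

test_that("duplicates are informationless and never picked over distinct candidates", {
  set.seed(50)
  X <- matrix(rbinom(8 * 6, 1, 0.5), 8)
  X <- X[!duplicated(X), , drop = FALSE]
  X <- rbind(X, X[1, ])  # a duplicate of row 1
  dup_row <- nrow(X)
  spec <- kernel_spec("squared_exponential", variance = 1, lengthscale = 2)
  sel <- select_training_set(X, spec, n_select = nrow(X) - 2,
                             mandatory = 1L)
  expect_false(dup_row %in% sel$index)
})

test_that("MI-selected sets are more spread than random sets", {
  set.seed(51)
  sys <- toy_system(length = 24, n_blocks = 3)
  chim <- enumerate_chimeras(sys$parents, sys$designs, sequences = TRUE)
  X <- encode_sequences(chim$sequence, sys$encoding)
  spec <- kernel_spec("linear", variance = 1)
  sel <- select_training_set(X, spec, n_select = 5)
  seq_dist <- function(idx) {
    s <- chim$sequence[idx]
    d <- utils::combn(length(s), 2, function(ij) {
      sum(strsplit(s[ij[1]], "")[[1]] != strsplit(s[ij[2]], "")[[1]])
    })
    mean(d)
  }
  d_sel <- seq_dist(sel$index)
  wins <- sum(vapply(1:100, function(k) {
    d_sel >= seq_dist(sample(nrow(chim), 5))
  }, logical(1)))
  expect_gte(wins, 95)
})

test_that("block-swap proposals match brute-force scoring of all swaps", {
  sys <- toy_system(length = 24, n_blocks = 3)
  sl <- simulate_landscape(sys$parents, sys$designs, sys$contacts,
                           landscape_spec(seed = 7), n_multi = 20)
  y <- log2_response(sl$measurements$GFP_mean)
  m <- fit_gp_regression(as.matrix(sl$X), y, kernel = "linear", n_restarts = 3)
  # homolog: mutate a few positions of parent 2
  hom <- strsplit(unname(sys$parents$seqs[2]), "")[[1]]
  hom[c(3, 11, 19)] <- c("W", "W", "W")
  hom <- paste(hom, collapse = "")
  enc <- build_encoding(sys$parents, sys$contacts, extra_sequences = hom)
  props <- propose_block_improvements(hom, sys$parents, sys$designs[[1]], m,
                                      enc, mode = "ucb", n_proposals = 100)
  swaps <- single_block_swaps(hom, sys$parents, sys$designs[[1]])
  expect_equal(nrow(props), nrow(swaps))
  expect_true(all(props$n_changed > 0))
  pr <- predict(m, encode_sequences(swaps$sequence, enc))
  expect_equal(sort(props$acquisition, decreasing = TRUE),
               sort(pr$.pred + pr$.pred_sd, decreasing = TRUE),
               tolerance = 1e-8)
  expect_equal(props$acquisition, sort(props$acquisition, decreasing = TRUE))
  # homolog identical to a parent reduces to that parent's swap scan
  p1 <- unname(sys$parents$seqs[1])
  props_p1 <- propose_block_improvements(p1, sys$parents, sys$designs[[1]], m,
                                         sys$encoding, n_proposals = 100)
  swaps_p1 <- single_block_swaps(p1, sys$parents, sys$designs[[1]])
  expect_setequal(props_p1$sequence, swaps_p1$sequence)
})

test_that("exploration sets respect the probability and diversity filters", {
  sys <- toy_system(length = 24, n_blocks = 3)
  sl <- simulate_landscape(sys$parents, sys$designs, sys$contacts,
                           landscape_spec(seed = 8), n_multi = 20)
  y <- log2_response(sl$measurements$GFP_mean)
  lab <- ifelse(y > stats::median(y), 1, -1)
  m <- fit_gp_classifier(as.matrix(sl$X), lab, kernel = "linear",
                         n_restarts = 3)
  scan <- classify_library(m, sys$parents, sys$designs, sys$encoding)
  ex <- exploration_set(scan, sys$parents, sys$designs, n_select = 5,
                        prob_min = 0.4, min_mutations = 2)
  expect_lte(nrow(ex), 5)
  expect_true(all(ex$.prob > 0.4))
  expect_true(all(ex$n_mutations >= 2))
})
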