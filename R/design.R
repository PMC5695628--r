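#' Acquisition values from predicted mean and standard deviation
#'
#' Lower confidence bound (`lcb`, mean − κ·sd) for conservative optimal
#' design, upper confidence bound (`ucb`, mean + κ·sd) for
#' exploration-biased design, or the plain predicted mean. The default
#' κ = 1 gives "mean minus/plus one standard deviation".
#'
#' @param mean Predicted means.
#' @param sd Predicted standard deviations (≥ 0).
#' @param mode One of `"lcb"`, `"ucb"`, `"mean"`.
#' @param kappa Confidence multiplier κ (default 1).
#' @return Numeric acquisition values.
#' @export
acquisition <- function(mean, sd, mode = c("lcb", "ucb", "mean"), kappa = 1) {
  mode <- match.arg(mode)
  if (any(sd < 0)) abort("`sd` must be nonnegative.", class = "chimeraGP_error")
  switch(mode,
         lcb = mean - kappa * sd,
         ucb = mean + kappa * sd,
         mean = mean)
}

# deterministic acquisition ordering: value desc, then fewer mutations,
# then lexicographic id
rank_order <- function(value, n_mutations, id) {
  order(-value, n_mutations, id, method = "radix")
}

#' Rank a recombination library by an acquisition rule
#'
#' Streams over every chimera of the designs in chunks, predicts mean and
#' standard deviation with a GP regression model, computes the acquisition
#' value, and returns the top fraction of the library ranked by it. Ties are
#' broken by fewer mutations from the nearest parent, then lexicographic id,
#' so rankings are deterministic and independent of scan order.
#'
#' @param model A fitted `gp_regression` model.
#' @param parents,designs Library definition.
#' @param encoding The [build_encoding()] used in training.
#' @param mode,kappa See [acquisition()].
#' @param top_fraction Fraction of the library to retain (default 1 = all);
#'   the number kept is `floor(top_fraction * library size)`.
#' @param chunk_size Chimeras per scan chunk.
#' @return A tibble `id`, `.pred`, `.pred_sd`, `acquisition`, `n_mutations`,
#'   `rank`, sorted by rank.
#' @export
rank_library <- function(model, parents, designs, encoding,
                         mode = "lcb", kappa = 1, top_fraction = 1,
                         chunk_size = 5000) {
  designs <- as_design_list(designs)
  scan <- scan_designs(parents, designs, encoding, chunk_size, function(X) {
    predict(model, X)[, c(".pred", ".pred_sd")]
  })
  preds <- scan$value
  ids <- scan$id
  # mutation counts from assignments (cheap: recompute per design)
  muts <- integer(0)
  for (d in designs) {
    n <- parents$n_parents^d$n_blocks
    A <- assignment_chunk(seq_len(n) - 1, d$n_blocks, parents$n_parents)
    # Hamming distance to nearest parent = number of positions whose
    # assigned parent's residue differs from that parent's; computed from
    # block assignments and parent-difference counts per (block, p, q).
    diffs <- array(0L, dim = c(d$n_blocks, parents$n_parents, parents$n_parents))
    for (b in seq_len(d$n_blocks)) {
      pos <- which(d$block == b)
      for (p in seq_len(parents$n_parents)) {
        for (q in seq_len(parents$n_parents)) {
          a <- parents$chars[p, pos]; bb <- parents$chars[q, pos]
          diffs[b, p, q] <- sum(a != bb & !(is_gap(a) & is_gap(bb)))
        }
      }
    }
    m <- matrix(0L, nrow = n, ncol = parents$n_parents)
    for (q in seq_len(parents$n_parents)) {
      for (b in seq_len(d$n_blocks)) {
        m[, q] <- m[, q] + diffs[b, A[, b], q]
      }
    }
    muts <- c(muts, apply(m, 1, min))
  }
  acq <- acquisition(preds$.pred, preds$.pred_sd, mode = mode, kappa = kappa)
  ord <- rank_order(acq, muts, ids)
  n_keep <- if (top_fraction >= 1) length(ids)
            else max(floor(top_fraction * length(ids)), 1L)
  keep <- ord[seq_len(n_keep)]
  tibble(
    id = ids[keep],
    .pred = preds$.pred[keep],
    .pred_sd = preds$.pred_sd[keep],
    acquisition = acq[keep],
    n_mutations = muts[keep],
    rank = seq_len(n_keep)
  )
}

# conditional prior variance of candidate rows given an index set, from the
# kernel matrix K (with jitter for stability)
cond_var <- function(K, targets, given, jitter = 1e-9) {
  if (!length(given)) return(diag(K)[targets])
  Kss <- K[given, given, drop = FALSE]
  U <- chol_jitter(Kss, jitter = jitter)
  Kts <- K[targets, given, drop = FALSE]
  v <- backsolve(U, t(Kts), transpose = TRUE)
  pmax(diag(K)[targets] - colSums(v^2), jitter)
}

#' Greedy mutual-information training-set selection
#'
#' Selects chimeras that are maximally informative about the remainder of
#' the candidate pool under the GP prior: starting from a mandatory set
#' (e.g. all single-block swaps), each step adds the candidate `y`
#' maximizing the mutual-information gain
#' \eqn{\tfrac12 \log( \sigma^2_{y|A} / \sigma^2_{y|\bar A} )}, where `A` is
#' the current selection and \eqn{\bar A} the unselected remainder — i.e.
#' the candidate whose measurement most reduces the Shannon entropy of
#' predictions for the rest of the library. The selection is deterministic
#' given its inputs.
#'
#' @param X Feature matrix of the candidate pool (one row per candidate).
#' @param spec A [kernel_spec()] defining the GP prior.
#' @param n_select Number of candidates to add.
#' @param mandatory Integer indices of rows that are already selected.
#' @param pool_max If the pool is larger, a seeded down-sample of this size
#'   is used for tractability (mandatory rows always kept).
#' @param seed Seed for the down-sample.
#' @return Tibble `step`, `index`, `gain` of newly selected rows.
#' @export
select_training_set <- function(X, spec, n_select, mandatory = integer(0),
                                pool_max = 2000, seed = 0) {
  n <- nrow(X)
  if (n_select < 1) abort("`n_select` must be >= 1.", class = "chimeraGP_error")
  if (n_select > n - length(mandatory)) {
    abort("`n_select` exceeds the number of available candidates.",
          class = "chimeraGP_error")
  }
  rows <- seq_len(n)
  if (n > pool_max) {
    extra <- with_seed(seed, sample(setdiff(rows, mandatory),
                                    pool_max - length(mandatory)))
    rows <- sort(c(mandatory, extra))
  }
  K <- kernel_matrix(spec, X[rows, , drop = FALSE])
  local_idx <- seq_along(rows)
  A <- match(mandatory, rows)
  picked <- integer(0); gains <- numeric(0)
  for (step in seq_len(n_select)) {
    cand <- setdiff(local_idx, c(A, picked))
    sel <- c(A, picked)
    num <- cond_var(K, cand, sel)
    gain <- vapply(seq_along(cand), function(ci) {
      y <- cand[ci]
      rest <- setdiff(cand, y)
      den <- if (length(rest)) cond_var(K, y, rest) else diag(K)[y]
      0.5 * log(num[ci] / den)
    }, numeric(1))
    best <- cand[which.max(gain)]
    picked <- c(picked, best)
    gains <- c(gains, max(gain))
  }
  tibble(step = seq_len(n_select), index = rows[picked], gain = gains)
}

#' Exact mutual information of a candidate subset
#'
#' \eqn{I(A; V \setminus A) = H(A) + H(V \setminus A) - H(V)} under the GP
#' prior, from log-determinants of kernel submatrices. Used as the
#' exhaustive reference for small pools.
#'
#' @param K Kernel matrix over the pool.
#' @param subset Integer indices of the subset A.
#' @export
subset_mutual_information <- function(K, subset) {
  ld <- function(idx) {
    if (!length(idx)) return(0)
    2 * sum(log(diag(chol_jitter(K[idx, idx, drop = FALSE], jitter = 1e-9))))
  }
  rest <- setdiff(seq_len(nrow(K)), subset)
  0.5 * (ld(subset) + ld(rest) - ld(seq_len(nrow(K))))
}

#' Propose single-block improvements of an external homolog
#'
#' Scores every single-block swap from the library parents into a
#' background sequence (typically a homolog from outside the recombination
#' library) with a GP regression model and returns the top proposals by an
#' acquisition rule (UCB by default, balancing predicted improvement and
#' informative uncertainty). Swaps that change no position are excluded.
#'
#' @param background Aligned background sequence.
#' @param parents Donor [parent_set()].
#' @param design A [block_design()].
#' @param model Fitted `gp_regression` model.
#' @param encoding The model's [build_encoding()] (build it with
#'   `extra_sequences = background` so homolog residues are representable).
#' @param mode,kappa See [acquisition()]; default `"ucb"`.
#' @param n_proposals Number of proposals to return (default 4).
#' @return Tibble `block`, `donor_name`, `sequence`, `.pred`, `.pred_sd`,
#'   `acquisition`, `n_changed`, `n_mutations` (from nearest parent),
#'   `rank`.
#' @export
propose_block_improvements <- function(background, parents, design, model,
                                       encoding, mode = "ucb", kappa = 1,
                                       n_proposals = 4) {
  swaps <- single_block_swaps(background, parents, design)
  if (!nrow(swaps)) {
    abort("No non-trivial single-block swaps exist for this background.",
          class = "chimeraGP_error")
  }
  X <- encode_sequences(swaps$sequence, encoding)
  pr <- predict(model, X)
  swaps$.pred <- pr$.pred
  swaps$.pred_sd <- pr$.pred_sd
  swaps$acquisition <- acquisition(pr$.pred, pr$.pred_sd, mode = mode,
                                   kappa = kappa)
  swaps$n_mutations <- mutation_count(swaps$sequence, parents)
  ord <- rank_order(swaps$acquisition, swaps$n_changed,
                    paste(swaps$block, swaps$donor))
  out <- swaps[ord[seq_len(min(n_proposals, nrow(swaps)))], ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Select a diverse exploration set above a probability threshold
#'
#' Implements the exploration-set rule: from a classifier scan of the
#' library, keep chimeras with predicted probability of the 'high' class
#' above `prob_min` (default 0.4), optionally enforce a minimum number of
#' mutations (to target diverse multi-block swaps) and a minimum pairwise
#' mutation distance among the selected set, then return `n_select` of them
#' ranked by probability.
#'
#' @param scan Tibble from [classify_library()] (columns `id`, `.prob`).
#' @param parents,designs Library definition (used to reconstruct sequences
#'   for the distance filters).
#' @param n_select Number of chimeras to select.
#' @param prob_min Probability threshold for candidacy (default 0.4).
#' @param min_mutations Minimum mutations from the nearest parent
#'   (default 0 = off).
#' @param min_pairwise Minimum pairwise mutation distance among selections
#'   (default 0 = off).
#' @return Tibble of selected chimeras with `id`, `.prob`, `n_mutations`.
#' @export
exploration_set <- function(scan, parents, designs, n_select,
                            prob_min = 0.4, min_mutations = 0,
                            min_pairwise = 0) {
  designs <- as_design_list(designs)
  cand <- scan[scan$.prob > prob_min, ]
  if (!nrow(cand)) return(tibble(id = character(0), .prob = numeric(0),
                                 n_mutations = integer(0)))
  parsed <- lapply(cand$id, parse_chimera_id, parents = parents,
                   designs = designs)
  seqs <- map_chr(parsed, "sequence")
  cand$n_mutations <- mutation_count(seqs, parents)
  cand <- cand[cand$n_mutations >= min_mutations, ]
  seqs <- seqs[match(cand$id, map_chr(parsed, "id"))]
  ord <- order(-cand$.prob, cand$id)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= n_select) break
    if (min_pairwise > 0 && length(chosen)) {
      d <- vapply(chosen, function(j) {
        sum(seq_chars(seqs[i]) != seq_chars(seqs[j]))
      }, numeric(1))
      if (any(d < min_pairwise)) next
    }
    chosen <- c(chosen, i)
  }
  cand[chosen, c("id", ".prob", "n_mutations")]
}
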