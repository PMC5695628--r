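AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate synthetic aligned parents at a target identity
#'
#' Parents share a conserved residue at a position with probability chosen
#' so that the expected pairwise identity equals `target_identity`
#' (identical conserved positions plus chance agreement at variable
#' positions); variable positions draw residues independently per parent.
#' Realized pairwise identities are checked to fall within ±0.05 of the
#' target (resampled a few times if not). Emulates a set of homologous
#' seven-transmembrane parents at moderate identity.
#'
#' @param n_parents Number of parents (default 3).
#' @param length Alignment length (default 300; must be ≥ 20).
#' @param target_identity Target pairwise identity in (0, 1) (default 0.5).
#' @param seed Random seed (default 0).
#' @param signal_peptide Span of the signal peptide (default `c(1, 20)`).
#' @return A [parent_set()].
#' @export
generate_parents <- function(n_parents = 3, length = 300,
                             target_identity = 0.5, seed = 0,
                             signal_peptide = c(1, 20)) {
  if (target_identity <= 0 || target_identity >= 1) {
    abort("`target_identity` must be in (0, 1).", class = "chimeraGP_error")
  }
  if (length < 20) {
    abort("Alignments shorter than 20 cannot hit an identity target reliably.",
          class = "chimeraGP_error")
  }
  chance <- 1 / 20
  q <- (target_identity - chance) / (1 - chance)
  q <- min(max(q, 0), 1)
  with_seed(seed, {
    for (try in 1:20) {
      conserved <- runif(length) < q
      base <- sample(AA20, length, replace = TRUE)
      chars <- matrix("", nrow = n_parents, ncol = length)
      for (p in seq_len(n_parents)) {
        chars[p, ] <- ifelse(conserved, base,
                             sample(AA20, length, replace = TRUE))
      }
      seqs <- apply(chars, 1, paste, collapse = "")
      names(seqs) <- paste0("P", seq_len(n_parents))
      ps <- parent_set(seqs, signal_peptide = signal_peptide)
      ident <- pairwise_identity(ps)$identity
      if (all(abs(ident - target_identity) <= 0.05)) return(ps)
    }
    abort("Could not realize the identity target within +/- 0.05.",
          class = "chimeraGP_error")
  })
}

#' Generate a synthetic contact map
#'
#' Samples contact pairs with probability decaying in sequence separation
#' (geometric-style contacts of a folded chain), excluding self and
#' adjacent pairs (`|i - j| < 2`). The expected number of contacts per
#' residue equals `mean_contacts_per_residue`.
#'
#' @param length Alignment length (≥ 3).
#' @param mean_contacts_per_residue Average contact degree (default 4).
#' @param seed Random seed.
#' @param decay Separation scale of the decay (default 10).
#' @return A [contact_map()].
#' @export
generate_contacts <- function(length, mean_contacts_per_residue = 4,
                              seed = 0, decay = 10) {
  if (length < 3) abort("`length` must be >= 3.", class = "chimeraGP_error")
  n_pairs <- round(length * mean_contacts_per_residue / 2)
  if (n_pairs == 0) {
    return(contact_map(matrix(integer(0), ncol = 2), threshold = NA_real_))
  }
  elig <- which(upper.tri(matrix(0, length, length)), arr.ind = TRUE)
  elig <- elig[elig[, 2] - elig[, 1] >= 2, , drop = FALSE]
  if (n_pairs > nrow(elig)) {
    abort("Requested more contacts than eligible pairs.",
          class = "chimeraGP_error")
  }
  with_seed(seed, {
    w <- exp(-(elig[, 2] - elig[, 1]) / decay)
    pick <- sample(nrow(elig), n_pairs, prob = w)
    contact_map(elig[pick, , drop = FALSE], threshold = NA_real_,
                source = "synthetic")
  })
}

#' Generate a (possibly non-contiguous) block design
#'
#' Contiguous designs split the alignment into near-equal runs. For
#' non-contiguous designs the alignment is cut into `2 * n_blocks` segments
#' which are dealt to blocks at random, giving blocks contiguous in
#' "structure" but not in sequence.
#'
#' @param length Alignment length.
#' @param n_blocks Number of blocks (default 10).
#' @param library_id Design label.
#' @param contiguous Contiguity flag.
#' @param seed Seed for the non-contiguous shuffle.
#' @return A [block_design()].
#' @export
generate_block_design <- function(length, n_blocks = 10, library_id = "c",
                                  contiguous = TRUE, seed = 0) {
  if (contiguous) return(block_design_contiguous(length, n_blocks, library_id))
  seg_of_pos <- sort(rep_len(seq_len(2 * n_blocks), length))
  with_seed(seed, {
    block_of_seg <- sample(rep_len(seq_len(n_blocks), 2 * n_blocks))
    block_design(block_of_seg[seg_of_pos], library_id = library_id)
  })
}

#' Specification of a synthetic fitness landscape
#'
#' Defines the ground truth used by [simulate_landscape()]: a sparse set of
#' additive (position, residue) weights, a sparse set of epistatic
#' (contact, residue-pair) weights, Gaussian noise on the log2 scale, and
#' the seed. Magnitudes default to |weight| in \[1, 2\] (log2 units, random
#' signs) with noise 0.5, i.e. effects well above noise, as appropriate for
#' a membrane-protein localization landscape dominated by a limited set of
#' strong sequence/contact determinants.
#'
#' @param n_additive Number of non-zero additive features (default 6).
#' @param n_epistatic Number of non-zero contact features (default 4).
#' @param weight_range Range of |weight| (default `c(1, 2)`).
#' @param noise_sd Gaussian noise standard deviation on log2 scale
#'   (default 0.5).
#' @param base_log2 Landscape intercept on log2 scale (default 2).
#' @param threshold Optional classification threshold on the log2 scale;
#'   `NULL` (default) defers labeling to [make_labels()].
#' @param seed Random seed (default 0).
#' @export
landscape_spec <- function(n_additive = 6, n_epistatic = 4,
                           weight_range = c(1, 2), noise_sd = 0.5,
                           base_log2 = 2, threshold = NULL, seed = 0) {
  structure(
    list(n_additive = n_additive, n_epistatic = n_epistatic,
         weight_range = weight_range, noise_sd = noise_sd,
         base_log2 = base_log2, threshold = threshold, seed = seed),
    class = "landscape_spec"
  )
}

sample_true_features <- function(encoding, spec) {
  idx <- encoding$index
  # additive truths on variable positions only (constant features are
  # confounded with the intercept)
  variable_se <- idx$column[idx$type == "residue" &
                              vapply(idx$pos_i, function(p) {
                                length(encoding$pos_alpha[[p]]) > 1
                              }, logical(1)) & idx$type == "residue"]
  variable_st <- idx$column[idx$type == "contact"]
  if (length(variable_st)) {
    varying <- vapply(variable_st, function(cl) {
      r <- idx[cl, ]
      length(encoding$pos_alpha[[r$pos_i]]) > 1 ||
        length(encoding$pos_alpha[[r$pos_j]]) > 1
    }, logical(1))
    variable_st <- variable_st[varying]
  }
  n_add <- min(spec$n_additive, length(variable_se))
  n_epi <- min(spec$n_epistatic, length(variable_st))
  cols <- c(sample(variable_se, n_add),
            if (n_epi > 0) sample(variable_st, n_epi))
  signs <- sample(c(-1, 1), length(cols), replace = TRUE)
  mags <- runif(length(cols), spec$weight_range[1], spec$weight_range[2])
  tibble(column = cols,
         type = idx$type[cols],
         weight = signs * mags)
}

#' Simulate measurements over a synthetic recombination library
#'
#' Draws a training-style set of chimeras (the parents, every single-block
#' swap of every design, and a random sample of multi-block-swap chimeras),
#' computes responses from a sparse additive + contact-epistatic landscape
#' on the log2 scale with Gaussian noise, and emits a measurements table in
#' the standard dialect (linear-scale means, so the pipeline's log2
#' transform recovers the modeled scale). Localization (`GFP_mean`) carries
#' the full epistatic landscape; expression (`mKate_mean`) carries an
#' additive-only landscape, echoing the observation that expression is the
#' simpler property.
#'
#' @param parents A [parent_set()].
#' @param designs A [block_design()] or list of them.
#' @param contacts A [contact_map()].
#' @param spec A [landscape_spec()].
#' @param n_multi Number of random multi-block-swap chimeras (default 103).
#' @param detection_limit Optional linear-scale limit below which
#'   localization values are reported as missing (`ND`).
#' @return An object of class `synthetic_landscape`: list with
#'   `measurements` (tibble), `encoding`, `X` (feature matrix of the
#'   measured chimeras), `truth` (list with per-property weight tables and
#'   the log2-scale responses before noise), and `spec`.
#' @export
simulate_landscape <- function(parents, designs, contacts,
                               spec = landscape_spec(), n_multi = 103,
                               detection_limit = NULL) {
  designs <- as_design_list(designs)
  encoding <- build_encoding(parents, contacts)
  P <- parents$n_parents

  rows <- list()
  for (d in designs) {
    check_design(d, parents)
    B <- d$n_blocks
    # single-block swaps: background parent b, one block from donor q != b
    for (bg in seq_len(P)) {
      for (blk in seq_len(B)) {
        for (q in setdiff(seq_len(P), bg)) {
          a <- rep(bg, B); a[blk] <- q
          rows[[length(rows) + 1L]] <- list(design = d, a = a,
                                            set = "single_block_swap")
        }
      }
    }
  }
  seen <- vapply(rows, function(r) paste0(r$design$library_id,
                                          paste(r$a, collapse = "")),
                 character(1))
  with_seed(spec$seed, {
    # random multi-block chimeras, distinct from the single swaps
    n_try <- 0
    while (sum(vapply(rows, function(r) r$set == "multi_block_swap",
                      logical(1))) < n_multi && n_try < 50 * n_multi) {
      n_try <- n_try + 1
      d <- designs[[sample(length(designs), 1)]]
      a <- sample(P, d$n_blocks, replace = TRUE)
      key <- paste0(d$library_id, paste(a, collapse = ""))
      if (key %in% seen || length(unique(a)) == 1) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- list(design = d, a = a,
                                        set = "multi_block_swap")
    }
    # parents, represented in the first design
    for (p in seq_len(P)) {
      rows[[length(rows) + 1L]] <- list(design = designs[[1]],
                                        a = rep(p, designs[[1]]$n_blocks),
                                        set = "parent")
    }

    lib_ids <- vapply(rows, function(r) r$design$library_id, character(1))
    parts <- list(); part_rows <- list()
    for (lid in unique(lib_ids)) {
      idxs <- which(lib_ids == lid)
      d <- rows[[idxs[1]]]$design
      A <- do.call(rbind, lapply(rows[idxs], function(r) r$a))
      parts[[length(parts) + 1L]] <- encode_assignments(A, d, encoding)
      part_rows[[length(part_rows) + 1L]] <- idxs
    }
    X <- do.call(rbind, parts)[match(seq_along(rows), unlist(part_rows)), ,
                               drop = FALSE]
    attr(X, "extra_active") <- integer(nrow(X))

    truth_gfp <- sample_true_features(encoding, spec)
    truth_mkate <- sample_true_features(
      encoding,
      landscape_spec(n_additive = spec$n_additive, n_epistatic = 0,
                     weight_range = spec$weight_range)
    )
    resp <- function(truth) {
      w <- rep(0, encoding$n_features)
      w[truth$column] <- truth$weight
      spec$base_log2 + as.numeric(X %*% w)
    }
    f_gfp <- resp(truth_gfp)
    f_mkate <- resp(truth_mkate)
    y_gfp <- f_gfp + rnorm(length(f_gfp), 0, spec$noise_sd)
    y_mkate <- f_mkate + rnorm(length(f_mkate), 0, spec$noise_sd)

    seqs <- vapply(rows, function(r) {
      build_sequences(matrix(r$a, nrow = 1), parents, r$design)
    }, character(1))
    ids <- vapply(rows, function(r) {
      emit_chimera_id(r$a, r$design)
    }, character(1))
    name <- ifelse(
      vapply(rows, function(r) r$set == "parent", logical(1)),
      parents$names[vapply(rows, function(r) r$a[1], integer(1))],
      ids
    )
    gfp <- 2^y_gfp
    mkate <- 2^y_mkate
    nd <- rep(FALSE, length(gfp))
    if (!is.null(detection_limit)) {
      nd <- gfp < detection_limit
      gfp[nd] <- NA_real_
    }
    measurements <- tibble(
      chimera_name = name,
      set = vapply(rows, function(r) r$set, character(1)),
      n_mutations = mutation_count(seqs, parents),
      chimera_block_ID = ids,
      sequence = seqs,
      mKate_mean = mkate,
      mKate_std = 0.1 * mkate,
      GFP_mean = gfp,
      GFP_std = 0.1 * gfp,
      intensity_ratio_mean = gfp / mkate,
      intensity_ratio_std = 0.1 * gfp / mkate
    )
    structure(
      list(measurements = measurements, encoding = encoding, X = X,
           truth = list(gfp = truth_gfp, mkate = truth_mkate,
                        f_gfp = f_gfp, f_mkate = f_mkate,
                        y_gfp = y_gfp, y_mkate = y_mkate),
           parents = parents, designs = designs, contacts = contacts,
           spec = spec),
      class = "synthetic_landscape"
    )
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(
    "<synthetic_landscape> %d chimeras (%d features); %d additive + %d epistatic true weights, noise sd %.2f\n",
    nrow(x$measurements), x$encoding$n_features,
    sum(x$truth$gfp$type == "residue"), sum(x$truth$gfp$type == "contact"),
    x$spec$noise_sd))
  invisible(x)
}

#' Log2 response with below-detection imputation
#'
#' Measurements are modeled on the log2 scale. Below-detection (`NA`)
#' values are imputed at half the smallest detected value before the
#' transform; the returned `imputed` attribute flags them.
#'
#' @param values Linear-scale measurements (NA = below detection).
#' @return log2 values with attribute `imputed` (logical vector).
#' @export
log2_response <- function(values) {
  nd <- is.na(values)
  if (all(nd)) abort("All values are below detection.", class = "chimeraGP_error")
  fill <- min(values[!nd]) / 2
  v <- ifelse(nd, fill, values)
  out <- log2(v)
  attr(out, "imputed") <- nd
  out
}

#' Learning curve of predictive performance vs training-set size
#'
#' Holds out a fixed, seeded test set, then for each training-set size
#' fits models on random subsets of the remaining pool and averages the
#' test metric (Pearson R for regression, AUC for classification) over
#' replicates. Degenerate single-class classification subsamples are
#' redrawn (and counted).
#'
#' @param X Feature matrix.
#' @param y Responses on the modeling scale (regression) — always required
#'   (used for stratifying nothing, only for `metric = "r"`).
#' @param labels Optional class labels (required for `metric = "auc"`).
#' @param sizes Training-set sizes to evaluate.
#' @param replicates Random subsets per size (default 100).
#' @param metric `"r"` (regression LOO-free test Pearson R) or `"auc"`.
#' @param n_test Held-out test-set size (default 50).
#' @param kernel Kernel form passed to the fitters.
#' @param n_restarts Optimizer restarts per fit (default 3; learning curves
#'   fit many models).
#' @param seed Seed controlling the test split and all subsamples.
#' @return An object of class `learning_curve`: list with `results`
#'   (size, replicate, value) and `summary` (size, mean, se, n).
#' @export
learning_curve <- function(X, y, labels = NULL, sizes, replicates = 100,
                           metric = c("r", "auc"), n_test = 50,
                           kernel = "linear", n_restarts = 3, seed = 0) {
  metric <- match.arg(metric)
  n <- nrow(X)
  if (metric == "auc" && is.null(labels)) {
    abort("`labels` are required for metric = 'auc'.", class = "chimeraGP_error")
  }
  if (any(sizes > n - n_test)) {
    abort("`sizes` must leave room for the test set.", class = "chimeraGP_error")
  }
  yy <- if (metric == "auc") as_pm1(labels) else NULL
  results <- with_seed(seed, {
    test_idx <- sample(n, n_test)
    pool <- setdiff(seq_len(n), test_idx)
    purrr::map_dfr(sizes, function(sz) {
      purrr::map_dfr(seq_len(replicates), function(rep_i) {
        redraws <- 0
        repeat {
          tr <- sample(pool, sz)
          if (metric == "r" || length(unique(yy[tr])) > 1) break
          redraws <- redraws + 1
          if (redraws > 50) {
            abort("Could not draw a two-class training subsample.",
                  class = "chimeraGP_error")
          }
        }
        value <- if (metric == "r") {
          m <- fit_gp_regression(X[tr, , drop = FALSE], y[tr],
                                 kernel = kernel, n_restarts = n_restarts)
          cor(y[test_idx],
              predict(m, X[test_idx, , drop = FALSE])$.pred)
        } else {
          m <- fit_gp_classifier(X[tr, , drop = FALSE], yy[tr],
                                 kernel = kernel, n_restarts = n_restarts)
          roc_auc(yy[test_idx],
                  predict(m, X[test_idx, , drop = FALSE])$.prob)
        }
        tibble(size = sz, replicate = rep_i, value = value,
               redraws = redraws)
      })
    })
  })
  summary <- results |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(results = results, summary = summary, metric = metric,
                 seed = seed, n_test = n_test),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> metric %s, %d sizes x %d replicates\n",
              x$metric, nrow(x$summary), max(x$results$replicate)))
  print(x$summary)
  invisible(x)
}
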