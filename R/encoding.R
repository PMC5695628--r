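#' Create a residue contact map
#'
#' A contact map is a set of unordered alignment-position pairs whose
#' residues are in structural contact in a reference structure. Pairs are
#' stored canonically with `pos_i < pos_j`.
#'
#' @param pairs Two-column matrix or data frame of alignment positions.
#' @param threshold Heavy-atom distance threshold in Angstrom used to build
#'   the map (metadata).
#' @param source Structure identifier (metadata).
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(pairs, threshold = 4.5, source = NA_character_) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1] == pairs[, 2])) {
    abort("A contact map may not contain self pairs (i, i).",
          class = "chimeraGP_error")
  }
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("pos_i", "pos_j")
  structure(
    list(pairs = pairs, n_contacts = nrow(pairs),
         threshold = threshold, source = source),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d contacts (threshold %.2f A, source: %s)\n",
              x$n_contacts, x$threshold, x$source))
  invisible(x)
}

#' Build a contact map from atomic coordinates
#'
#' Two residues are in contact if any of their non-hydrogen atoms lie within
#' `threshold` Angstrom. Contacts between alignment neighbours
#' (`|i - j| < min_separation`) are excluded by default because
#' backbone-adjacent contacts are always present and duplicate sequence
#' information.
#'
#' @param atoms Data frame of heavy-atom records with columns `resno`
#'   (residue number in the structure), `element` (element symbol; rows with
#'   `"H"` are dropped), and coordinates `x`, `y`, `z`.
#' @param mapping Optional data frame with columns `resno`, `position`
#'   mapping structure residue numbers to alignment positions. Defaults to
#'   the identity. Residues without a mapping are skipped with a warning.
#' @param threshold Distance threshold in Angstrom (default 4.5).
#' @param min_separation Minimum alignment-position separation for a pair to
#'   be retained (default 2; set to 1 to keep adjacent contacts).
#' @return A [contact_map()].
#' @export
contact_map_from_atoms <- function(atoms, mapping = NULL, threshold = 4.5,
                                   min_separation = 2) {
  atoms <- as_tibble(atoms)
  if (!all(c("resno", "x", "y", "z") %in% names(atoms))) {
    abort("`atoms` needs columns resno, x, y, z.", class = "chimeraGP_error")
  }
  if ("element" %in% names(atoms)) {
    atoms <- dplyr::filter(atoms, toupper(.data$element) != "H")
  }
  resnos <- sort(unique(atoms$resno))
  if (is.null(mapping)) {
    pos_of <- setNames(resnos, resnos)
  } else {
    pos_of <- setNames(mapping$position, mapping$resno)
    unmapped <- setdiff(resnos, mapping$resno)
    if (length(unmapped)) {
      warn(sprintf("%d structure residues have no alignment mapping; skipped.",
                   length(unmapped)))
      resnos <- setdiff(resnos, unmapped)
    }
  }
  coords <- lapply(resnos, function(r) {
    as.matrix(atoms[atoms$resno == r, c("x", "y", "z")])
  })
  names(coords) <- resnos
  pairs <- list()
  n <- length(resnos)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      pi <- pos_of[as.character(resnos[a])]
      pj <- pos_of[as.character(resnos[b])]
      if (abs(pi - pj) < min_separation) next
      A <- coords[[a]]; B <- coords[[b]]
      # min inter-residue heavy-atom distance
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      if (min(d2) <= threshold^2) {
        pairs[[length(pairs) + 1L]] <- c(pi, pj)
      }
    }
  }
  if (!length(pairs)) {
    return(contact_map(matrix(integer(0), ncol = 2), threshold = threshold))
  }
  contact_map(do.call(rbind, pairs), threshold = threshold)
}

#' Build a contact map from a PDB file
#'
#' Reads heavy atoms from a PDB file (via the bio3d package) and delegates to
#' [contact_map_from_atoms()].
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier to restrict to.
#' @inheritParams contact_map_from_atoms
#' @export
contact_map_from_pdb <- function(path, mapping = NULL, threshold = 4.5,
                                 min_separation = 2, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Package 'bio3d' is required to read PDB files.")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem))) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  atoms <- tibble(resno = at$resno, element = elem,
                  x = at$x, y = at$y, z = at$z)
  cm <- contact_map_from_atoms(atoms, mapping = mapping, threshold = threshold,
                               min_separation = min_separation)
  cm$source <- basename(path)
  cm
}

#' Build a sequence/structure feature encoding for a chimera library
#'
#' Constructs the binary feature space: one indicator per (alignment
#' position, residue) for every residue observed among the parents at that
#' position, and one indicator per (contact, ordered residue pair) for every
#' combination of parental residues at the two contacting positions. Gap
#' characters contribute no feature. Sequences passed via `extra_sequences`
#' (e.g. an external homolog to be scored later) extend the per-position
#' alphabets.
#'
#' @param parents A [parent_set()].
#' @param contacts A [contact_map()] on the same alignment.
#' @param extra_sequences Optional aligned sequences whose residues are added
#'   to the alphabets.
#' @return An object of class `chimera_encoding` with fields `index` (a
#'   tibble describing every feature column), `n_se`, `n_st`, and fast
#'   lookup tables used by [encode_sequences()] and [encode_assignments()].
#' @export
build_encoding <- function(parents, contacts, extra_sequences = NULL) {
  stopifnot(inherits(parents, "parent_set"), inherits(contacts, "contact_map"))
  if (contacts$n_contacts > 0 && max(contacts$pairs) > parents$length) {
    abort("Contact map refers to positions beyond the alignment.",
          class = "chimeraGP_error")
  }
  L <- parents$length
  obs <- parents$chars
  if (!is.null(extra_sequences)) {
    extra <- do.call(rbind, strsplit(toupper(extra_sequences), "", fixed = TRUE))
    if (ncol(extra) != L) {
      abort("`extra_sequences` must match the alignment length.",
            class = "chimeraGP_error")
    }
    obs <- rbind(obs, extra)
  }
  pos_alpha <- lapply(seq_len(L), function(p) {
    aa <- unique(obs[, p])
    sort(aa[!is_gap(aa)])
  })

  # sequence features
  se_index <- purrr::map_dfr(seq_len(L), function(p) {
    if (!length(pos_alpha[[p]])) return(NULL)
    tibble(type = "residue", pos_i = p, pos_j = NA_integer_,
           aa_i = pos_alpha[[p]], aa_j = NA_character_)
  })
  n_se <- nrow(se_index)

  # structural contact features: cross product of the two position alphabets
  st_index <- NULL
  if (contacts$n_contacts > 0) {
    st_index <- purrr::map_dfr(seq_len(contacts$n_contacts), function(k) {
      i <- contacts$pairs[k, 1]; j <- contacts$pairs[k, 2]
      if (!length(pos_alpha[[i]]) || !length(pos_alpha[[j]])) return(NULL)
      grid <- expand.grid(aa_i = pos_alpha[[i]], aa_j = pos_alpha[[j]],
                          stringsAsFactors = FALSE)
      tibble(type = "contact", pos_i = i, pos_j = j,
             aa_i = grid$aa_i, aa_j = grid$aa_j, contact = k)
    })
  }
  n_st <- if (is.null(st_index)) 0L else nrow(st_index)

  index <- dplyr::bind_rows(se_index, st_index)
  index$column <- seq_len(nrow(index))

  # carriers: which parents realize each feature
  carrier <- character(nrow(index))
  for (r in seq_len(nrow(index))) {
    i <- index$pos_i[r]
    who <- parents$chars[, i] == index$aa_i[r]
    if (index$type[r] == "contact") {
      who_j <- parents$chars[, index$pos_j[r]] == index$aa_j[r]
      carrier[r] <- paste0(
        paste(parents$names[who], collapse = ","), "|",
        paste(parents$names[who_j], collapse = ",")
      )
    } else {
      carrier[r] <- paste(parents$names[who], collapse = ",")
    }
  }
  index$parents <- carrier

  # fast lookups
  se_lookup <- lapply(seq_len(L), function(p) {
    cols <- index$column[index$type == "residue" & index$pos_i == p]
    setNames(cols, index$aa_i[cols])
  })
  # per-parent column map: se_colmap[q, p] = column of (p, chars[q, p])
  se_colmap <- matrix(NA_integer_, nrow = parents$n_parents, ncol = L)
  for (p in seq_len(L)) {
    for (q in seq_len(parents$n_parents)) {
      aa <- parents$chars[q, p]
      if (!is_gap(aa)) se_colmap[q, p] <- se_lookup[[p]][[aa]]
    }
  }
  st_lookup <- list(); st_colmap <- list()
  if (n_st > 0) {
    sti <- index[index$type == "contact", ]
    by_contact <- split(sti, sti$contact)
    for (k in names(by_contact)) {
      tab <- by_contact[[k]]
      st_lookup[[k]] <- setNames(tab$column, paste(tab$aa_i, tab$aa_j))
      cm <- matrix(NA_integer_, parents$n_parents, parents$n_parents)
      i <- tab$pos_i[1]; j <- tab$pos_j[1]
      for (qa in seq_len(parents$n_parents)) {
        for (qb in seq_len(parents$n_parents)) {
          key <- paste(parents$chars[qa, i], parents$chars[qb, j])
          cm[qa, qb] <- st_lookup[[k]][key]  # NA if a gap is involved
        }
      }
      st_colmap[[k]] <- cm
    }
  }

  structure(
    list(index = index, n_se = n_se, n_st = n_st,
         n_features = nrow(index),
         pos_alpha = pos_alpha, contacts = contacts,
         parents = parents,
         se_lookup = se_lookup, se_colmap = se_colmap,
         st_lookup = st_lookup, st_colmap = st_colmap),
    class = "chimera_encoding"
  )
}

#' @export
print.chimera_encoding <- function(x, ...) {
  cat(sprintf(
    "<chimera_encoding> %d features (%d sequence, %d contact) over %d positions, %d contacts\n",
    x$n_features, x$n_se, x$n_st, x$parents$length, x$contacts$n_contacts))
  invisible(x)
}

#' Encode aligned sequences as binary feature vectors
#'
#' Each sequence activates exactly one (position, residue) feature per
#' non-gap position and one (contact, residue-pair) feature per contact not
#' involving a gap. Residues absent from the encoding's alphabet activate no
#' stored column; their count per sequence is returned in the
#' `extra_active` attribute so kernel computations can account for them
#' exactly (such features can never match a training sequence).
#'
#' @param sequences Character vector of aligned sequences.
#' @param encoding A [build_encoding()] result.
#' @return A sparse binary matrix (rows = sequences) with attribute
#'   `extra_active`.
#' @export
encode_sequences <- function(sequences, encoding) {
  stopifnot(inherits(encoding, "chimera_encoding"))
  L <- encoding$parents$length
  if (any(nchar(sequences) != L)) {
    abort("Sequences must match the alignment length.", class = "chimeraGP_error")
  }
  S <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  m <- nrow(S)
  rows <- integer(0); cols <- integer(0)
  extra <- integer(m)
  for (r in seq_len(m)) {
    ch <- S[r, ]
    cc <- integer(0)
    for (p in seq_len(L)) {
      if (is_gap(ch[p])) next
      col <- unname(encoding$se_lookup[[p]][ch[p]])
      if (is.na(col)) extra[r] <- extra[r] + 1L else cc <- c(cc, col)
    }
    cmap <- encoding$contacts$pairs
    for (k in seq_len(encoding$contacts$n_contacts)) {
      i <- cmap[k, 1]; j <- cmap[k, 2]
      if (is_gap(ch[i]) || is_gap(ch[j])) next
      lk <- encoding$st_lookup[[as.character(k)]]
      col <- if (is.null(lk)) NA_integer_ else unname(lk[paste(ch[i], ch[j])])
      if (is.na(col)) extra[r] <- extra[r] + 1L else cc <- c(cc, col)
    }
    rows <- c(rows, rep(r, length(cc)))
    cols <- c(cols, cc)
  }
  X <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(m, encoding$n_features))
  attr(X, "extra_active") <- extra
  X
}

#' Encode block-parent assignments directly (fast library path)
#'
#' Equivalent to reconstructing each chimera's sequence and calling
#' [encode_sequences()], but works directly from the assignment matrix via
#' precomputed lookup tables, which is what makes full-library scans cheap.
#'
#' @param assignments Integer matrix (rows = chimeras, cols = blocks).
#' @param design A [block_design()].
#' @param encoding A [build_encoding()] result.
#' @return Sparse binary feature matrix with attribute `extra_active`
#'   (always zero here: library chimeras only realize parental residues).
#' @export
encode_assignments <- function(assignments, design, encoding) {
  if (is.null(dim(assignments))) assignments <- matrix(assignments, nrow = 1)
  m <- nrow(assignments)
  L <- encoding$parents$length
  # parent index at every position for every chimera (m x L)
  P_idx <- assignments[, design$block, drop = FALSE]
  se_cols <- matrix(encoding$se_colmap[cbind(as.vector(P_idx),
                                             rep(seq_len(L), each = m))],
                    nrow = m)
  idx <- which(!is.na(se_cols))
  rows <- ((idx - 1L) %% m) + 1L
  cols <- se_cols[idx]
  cmap <- encoding$contacts$pairs
  st_rows <- list(); st_cols <- list()
  for (k in seq_len(encoding$contacts$n_contacts)) {
    i <- cmap[k, 1]; j <- cmap[k, 2]
    colmap <- encoding$st_colmap[[as.character(k)]]
    if (is.null(colmap)) next
    ck <- colmap[cbind(P_idx[, i], P_idx[, j])]
    keep <- which(!is.na(ck))
    st_rows[[k]] <- keep
    st_cols[[k]] <- ck[keep]
  }
  rows <- c(rows, unlist(st_rows))
  cols <- c(cols, unlist(st_cols))
  X <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(m, encoding$n_features))
  attr(X, "extra_active") <- integer(m)
  X
}

#' Sequence and structural similarity counts between encoded variants
#'
#' The number of identical aligned positions and the number of identical
#' contacts between two variants are the dot products of the sequence and
#' contact parts of their feature vectors.
#'
#' @param X_a,X_b Encoded feature matrices sharing a feature index (rows are
#'   variants). `X_b` defaults to `X_a`.
#' @param encoding The shared [build_encoding()].
#' @return A list with matrices `positions` and `contacts` of pairwise
#'   counts (rows of `X_a` by rows of `X_b`).
#' @export
similarity_counts <- function(X_a, encoding, X_b = X_a) {
  if (ncol(X_a) != encoding$n_features || ncol(X_b) != encoding$n_features) {
    abort("Feature matrices do not match the encoding's feature index.",
          class = "chimeraGP_error")
  }
  se <- seq_len(encoding$n_se)
  st <- setdiff(seq_len(encoding$n_features), se)
  pos <- as.matrix(X_a[, se, drop = FALSE] %*% Matrix::t(X_b[, se, drop = FALSE]))
  con <- if (length(st)) {
    as.matrix(X_a[, st, drop = FALSE] %*% Matrix::t(X_b[, st, drop = FALSE]))
  } else {
    matrix(0, nrow(X_a), nrow(X_b))
  }
  list(positions = pos, contacts = con)
}

#' Collapse covarying feature columns
#'
#' Columns that are identical across all rows of the training feature matrix
#' cannot be distinguished by any model fitted to those rows; they are merged
#' into a single representative feature. Constant-zero and constant-one
#' columns form their own (flagged) groups.
#'
#' @param X Binary feature matrix (rows = training variants).
#' @return A list with `reduced` (one column per group, the representative
#'   column values) and `groups` (tibble with `column`, `group`,
#'   `representative`, `constant`).
#' @export
collapse_covarying <- function(X) {
  M <- as.matrix(X)
  if (nrow(M) < 1) abort("Need at least one row.", class = "chimeraGP_error")
  key <- apply(M, 2, paste, collapse = "")
  group <- match(key, unique(key))
  rep_col <- vapply(seq_len(max(group)),
                    function(g) which(group == g)[1], integer(1))
  csum <- colSums(M)
  constant <- rep(NA_character_, ncol(M))
  constant[csum == 0] <- "zero"
  constant[csum == nrow(M)] <- "one"
  groups <- tibble(
    column = seq_len(ncol(M)),
    group = group,
    representative = rep_col[group],
    constant = constant
  )
  list(reduced = M[, rep_col, drop = FALSE], groups = groups)
}

#' Expand a collapsed matrix back to the original columns
#'
#' @param reduced Reduced matrix from [collapse_covarying()].
#' @param groups The `groups` tibble from [collapse_covarying()].
#' @export
expand_collapsed <- function(reduced, groups) {
  reduced[, groups$group, drop = FALSE]
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of hydropathy values for the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

#' Net hydrophobicity over transmembrane positions
#'
#' Sums Kyte-Doolittle hydropathy over the given positions of each sequence.
#' Gap characters contribute zero; unknown residue letters raise an error.
#'
#' @param sequences Character vector of (aligned) sequences.
#' @param tm_positions Integer vector of positions belonging to the
#'   transmembrane domains.
#' @return Numeric vector of hydrophobicity scores.
#' @export
hydrophobicity_score <- function(sequences, tm_positions) {
  scale <- kyte_doolittle()
  vapply(sequences, function(s) {
    ch <- seq_chars(toupper(s))[tm_positions]
    ch <- ch[!is_gap(ch)]
    if (!length(ch)) return(0)
    v <- scale[ch]
    if (anyNA(v)) {
      abort(sprintf("Unknown residue letter(s): %s",
                    paste(unique(ch[is.na(v)]), collapse = ", ")),
            class = "chimeraGP_error")
    }
    sum(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Signal-peptide parent of each chimera
#'
#' The signal peptide of a chimera is contributed by the parent assigned to
#' the N-terminal block (block 1 by default).
#'
#' @param assignments Integer matrix of block-parent assignments.
#' @param parents A [parent_set()].
#' @param sp_block Block index carrying the signal peptide (default 1).
#' @return Character vector of parent names.
#' @export
signal_peptide_parent <- function(assignments, parents, sp_block = 1L) {
  if (is.null(dim(assignments))) assignments <- matrix(assignments, nrow = 1)
  parents$names[assignments[, sp_block]]
}

#' Per-group baseline summary of measured properties
#'
#' Groups measurements (e.g. by signal-peptide parent) and summarizes each
#' property's mean, standard deviation and count. Groups present in the
#' grouping factor but empty in the data are omitted with a warning.
#'
#' @param measurements A measurements tibble.
#' @param group Character or factor vector, one label per row.
#' @param properties Names of numeric columns to summarize.
#' @return A tibble with one row per (group, property).
#' @export
baseline_group_summary <- function(measurements, group,
                                   properties = intersect(
                                     c("mKate_mean", "GFP_mean",
                                       "intensity_ratio_mean"),
                                     names(measurements))) {
  group <- as.factor(group)
  empty <- setdiff(levels(group), unique(as.character(group[!is.na(group)])))
  if (length(empty)) {
    warn(sprintf("Empty group(s) omitted: %s", paste(empty, collapse = ", ")))
  }
  measurements |>
    dplyr::mutate(.group = as.character(group)) |>
    tidyr::pivot_longer(dplyr::all_of(properties),
                        names_to = "property", values_to = "value") |>
    dplyr::group_by(.data$.group, .data$property) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::rename(group = ".group")
}
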