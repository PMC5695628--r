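#' Create a parent set
#'
#' A parent set holds two or more aligned parental protein sequences on a
#' shared alignment, plus optional per-parent signal-peptide spans. All
#' downstream objects (block designs, chimeras, contact maps, feature
#' encodings) live on this alignment coordinate frame.
#'
#' @param sequences Named character vector of aligned amino-acid sequences
#'   (equal length; `-` or `.` for gaps). Names are the parent identifiers.
#' @param signal_peptide Optional integer vector of length 2 (shared
#'   `c(start, end)` span on the alignment) or a named list of such vectors,
#'   one per parent.
#' @return An object of class `parent_set`.
#' @examples
#' parent_set(c(A = "MKTA", B = "MRTA"))
#' @export
parent_set <- function(sequences, signal_peptide = NULL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("`sequences` must be a named vector with unique parent names.",
          class = "chimeraGP_error")
  }
  if (length(sequences) < 2L) {
    abort("A parent set needs at least two parents.", class = "chimeraGP_error")
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort("All aligned parent sequences must have identical length.",
          class = "chimeraGP_error")
  }
  chars <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  rownames(chars) <- names(sequences)
  if (!is.null(signal_peptide) && !is.list(signal_peptide)) {
    signal_peptide <- setNames(
      rep(list(as.integer(signal_peptide)), length(sequences)),
      names(sequences)
    )
  }
  structure(
    list(
      names = names(sequences),
      seqs = setNames(toupper(sequences), names(sequences)),
      chars = chars,
      length = unname(lens[1]),
      n_parents = length(sequences),
      signal_peptide = signal_peptide
    ),
    class = "parent_set"
  )
}

#' @export
print.parent_set <- function(x, ...) {
  cat(sprintf("<parent_set> %d parents, alignment length %d\n",
              x$n_parents, x$length))
  cat("  parents:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Mean pairwise sequence identity of a parent set
#'
#' Fraction of alignment positions at which two parents carry the same
#' character, averaged over all parent pairs (gap-gap positions excluded).
#'
#' @param parents A [parent_set()].
#' @return A tibble with one row per parent pair and an `identity` column.
#' @export
pairwise_identity <- function(parents) {
  stopifnot(inherits(parents, "parent_set"))
  combs <- utils::combn(parents$n_parents, 2)
  purrr::map_dfr(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    a <- parents$chars[i, ]; b <- parents$chars[j, ]
    keep <- !(is_gap(a) & is_gap(b))
    tibble(
      parent_a = parents$names[i], parent_b = parents$names[j],
      identity = mean(a[keep] == b[keep])
    )
  })
}

#' Create a block design
#'
#' Maps every alignment position to a recombination block. Blocks need not be
#' contiguous in sequence: the representation is a plain position-to-block
#' map, so contiguous and non-contiguous library designs are handled
#' identically everywhere downstream.
#'
#' @param block Integer vector, one entry per alignment position, giving the
#'   block index (1..n_blocks) of that position.
#' @param library_id Single-character label of the library design (e.g. `"c"`
#'   for contiguous, `"n"` for non-contiguous).
#' @return An object of class `block_design`.
#' @export
block_design <- function(block, library_id = "c") {
  block <- as.integer(block)
  if (anyNA(block)) abort("`block` must not contain NA.", class = "chimeraGP_error")
  n_blocks <- max(block)
  if (!setequal(unique(block), seq_len(n_blocks))) {
    abort("Block indices must be contiguous from 1.", class = "chimeraGP_error")
  }
  if (nchar(library_id) != 1L) {
    abort("`library_id` must be a single character.", class = "chimeraGP_error")
  }
  structure(
    list(library_id = library_id, n_blocks = n_blocks,
         block = block, length = length(block)),
    class = "block_design"
  )
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> '%s': %d blocks over %d positions\n",
              x$library_id, x$n_blocks, x$length))
  invisible(x)
}

#' Contiguous block design with near-equal block sizes
#'
#' @param length Alignment length.
#' @param n_blocks Number of blocks.
#' @inheritParams block_design
#' @export
block_design_contiguous <- function(length, n_blocks, library_id = "c") {
  block <- sort(rep_len(seq_len(n_blocks), length))
  block_design(block, library_id = library_id)
}

check_design <- function(design, parents) {
  if (design$length != parents$length) {
    abort(sprintf(
      "Design '%s' covers %d positions but the alignment has %d.",
      design$library_id, design$length, parents$length
    ), class = "chimeraGP_design_error")
  }
  invisible(design)
}

as_design_list <- function(designs) {
  if (inherits(designs, "block_design")) list(designs) else designs
}

#' Number of chimeras in one or more library designs
#'
#' Each design with B blocks over P parents contributes P^B chimeras;
#' chimeras identical across designs are counted separately (use
#' [dedupe_chimeras()] to collapse them if needed).
#'
#' @param parents A [parent_set()].
#' @param designs A [block_design()] or list of them.
#' @return Total count as a double (counts can exceed integer range).
#' @examples
#' p <- parent_set(c(A = "AAAA", B = "CCCC", C = "DDDD"))
#' d <- block_design_contiguous(4, 2)
#' n_chimeras(p, d)  # 3^2 = 9
#' @export
n_chimeras <- function(parents, designs) {
  designs <- as_design_list(designs)
  sum(map_dbl(designs, function(d) {
    check_design(d, parents)
    parents$n_parents^d$n_blocks
  }))
}

# Decode chunk of chimera indices (0-based) of one design into an assignment
# matrix (rows = chimeras, cols = blocks, values = parent index 1..P).
# Digit order: block 1 is the most significant digit.
assignment_chunk <- function(idx, n_blocks, n_parents) {
  A <- matrix(0L, nrow = length(idx), ncol = n_blocks)
  for (b in seq_len(n_blocks)) {
    A[, b] <- (idx %/% n_parents^(n_blocks - b)) %% n_parents + 1L
  }
  A
}

#' Enumerate every chimera of one or more block designs
#'
#' @inheritParams n_chimeras
#' @param sequences If `TRUE`, also reconstruct each chimera's aligned
#'   sequence (memory-heavy for large libraries; prefer the chunked scanners
#'   in [rank_library()] / [classify_library()] there).
#' @param digit_map Character vector mapping parents (in parent-set order) to
#'   ID digits; defaults to `"0", "1", ...`.
#' @return A tibble with columns `id`, `library_id`, `assignment` (digit
#'   string, one digit per block) and optionally `sequence`.
#' @export
enumerate_chimeras <- function(parents, designs, sequences = FALSE,
                               digit_map = NULL) {
  designs <- as_design_list(designs)
  digit_map <- digit_map %||% as.character(seq_len(parents$n_parents) - 1L)
  purrr::map_dfr(designs, function(d) {
    check_design(d, parents)
    n <- parents$n_parents^d$n_blocks
    A <- assignment_chunk(seq_len(n) - 1, d$n_blocks, parents$n_parents)
    digits <- matrix(digit_map[A], nrow = nrow(A))
    assignment <- apply(digits, 1, paste, collapse = "")
    out <- tibble(
      id = paste0(d$library_id, assignment),
      library_id = d$library_id,
      assignment = assignment
    )
    if (sequences) out$sequence <- build_sequences(A, parents, d)
    out
  })
}

#' Reconstruct chimera sequences from block-parent assignments
#'
#' @param assignments Integer matrix (rows = chimeras, cols = blocks, values =
#'   parent indices 1..P) or a single integer vector for one chimera.
#' @param parents A [parent_set()].
#' @param design A [block_design()].
#' @return Character vector of aligned sequences.
#' @export
build_sequences <- function(assignments, parents, design) {
  if (is.null(dim(assignments))) assignments <- matrix(assignments, nrow = 1)
  check_design(design, parents)
  if (ncol(assignments) != design$n_blocks) {
    abort("Assignment length must equal the number of blocks.",
          class = "chimeraGP_error")
  }
  if (any(assignments < 1 | assignments > parents$n_parents)) {
    abort("Unknown parent index in assignment.", class = "chimeraGP_error")
  }
  S <- matrix("", nrow = nrow(assignments), ncol = design$length)
  for (b in seq_len(design$n_blocks)) {
    pos <- which(design$block == b)
    S[, pos] <- parents$chars[assignments[, b], pos, drop = FALSE]
  }
  apply(S, 1, paste, collapse = "")
}

#' @rdname build_sequences
#' @export
build_sequence <- function(assignments, parents, design) {
  build_sequences(assignments, parents, design)[1]
}

#' Parse a chimera identifier
#'
#' IDs consist of a one-character library prefix selecting the design,
#' followed by one digit per block giving the donor parent of that block.
#' The digit-to-parent mapping is configurable and defaults to digit `i`
#' meaning parent `i + 1` in parent-set order (the convention in which parent
#' order is chosen so that e.g. `'0'` = CheRiff, `'1'` = C1C2,
#' `'2'` = CsChrimR).
#'
#' @param id Chimera ID string, e.g. `"c0120012001"`.
#' @inheritParams enumerate_chimeras
#' @return A list with `design`, `block_parents` (integer vector),
#'   `id`, and `sequence`.
#' @export
parse_chimera_id <- function(id, parents, designs, digit_map = NULL) {
  designs <- as_design_list(designs)
  digit_map <- digit_map %||% as.character(seq_len(parents$n_parents) - 1L)
  prefix <- substr(id, 1, 1)
  hit <- purrr::detect(designs, function(d) d$library_id == prefix)
  if (is.null(hit)) {
    abort(sprintf("Unknown library prefix '%s' at position 1 of id '%s'.",
                  prefix, id),
          class = "chimeraGP_parse_error")
  }
  digits <- seq_chars(substr(id, 2, nchar(id)))
  if (length(digits) != hit$n_blocks) {
    abort(sprintf(
      "Id '%s' has %d block digits but design '%s' has %d blocks (position %d).",
      id, length(digits), hit$library_id, hit$n_blocks, nchar(id)
    ), class = "chimeraGP_parse_error")
  }
  bp <- match(digits, digit_map)
  if (anyNA(bp)) {
    bad <- which(is.na(bp))[1]
    abort(sprintf("Unknown parent digit '%s' at position %d of id '%s'.",
                  digits[bad], bad + 1L, id),
          class = "chimeraGP_parse_error")
  }
  list(
    design = hit,
    block_parents = bp,
    id = id,
    sequence = build_sequences(matrix(bp, nrow = 1), parents, hit)
  )
}

#' Emit a chimera identifier
#'
#' Inverse of [parse_chimera_id()].
#'
#' @param block_parents Integer vector of parent indices, one per block.
#' @param design A [block_design()].
#' @inheritParams enumerate_chimeras
#' @export
emit_chimera_id <- function(block_parents, design, digit_map = NULL) {
  digit_map <- digit_map %||% as.character(0:9)
  paste0(design$library_id,
         paste(digit_map[block_parents], collapse = ""))
}

#' Mutations from the nearest parent
#'
#' Hamming distance on the alignment between each chimera sequence and its
#' closest parent (positions where both carry a gap are ignored; a gap versus
#' a residue counts as a difference).
#'
#' @param sequences Character vector of aligned sequences.
#' @param parents A [parent_set()].
#' @return Integer vector of mutation counts.
#' @export
mutation_count <- function(sequences, parents) {
  stopifnot(inherits(parents, "parent_set"))
  if (any(nchar(sequences) != parents$length)) {
    abort("Sequences must match the alignment length.", class = "chimeraGP_error")
  }
  S <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  D <- matrix(0L, nrow = nrow(S), ncol = parents$n_parents)
  for (p in seq_len(parents$n_parents)) {
    pc <- matrix(parents$chars[p, ], nrow = nrow(S), ncol = parents$length,
                 byrow = TRUE)
    both_gap <- is_gap(S) & is_gap(pc)
    D[, p] <- rowSums((S != pc) & !both_gap)
  }
  as.integer(apply(D, 1, min))
}

#' All single-block swaps into a background sequence
#'
#' Generates every variant obtained by replacing one block of the background
#' sequence with the corresponding block of a donor parent. The background
#' may be any sequence aligned to the parents, including a homolog from
#' outside the recombination library. Swaps that change no position are
#' dropped.
#'
#' @param background Aligned background sequence (character scalar).
#' @param parents A [parent_set()] of donor parents.
#' @param design A [block_design()].
#' @return A tibble with columns `block`, `donor`, `donor_name`, `sequence`
#'   and `n_changed` (positions changed relative to the background).
#' @export
single_block_swaps <- function(background, parents, design) {
  check_design(design, parents)
  if (nchar(background) != parents$length) {
    abort("Background must be aligned to the parents.", class = "chimeraGP_error")
  }
  bg <- seq_chars(toupper(background))
  out <- purrr::map_dfr(seq_len(design$n_blocks), function(b) {
    pos <- which(design$block == b)
    purrr::map_dfr(seq_len(parents$n_parents), function(q) {
      donor_chars <- parents$chars[q, pos]
      n_changed <- sum(donor_chars != bg[pos])
      if (n_changed == 0L) return(NULL)
      variant <- bg
      variant[pos] <- donor_chars
      tibble(block = b, donor = q, donor_name = parents$names[q],
             sequence = chars_to_seq(variant), n_changed = n_changed)
    })
  })
  out
}

#' Drop duplicate chimeras by sequence
#'
#' Chimeras identical across designs (or across assignments) are counted
#' separately during enumeration; this utility collapses them when a unique
#' sequence set is wanted.
#'
#' @param chimeras Tibble with a `sequence` column.
#' @export
dedupe_chimeras <- function(chimeras) {
  dplyr::distinct(chimeras, .data$sequence, .keep_all = TRUE)
}

#' Strip alignment gaps from sequences
#'
#' @param sequences Character vector of aligned sequences.
#' @export
ungap <- function(sequences) gsub("[-.]", "", sequences)
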