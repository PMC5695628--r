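#' Read aligned sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    return(setNames(as.character(x), names(x)))
  }
  # minimal fallback parser
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param ungapped Strip alignment gaps before writing.
#' @export
write_fasta <- function(sequences, path, ungapped = FALSE) {
  if (ungapped) sequences <- ungap(sequences)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(c(paste0(">", names(sequences)[i]), sequences[[i]]), con)
  }
  invisible(path)
}

#' Read a parent set from FASTA
#'
#' @inheritParams read_fasta
#' @param signal_peptide Passed to [parent_set()].
#' @export
read_parents <- function(path, signal_peptide = NULL) {
  parent_set(read_fasta(path), signal_peptide = signal_peptide)
}

#' Read / write block designs as TSV
#'
#' The file has columns `library_id`, `position` (1-based on the
#' alignment), `block`; several designs may share a file.
#'
#' @param path TSV path.
#' @return A list of [block_design()] objects (length one if the file holds
#'   a single design).
#' @export
read_block_designs <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    library_id = readr::col_character(),
    position = readr::col_integer(),
    block = readr::col_integer()
  ))
  lapply(split(tab, tab$library_id), function(d) {
    d <- d[order(d$position), ]
    if (!identical(d$position, seq_len(nrow(d)))) {
      abort(sprintf("Design '%s' does not cover positions 1..%d exactly.",
                    d$library_id[1], nrow(d)),
            class = "chimeraGP_io_error")
    }
    block_design(d$block, library_id = d$library_id[1])
  })
}

#' @rdname read_block_designs
#' @param designs A [block_design()] or list of them.
#' @export
write_block_designs <- function(designs, path) {
  designs <- as_design_list(designs)
  tab <- purrr::map_dfr(designs, function(d) {
    tibble(library_id = d$library_id, position = seq_len(d$length),
           block = d$block)
  })
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read / write contact maps as TSV
#'
#' Columns `pos_i`, `pos_j` (1-based alignment positions) and optionally
#' `min_distance`.
#'
#' @param path TSV path.
#' @param threshold Threshold metadata to attach on read.
#' @export
read_contacts <- function(path, threshold = 4.5) {
  tab <- readr::read_tsv(path, col_types = readr::cols())
  if (!all(c("pos_i", "pos_j") %in% names(tab))) {
    abort("Contact file needs columns pos_i, pos_j.",
          class = "chimeraGP_io_error")
  }
  contact_map(as.matrix(tab[, c("pos_i", "pos_j")]), threshold = threshold,
              source = basename(path))
}

#' @rdname read_contacts
#' @param contacts A [contact_map()].
#' @export
write_contacts <- function(contacts, path) {
  readr::write_tsv(as_tibble(contacts$pairs), path)
  invisible(path)
}

measurement_cols <- c("chimera_name", "set", "n_mutations",
                      "chimera_block_ID", "sequence",
                      "mKate_mean", "mKate_std", "GFP_mean", "GFP_std",
                      "intensity_ratio_mean", "intensity_ratio_std")

#' Read a measurements table
#'
#' Reads the standard measurements dialect: one row per chimera with its
#' name, set label, mutation count, block ID, sequence, and mean/std of
#' expression (`mKate`), localization (`GFP`) and localization efficiency
#' (`intensity_ratio`). The sentinel `ND` (below the detection limit) is
#' parsed to `NA` and flagged in the logical columns `<property>_nd`; rows
#' are never dropped. When `parents` and `designs` are given, each
#' `chimera_block_ID` is validated against the reconstructed sequence and
#' mismatches are reported.
#'
#' @param path CSV path.
#' @param parents,designs Optional library definition for validation.
#' @return A tibble.
#' @export
read_measurements <- function(path, parents = NULL, designs = NULL) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  missing <- setdiff(setdiff(measurement_cols, "n_mutations"), names(tab))
  if ("number of mutations" %in% names(tab)) {
    tab <- dplyr::rename(tab, n_mutations = "number of mutations")
  }
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "chimeraGP_io_error")
  }
  num_cols <- grep("_(mean|std)$", measurement_cols, value = TRUE)
  for (cc in num_cols) {
    nd <- trimws(tab[[cc]]) == "ND"
    vals <- suppressWarnings(as.numeric(ifelse(nd, NA, tab[[cc]])))
    bad <- which(!nd & is.na(vals) & trimws(tab[[cc]]) != "")
    if (length(bad)) {
      abort(sprintf("Unparseable value in column '%s', line %d.",
                    cc, bad[1] + 1L),
            class = "chimeraGP_io_error")
    }
    tab[[cc]] <- vals
    if (grepl("_mean$", cc)) tab[[paste0(sub("_mean$", "", cc), "_nd")]] <- nd
  }
  if ("n_mutations" %in% names(tab)) {
    tab$n_mutations <- as.integer(tab$n_mutations)
  }
  if (!is.null(parents) && !is.null(designs)) {
    bad <- purrr::imap(tab$chimera_block_ID, function(id, i) {
      parsed <- tryCatch(parse_chimera_id(id, parents, designs),
                         error = function(e) NULL)
      if (is.null(parsed)) return(sprintf("row %d: unparseable id '%s'", i, id))
      if (!is.na(tab$sequence[i]) && nzchar(tab$sequence[i]) &&
          parsed$sequence != tab$sequence[i]) {
        return(sprintf("row %d: sequence does not match id '%s'", i, id))
      }
      NULL
    })
    bad <- purrr::compact(bad)
    if (length(bad)) {
      abort(paste(c("Measurements failed validation:",
                    unlist(bad)), collapse = "\n  "),
            class = "chimeraGP_io_error")
    }
  }
  tab
}

#' @rdname read_measurements
#' @param measurements Measurements tibble (e.g. from
#'   [simulate_landscape()]).
#' @export
write_measurements <- function(measurements, path) {
  out <- measurements
  for (cc in grep("_(mean|std)$", names(out), value = TRUE)) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), "ND",
                        formatC(out[[cc]], format = "g", digits = 15))
  }
  out <- out[, setdiff(names(out), grep("_nd$", names(out), value = TRUE))]
  readr::write_csv(out, path)
  invisible(path)
}

#' Export the feature index as TSV
#'
#' Makes model weights interpretable outside R: each feature column with
#' its type, position(s), residue(s) and carrier parents.
#'
#' @param encoding A [build_encoding()].
#' @param path Output TSV path.
#' @export
write_feature_index <- function(encoding, path) {
  readr::write_tsv(encoding$index, path)
  invisible(path)
}

#' Serialize a fitted model's configuration as JSON
#'
#' Stores kernel form and hyperparameters, the noise variance (regression),
#' link (classification), seed, and training dimensions — enough to log and
#' reproduce a fit, not the training data itself.
#'
#' @param model A `gp_regression` or `gp_classifier`.
#' @param path Output JSON path.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    class = class(model)[1],
    kernel = list(form = model$spec$form,
                  log_variance = log(model$spec$variance),
                  log_lengthscale = if (!is.null(model$spec$lengthscale))
                    log(model$spec$lengthscale),
                  feature_subset = model$spec$feature_subset),
    sigma_n2 = model$sigma_n2,
    link = model$link,
    n_train = model$n,
    log_marginal_likelihood = model$lml,
    seed = model$seed
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' A run configuration collects the file paths (parents, designs, contacts,
#' measurements), the modeled property, kernel settings, thresholds and the
#' seed used by the command-line interface.
#'
#' @param path YAML path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(property = "localization", kernel = "auto",
                   prob_explore = 0.4, prob_summary = 0.5,
                   kappa = 1, top_fraction = 0.001, seed = 0)
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @param config Named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

property_column <- function(property) {
  switch(property,
         expression = "mKate_mean",
         localization = "GFP_mean",
         localization_efficiency = "intensity_ratio_mean",
         abort(sprintf("Unknown property '%s'.", property),
               class = "chimeraGP_error"))
}
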