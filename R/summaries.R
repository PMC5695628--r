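#' Per-set descriptive summary of a chimera measurement campaign
#'
#' For each chimera set (parents, single-block swaps, multi-block swaps,
#' exploration, verification, optimization, ...) reports the count, the
#' mean ± sd of mutations from the nearest parent, the percentage of
#' chimeras with 'good' performance (at or above the lowest-performing
#' parent, see [make_labels()]) and the mean ± sd of the measured property.
#'
#' @param measurements Measurements tibble (with `set`, `n_mutations` and
#'   the property column).
#' @param property Property column to summarize (default `"GFP_mean"`,
#'   plasma-membrane localization).
#' @param parent_names Parent row names for the class threshold.
#' @return A tibble with one row per set.
#' @export
table1_summary <- function(measurements, property = "GFP_mean",
                           parent_names) {
  lab <- make_labels(measurements, property, parent_names)
  lab$data |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      count = dplyr::n(),
      mutations_mean = mean(.data$n_mutations),
      mutations_sd = sd(.data$n_mutations),
      pct_good = 100 * mean(.data$.label == "high"),
      property_mean = mean(.data[[property]], na.rm = TRUE),
      property_sd = sd(.data[[property]], na.rm = TRUE),
      .groups = "drop"
    )
}
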