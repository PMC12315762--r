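# broom-style tidiers for the fitted result objects.

#' Tidy a decoding result
#'
#' @param x a `decoding_result` tibble.
#' @param ... unused.
#' @return A plain tibble, one row per subject x parcel x target cell.
#' @export
tidy.decoding_result <- function(x, ...) as_tibble(x)

#' One-row summary of a decoding result
#'
#' @param x a `decoding_result` tibble.
#' @param ... unused.
#' @return A tibble with cohort size, parcel count, median performance and
#'   the fraction of non-missing cells, per target.
#' @export
glance.decoding_result <- function(x, ...) {
  x |>
    group_by(.data$target) |>
    summarise(n_subjects = dplyr::n_distinct(.data$subject_id),
              n_rois = dplyr::n_distinct(.data$roi_id),
              median_r = stats::median(.data$r_aggregated, na.rm = TRUE),
              prop_cells_ok = mean(!.data$missing),
              .groups = "drop")
}

#' Tidy a significance ledger
#'
#' @param x a `significance_ledger`.
#' @param ... unused.
#' @return Long tibble: one row per cell and correction level.
#' @export
tidy.significance_ledger <- function(x, ...) {
  x |>
    as_tibble() |>
    select(-any_of("level")) |>
    pivot_longer(all_of(paste0("sig_", ledger_levels)), names_to = "level",
                 names_prefix = "sig_", values_to = "significant") |>
    mutate(level = factor(.data$level, levels = ledger_levels))
}

#' One-row-per-level summary of a significance ledger
#'
#' @param x a `significance_ledger`.
#' @param ... unused.
#' @return Tibble per target and level: number and percentage of significant
#'   cells.
#' @export
glance.significance_ledger <- function(x, ...) {
  tidy.significance_ledger(x) |>
    group_by(.data$target, .data$level) |>
    summarise(n_significant = sum(.data$significant),
              pct_cells = 100 * mean(.data$significant), .groups = "drop")
}

#' Tidy a sufficiency curve
#'
#' @param x a `sufficiency_curve`.
#' @param ... unused.
#' @return The curve as a plain tibble.
#' @export
tidy.sufficiency_curve <- function(x, ...) as_tibble(x)

#' One-row summary of a sufficiency curve
#'
#' @param x a `sufficiency_curve`.
#' @param ... unused.
#' @return Tibble with the two optimal fractions and the performance range.
#' @export
glance.sufficiency_curve <- function(x, ...) {
  opt <- optimal_fractions(x)
  tibble(min_variance_fraction = opt$min_variance_fraction,
         max_gap_fraction = opt$max_gap_fraction,
         max_mean_perf = max(x$mean_perf, na.rm = TRUE),
         min_sd_perf = min(x$sd_perf, na.rm = TRUE))
}
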