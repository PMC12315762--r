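# Opposite-sign brain-behavior relationships: parcels where at least one
# subject decodes significantly with a positive activation-behavior slope and
# at least one other with a negative slope.

#' Per-parcel counts of significantly positive / negative subjects
#'
#' Counts, at one correction level of the ledger, how many subjects decode
#' the target significantly with positive and with negative fitted slope
#' (cell direction; exact-zero directions count in neither group).
#'
#' @param results a `decoding_result` tibble (source of `direction`).
#' @param ledger a `significance_ledger` aligned with `results`.
#' @param level one of `"uncorrected"`, `"by_subjects"`, `"by_rois"`,
#'   `"by_cells"`.
#' @return Tibble per parcel and target: `n_pos`, `n_neg`.
#' @export
sign_counts <- function(results, ledger, level = "uncorrected") {
  level <- match.arg(level, ledger_levels)
  sig_col <- paste0("sig_", level)
  results |>
    select("subject_id", "roi_id", "target", "direction") |>
    inner_join(ledger |> as_tibble() |>
                 select("subject_id", "roi_id", "target", all_of(sig_col)),
               by = c("subject_id", "roi_id", "target")) |>
    group_by(.data$roi_id, .data$target) |>
    summarise(
      n_pos = sum(.data[[sig_col]] & !is.na(.data$direction) &
                    .data$direction > 0),
      n_neg = sum(.data[[sig_col]] & !is.na(.data$direction) &
                    .data$direction < 0),
      .groups = "drop")
}

#' Detect parcels with opposite-sign brain-behavior relationships
#'
#' A parcel is divergent at a correction level when at least one subject
#' decodes significantly with a positive slope and at least one with a
#' negative slope. Computed at all four ledger levels; divergent sets are
#' nested (stricter level implies looser). With an atlas, also reports the
#' percentage of each network's parcels that are divergent (network sizes as
#' denominators).
#'
#' @param results a `decoding_result` tibble.
#' @param ledger a `significance_ledger`.
#' @param atlas optional atlas tibble for the network breakdown.
#' @return A `divergence_result` list: `counts` (per target/level/parcel,
#'   `n_pos`, `n_neg`, `divergent`), `summary` (per target/level,
#'   `pct_rois_divergent`), and `by_network` (per target/level/network,
#'   `pct_divergent`; `NULL` without an atlas).
#' @export
divergent_rois <- function(results, ledger, atlas = NULL) {
  counts <- map(ledger_levels, function(lv) {
    sign_counts(results, ledger, lv) |>
      mutate(level = lv, divergent = .data$n_pos >= 1 & .data$n_neg >= 1)
  }) |>
    bind_rows() |>
    mutate(level = factor(.data$level, levels = ledger_levels))

  summary <- counts |>
    group_by(.data$target, .data$level) |>
    summarise(n_rois = dplyr::n(),
              n_divergent = sum(.data$divergent),
              pct_rois_divergent = 100 * mean(.data$divergent),
              .groups = "drop")

  by_network <- NULL
  if (!is.null(atlas)) {
    by_network <- counts |>
      inner_join(atlas |> select("roi_id", "network"), by = "roi_id") |>
      group_by(.data$target, .data$level, .data$network) |>
      summarise(n_rois = dplyr::n(),
                pct_divergent = 100 * mean(.data$divergent),
                .groups = "drop")
  }

  structure(list(counts = counts, summary = summary, by_network = by_network),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("<divergence_result> % of ROIs with opposite-sign significant subjects:\n")
  print(pivot_wider(x$summary |>
                      select("target", "level", "pct_rois_divergent"),
                    names_from = "level", values_from = "pct_rois_divergent"))
  invisible(x)
}
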