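# Writing and re-reading result matrices and the coverage summary.

# Format numeric columns as full-precision decimal strings so the text
# round-trip is exact (write_tsv's shortest-representation formatting can
# lose the final bit).
write_matrix_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

result_matrix <- function(results, value_col, target) {
  results |>
    filter(.data$target == !!target) |>
    arrange(.data$roi_id) |>
    select("subject_id", "roi_id", all_of(value_col)) |>
    pivot_wider(names_from = "roi_id", values_from = all_of(value_col),
                names_prefix = "roi_", names_sort = FALSE) |>
    arrange(.data$subject_id)
}

#' Write the per-cell result tables and coverage summary
#'
#' Writes, per target: a subject x parcel matrix of aggregated decoding
#' performance (`performance_<target>.tsv`), of permutation p-values
#' (`pvalues_<target>.tsv`), and of the most conservative significance level
#' passed (`levels_<target>.tsv`; integer 0 = not significant .. 4 = passes
#' the strictest correction), plus one JSON coverage summary
#' (`coverage.json`). Columns are ordered by ascending parcel id; missing
#' cells are written as empty fields; numeric values round-trip at full
#' precision.
#'
#' @param results a `decoding_result` tibble.
#' @param ledger the matching `significance_ledger`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_result_tables <- function(results, ledger, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(paste0("cannot create output directory: ", out_dir),
          class = "decodr_io_error")
  res <- results |>
    mutate(r_aggregated = ifelse(.data$missing, NA_real_, .data$r_aggregated),
           p_perm = ifelse(.data$missing, NA_real_, .data$p_perm))
  lev <- ledger |> as_tibble()
  if ("missing" %in% names(lev))
    lev <- lev |> mutate(level = ifelse(.data$missing, NA_integer_,
                                        .data$level))

  files <- character(0)
  for (tg in unique(res$target)) {
    f1 <- file.path(out_dir, paste0("performance_", tg, ".tsv"))
    f2 <- file.path(out_dir, paste0("pvalues_", tg, ".tsv"))
    f3 <- file.path(out_dir, paste0("levels_", tg, ".tsv"))
    write_matrix_tsv(result_matrix(res, "r_aggregated", tg), f1)
    write_matrix_tsv(result_matrix(res, "p_perm", tg), f2)
    write_matrix_tsv(result_matrix(lev, "level", tg), f3)
    files <- c(files, f1, f2, f3)
  }
  cov <- summarize_coverage(ledger)
  f4 <- file.path(out_dir, "coverage.json")
  jsonlite::write_json(
    list(alpha = attr(ledger, "alpha"),
         correction_factors = as.list(attr(ledger, "factors")),
         rois_any_subject = cov$rois_any_subject,
         subjects_per_roi = cov$subjects_per_roi,
         rois_per_subject = cov$rois_per_subject),
    f4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, f4))
}

#' Read back a result matrix written by [write_result_tables()]
#'
#' @param path a TSV written by [write_result_tables()].
#' @return Tibble with `subject_id` and one `roi_<id>` column per parcel.
#' @export
read_result_matrix <- function(path) {
  # parse doubles via as.numeric: exact for full-precision decimal strings
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  df[-1] <- lapply(df[-1], as.numeric)
  df
}
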