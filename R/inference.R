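# Multi-level Bonferroni significance ledger, group-level tests, coverage
# summaries, and the motion QC regression.

ledger_levels <- c("uncorrected", "by_subjects", "by_rois", "by_cells")

#' Build the multi-level Bonferroni significance ledger
#'
#' Evaluates every cell's permutation p-value at the base level `alpha` and
#' after Bonferroni correction for the number of subjects, the number of
#' parcels, and their product (e.g. 1, 50, 200, 10000 tests for a 50-subject,
#' 200-parcel cohort). A cell is significant at factor `k` iff
#' `p < alpha / k`; missing cells are not significant at any level. The four
#' levels are nested by construction. Note that a permutation p-value based
#' on `n_perm` permutations cannot fall below `1 / (n_perm + 1)`, so the
#' strictest level may be unreachable unless `p_col = "p_parametric"` is used.
#'
#' @param results a `decoding_result` tibble from [decode_all()].
#' @param alpha base significance level (default 0.05).
#' @param n_subjects,n_rois correction factors; default to the counts
#'   observed in `results`.
#' @param p_col which p-value column to threshold (`"p_perm"` default, or
#'   `"p_parametric"`).
#' @return A `significance_ledger` tibble: one row per cell with logical
#'   columns `sig_uncorrected`, `sig_by_subjects`, `sig_by_rois`,
#'   `sig_by_cells` and the integer `level` (0 = not significant, 4 = passes
#'   the strictest correction). Attributes `alpha` and `factors` record the
#'   thresholds.
#' @export
build_ledger <- function(results, alpha = 0.05, n_subjects = NULL,
                         n_rois = NULL, p_col = "p_perm") {
  n_subjects <- n_subjects %||% dplyr::n_distinct(results$subject_id)
  n_rois <- n_rois %||% dplyr::n_distinct(results$roi_id)
  factors <- c(1, n_subjects, n_rois, n_subjects * n_rois)
  p <- results[[p_col]]
  out <- results |>
    as_tibble() |>
    select(any_of(c("subject_id", "roi_id", "target", "direction",
                    "missing")), all_of(p_col))
  class(out) <- class(tibble())
  for (i in seq_along(factors)) {
    out[[paste0("sig_", ledger_levels[i])]] <-
      !is.na(p) & p < alpha / factors[i]
  }
  sig <- as.matrix(out[paste0("sig_", ledger_levels)])
  out$level <- as.integer(rowSums(sig))
  attr(out, "alpha") <- alpha
  attr(out, "factors") <- setNames(factors, ledger_levels)
  attr(out, "p_col") <- p_col
  class(out) <- c("significance_ledger", class(out))
  out
}

#' Group-level decoding test per parcel
#'
#' Aggregates subject-level performance on the Fisher-z scale (mean of
#' subjects' `z_aggregated`, reported back as r) and tests it against zero
#' with a one-tailed one-sample t-test, Bonferroni-corrected for the number
#' of parcels. Parcels with fewer than 3 contributing subjects are flagged
#' untestable; zero-variance parcels (all subjects identical) are flagged
#' degenerate rather than dropped.
#'
#' @param results a `decoding_result` tibble.
#' @param alpha base level (default 0.05).
#' @param n_rois Bonferroni factor; defaults to the number of parcels in
#'   `results`.
#' @return A `group_result` tibble: per parcel and target, `n_subjects`,
#'   `r_group`, `t`, `p` (one-tailed), `significant` (at `alpha / n_rois`),
#'   `degenerate`, `untestable`.
#' @export
group_decode <- function(results, alpha = 0.05, n_rois = NULL) {
  n_rois <- n_rois %||% dplyr::n_distinct(results$roi_id)
  out <- results |>
    filter(!.data$missing) |>
    group_by(.data$roi_id, .data$target) |>
    summarise(
      n_subjects = sum(!is.na(.data$z_aggregated)),
      mean_z = mean(.data$z_aggregated, na.rm = TRUE),
      sd_z = sd(.data$z_aggregated, na.rm = TRUE),
      .groups = "drop") |>
    mutate(
      untestable = .data$n_subjects < 3,
      degenerate = !.data$untestable & .data$sd_z == 0,
      r_group = tanh(.data$mean_z),
      t = ifelse(.data$untestable | .data$degenerate, NA_real_,
                 .data$mean_z / (.data$sd_z / sqrt(.data$n_subjects))),
      p = pt(.data$t, df = .data$n_subjects - 1, lower.tail = FALSE),
      significant = !is.na(.data$p) & .data$p < alpha / n_rois) |>
    select("roi_id", "target", "n_subjects", "r_group", "t", "p",
           "significant", "degenerate", "untestable")
  attr(out, "alpha") <- alpha
  attr(out, "n_rois") <- n_rois
  class(out) <- c("group_result", class(out))
  out
}

#' Coverage percentages across correction levels
#'
#' Summarizes a [build_ledger()] three ways, per target and correction level:
#' the percentage of parcels decodable in at least one subject
#' (`rois_any_subject`), the percentage of subjects per parcel
#' (`subjects_per_roi`), and the percentage of parcels per subject
#' (`rois_per_subject`). All three are non-increasing from the uncorrected
#' to the strictest level.
#'
#' @param ledger a `significance_ledger`.
#' @return A `coverage_summary` list of three tibbles, plus the levels used.
#' @export
summarize_coverage <- function(ledger) {
  long <- ledger |>
    as_tibble() |>
    select(-any_of("level")) |>
    pivot_longer(all_of(paste0("sig_", ledger_levels)),
                 names_to = "level", names_prefix = "sig_",
                 values_to = "significant") |>
    mutate(level = factor(.data$level, levels = ledger_levels))

  rois_any <- long |>
    group_by(.data$target, .data$level, .data$roi_id) |>
    summarise(any_sig = any(.data$significant), .groups = "drop") |>
    group_by(.data$target, .data$level) |>
    summarise(pct = 100 * mean(.data$any_sig), .groups = "drop")

  subj_per_roi <- long |>
    group_by(.data$target, .data$level, .data$roi_id) |>
    summarise(pct = 100 * mean(.data$significant), .groups = "drop")

  roi_per_subj <- long |>
    group_by(.data$target, .data$level, .data$subject_id) |>
    summarise(pct = 100 * mean(.data$significant), .groups = "drop")

  structure(list(rois_any_subject = rois_any,
                 subjects_per_roi = subj_per_roi,
                 rois_per_subject = roi_per_subj,
                 levels = ledger_levels),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat("<coverage_summary>\n% of ROIs decodable in >= 1 subject:\n")
  print(pivot_wider(x$rois_any_subject, names_from = "level",
                    values_from = "pct"))
  invisible(x)
}

#' Motion QC: does head motion predict decoding performance?
#'
#' Regresses each subject's average decoding performance (mean of
#' `z_aggregated` across parcels, per target) on the subject's mean frame
#' displacement, reporting R-squared and the two-tailed p-value. On
#' simulated cohorts motion is independent of the planted couplings, so this
#' check is null by construction.
#'
#' @param cohort named list of `subject_data` (source of `mean_fd`).
#' @param results a `decoding_result` tibble.
#' @return Tibble per target: `r_squared`, `p`, `slope`, `n_subjects`,
#'   `degenerate` (TRUE when motion has zero variance).
#' @export
fd_qc <- function(cohort, results) {
  fd <- tibble(subject_id = vapply(cohort, subject_id, character(1)),
               mean_fd = vapply(cohort, mean_fd, numeric(1)))
  perf <- results |>
    filter(!.data$missing) |>
    group_by(.data$subject_id, .data$target) |>
    summarise(perf = mean(.data$z_aggregated, na.rm = TRUE), .groups = "drop") |>
    inner_join(fd, by = "subject_id")
  perf |>
    group_by(.data$target) |>
    group_modify(function(d, key) {
      if (nrow(d) < 3 || is.na(var(d$mean_fd)) || var(d$mean_fd) == 0)
        return(tibble(r_squared = NA_real_, p = NA_real_, slope = NA_real_,
                      n_subjects = nrow(d), degenerate = TRUE))
      fit <- lm(perf ~ mean_fd, data = d)
      s <- summary(fit)
      tibble(r_squared = s$r.squared, p = s$coefficients["mean_fd", 4],
             slope = coef(fit)[["mean_fd"]], n_subjects = nrow(d),
             degenerate = FALSE)
    }) |>
    ungroup()
}
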