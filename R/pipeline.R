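# End-to-end pipeline: simulate -> decode -> ledger/group -> sufficiency ->
# divergence -> report.

#' Pipeline run configuration
#'
#' Presets mirror the two study designs the pipeline targets plus a tiny
#' smoke-test configuration:
#' * `"dataset1"`: 50 subjects, 700 trials, 200 parcels, 350/350 splits for
#'   both targets, correction factors (1, 50, 200, 10000);
#' * `"dataset2"`: 36 subjects, 804 trials, 402/402 splits for RT, 301/101
#'   for confidence (ratings on only half the trials), factors
#'   (1, 36, 200, 7200);
#' * `"tiny"`: 4 subjects, 60 trials, 10 parcels, 50 permutations - a
#'   seconds-scale end-to-end run.
#'
#' @param preset one of `"dataset1"`, `"dataset2"`, `"tiny"`.
#' @param seed master seed; all stage seeds derive from it.
#' @param stages stages to run, in dependency order. `"report"` writes the
#'   result tables and a summary JSON.
#' @param ... overrides for any config element (e.g. `n_perm`, `synthetic`,
#'   `splits`, `sufficiency_fractions`).
#' @return A `run_config` list.
#' @export
run_config <- function(preset = c("tiny", "dataset1", "dataset2"), seed = 1,
                       stages = c("simulate", "decode", "group",
                                  "sufficiency", "divergence", "report"),
                       ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    dataset1 = list(
      synthetic = synthetic_config(n_subjects = 50, n_trials = 700,
                                   n_rois = 200, seed = seed),
      splits = list(rt = c(350, 350), confidence = c(350, 350)),
      n_repeats = 25, n_perm = 1000, n_null_repeats = 5,
      sufficiency_fractions = seq(0.05, 0.95, by = 0.05),
      sufficiency_repeats = 25),
    dataset2 = list(
      synthetic = synthetic_config(n_subjects = 36, n_trials = 804,
                                   n_rois = 200,
                                   confidence_missing_fraction = 0.5,
                                   seed = seed),
      splits = list(rt = c(402, 402), confidence = c(301, 101)),
      n_repeats = 25, n_perm = 1000, n_null_repeats = 5,
      sufficiency_fractions = seq(0.05, 0.95, by = 0.05),
      sufficiency_repeats = 25),
    tiny = list(
      synthetic = synthetic_config(n_subjects = 4, n_trials = 60,
                                   n_rois = 10, coupling_sparsity = 0.5,
                                   coupling_magnitude = 0.4, seed = seed),
      splits = list(rt = c(30, 30), confidence = c(30, 30)),
      n_repeats = 5, n_perm = 50, n_null_repeats = 2,
      sufficiency_fractions = c(0.25, 0.5, 0.75),
      sufficiency_repeats = 5)
  )
  cfg <- utils::modifyList(
    c(base, list(preset = preset, seed = as.integer(seed), stages = stages,
                 targets = c("rt", "confidence"), alpha = 0.05,
                 regressor = "ols", log_rt = FALSE)),
    list(...))
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated cohort:
#' cohort generation, per-cell decoding with permutation nulls, the
#' significance ledger and group-level tests, the trial-number sufficiency
#' sweep, the opposite-sign analysis, the motion QC check, and a report
#' (result tables plus `summary.json`). Every artifact is reproducible from
#' `(config, seed)`; the summary JSON contains no timestamps so identical
#' runs are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for report files (required when `"report"`
#'   is among the stages).
#' @return A manifest list: `config` echo, `paths` of written files,
#'   per-stage `timings` (seconds), and the in-memory stage results
#'   (`cohort`, `truth`, `results`, `ledger`, `group`, `coverage`,
#'   `sufficiency`, `divergence`, `fd_qc`, `summary`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  need <- function(stage, deps) {
    missing <- setdiff(deps, stages)
    if (stage %in% stages && length(missing) > 0)
      abort(sprintf("stage '%s' requires stage(s): %s", stage,
                    paste(missing, collapse = ", ")),
            class = "decodr_dependency_error")
  }
  need("decode", "simulate")
  need("group", c("simulate", "decode"))
  need("divergence", c("simulate", "decode"))
  need("sufficiency", "simulate")
  need("report", c("simulate", "decode"))

  manifest <- list(config = unclass(config), paths = character(0),
                   timings = list())
  out <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }

  if ("simulate" %in% stages) {
    sim <- tick("simulate", simulate_cohort(config$synthetic))
    out$cohort <- sim$cohort
    out$truth <- sim$truth
    out$atlas <- sim$atlas
  }
  if ("decode" %in% stages) {
    out$results <- tick("decode", decode_all(
      out$cohort, out$atlas, targets = config$targets,
      splits = config$splits, n_repeats = config$n_repeats,
      n_perm = config$n_perm, n_null_repeats = config$n_null_repeats,
      regressor = if (config$regressor == "svr") regressor_svr() else
        regressor_ols(),
      log_rt = config$log_rt, seed = derive_seed(config$seed, "decode")))
    out$ledger <- build_ledger(out$results, alpha = config$alpha)
    out$coverage <- summarize_coverage(out$ledger)
  }
  if ("group" %in% stages)
    out$group <- tick("group", group_decode(out$results, alpha = config$alpha))
  if ("sufficiency" %in% stages) {
    sspec <- sufficiency_spec(fractions = config$sufficiency_fractions,
                              n_repeats = config$sufficiency_repeats,
                              seed = derive_seed(config$seed, "sufficiency"))
    out$sufficiency <- tick("sufficiency", map(
      setNames(config$targets, config$targets),
      function(tg) sufficiency_curve(out$cohort, tg, sspec,
                                     log_rt = config$log_rt)))
  }
  if ("divergence" %in% stages)
    out$divergence <- tick("divergence",
                           divergent_rois(out$results, out$ledger, out$atlas))
  if ("decode" %in% stages)
    out$fd_qc <- fd_qc(out$cohort, out$results)

  if ("report" %in% stages) {
    if (is.null(out_dir))
      abort("stage 'report' needs an out_dir", class = "decodr_io_error")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$paths <- tick("report",
                           write_result_tables(out$results, out$ledger,
                                               out_dir))
    summary <- list(
      preset = config$preset, seed = config$seed,
      n_subjects = length(out$cohort),
      n_rois = dplyr::n_distinct(out$results$roi_id),
      coverage_rois_any_subject = out$coverage$rois_any_subject,
      group_significant = if (!is.null(out$group)) out$group |>
        group_by(.data$target) |>
        summarise(pct_rois = 100 * mean(.data$significant),
                  .groups = "drop"),
      divergence = if (!is.null(out$divergence)) out$divergence$summary,
      sufficiency_optima = if (!is.null(out$sufficiency))
        map(out$sufficiency, optimal_fractions),
      fd_qc = out$fd_qc)
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest$paths <- c(manifest$paths, f)
    out$summary <- summary
  }
  c(manifest, out)
}
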