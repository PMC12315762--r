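# Small cohorts and synthetic result tables built in code.

tiny_sim <- function(n_subjects = 3, n_trials = 40, n_rois = 4, seed = 11,
                     ...) {
  simulate_cohort(synthetic_config(n_subjects = n_subjects,
                                   n_trials = n_trials, n_rois = n_rois,
                                   seed = seed, ...))
}

# A decoding_result-shaped tibble with arbitrary p-values/directions, for
# ledger/coverage/divergence property tests that do not need real decoding.
random_results <- function(n_subjects, n_rois, seed,
                           targets = c("rt", "confidence")) {
  withr::with_seed(seed, {
    g <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                     roi_id = seq_len(n_rois), target = targets,
                     stringsAsFactors = FALSE)
    tibble::as_tibble(g) |>
      dplyr::mutate(
        n_used = 100L,
        z_aggregated = rnorm(dplyr::n(), sd = 0.3),
        r_aggregated = tanh(z_aggregated),
        mean_slope = rnorm(dplyr::n()),
        direction = sign(mean_slope),
        p_perm = runif(dplyr::n())^2,  # skewed so some survive correction
        p_parametric = p_perm,
        missing = FALSE, reason = NA_character_)
  })
}

write_toy_subject_file <- function(path, rt = c(0.5, 0.7, 0.9, 1.1),
                                   confidence = c(1L, 2L, NA, 4L),
                                   n_rois = 3, seed = 1) {
  n <- length(rt)
  betas <- withr::with_seed(seed, matrix(rnorm(n * n_rois), n))
  colnames(betas) <- paste0("roi_", seq_len(n_rois))
  df <- tibble::tibble(trial = seq_len(n), run = 1L, rt = rt,
                       confidence = confidence) |>
    dplyr::bind_cols(tibble::as_tibble(betas))
  readr::write_tsv(df, path, na = "")
  path
}
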