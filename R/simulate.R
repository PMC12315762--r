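# Synthetic cohort generator with planted, analytically checkable couplings
# between parcel activation and trial-level behavior.
#
# Generative model, per subject s and trial t:
#   z_rt[t], z_conf[t] ~ N(0,1) independent latents
#   rt[t]         = exp(rt_meanlog + rt_sdlog * z_rt[t])          (seconds)
#   confidence[t] = equal-probability ordinal bin of z_conf[t]    (1..K)
#   beta[t, r]    = a_rt[s,r] z_rt[t] + a_conf[s,r] z_conf[t]
#                   + shared_noise_sd * f[t] + idiosyncratic_noise_sd * e[t,r]
# with f, e iid N(0,1). Raw loadings a are scaled so that the planted
# standardized coupling rho equals the population correlation between
# beta[,r] and the target latent exactly:
#   a_i = rho_i * sqrt(V),  V = (shared^2 + idio^2) / (1 - rho_rt^2 - rho_conf^2).
# On the observed behavior scale the correlation is attenuated by a known
# closed-form factor (see expected_correlation), which tests assert against.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the first study cohort the pipeline targets: 50 subjects,
#' 700 trials in 6 runs, 200 parcels, log-normal reaction times with a median
#' of 1 s, and a 4-point confidence scale. Couplings are planted per subject
#' x parcel cell: a parcel is eligible for coupling with probability
#' `coupled_roi_fraction` (cohort-level gate); within an eligible parcel each
#' subject x target cell is coupled with probability `coupling_sparsity`,
#' with standardized magnitude `coupling_magnitude` and positive sign with
#' probability `sign_mixture` - so different subjects can carry opposite
#' signs in the same parcel.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject.
#' @param n_rois number of parcels.
#' @param coupling_sparsity probability a subject x parcel cell is coupled
#'   (within parcels passing the `coupled_roi_fraction` gate).
#' @param coupling_magnitude standardized coupling `|rho|` in `[0, 1)`: the
#'   planted population correlation between parcel activation and the
#'   target's latent.
#' @param sign_mixture probability a coupled cell's slope is positive,
#'   sampled independently per subject and parcel.
#' @param coupled_roi_fraction probability a parcel carries any coupling at
#'   all (shared across subjects), so cohorts can contain parcels that are
#'   uncoupled for everyone.
#' @param shared_noise_sd sd of a per-trial factor added to every parcel
#'   (shared physiological/scanner noise).
#' @param idiosyncratic_noise_sd per-cell noise sd.
#' @param rt_meanlog,rt_sdlog location and scale of the log-normal reaction
#'   time distribution (log-seconds).
#' @param confidence_levels number of ordinal confidence levels.
#' @param confidence_missing_fraction fraction of trials without a confidence
#'   rating; applied to the earliest trials/runs, mirroring designs where
#'   confidence is collected only in later runs.
#' @param targets which behavioral targets receive couplings; both by
#'   default, each through its own independent latent.
#' @param n_runs number of runs trials are split across.
#' @param n_trials_per_subject optional integer vector of per-subject trial
#'   counts overriding `n_trials` (emulating subjects who stopped early).
#' @param seed master seed; the cohort is bitwise reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 50, n_trials = 700, n_rois = 200,
                             coupling_sparsity = 0.2, coupling_magnitude = 0.3,
                             sign_mixture = 0.5, coupled_roi_fraction = 1,
                             shared_noise_sd = 0.5, idiosyncratic_noise_sd = 1,
                             rt_meanlog = 0, rt_sdlog = 0.25,
                             confidence_levels = 4,
                             confidence_missing_fraction = 0,
                             targets = c("rt", "confidence"),
                             n_runs = 6, n_trials_per_subject = NULL,
                             seed = 1) {
  targets <- match.arg(targets, c("rt", "confidence"), several.ok = TRUE)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    n_rois = as.integer(n_rois), coupling_sparsity = coupling_sparsity,
    coupling_magnitude = coupling_magnitude, sign_mixture = sign_mixture,
    coupled_roi_fraction = coupled_roi_fraction,
    shared_noise_sd = shared_noise_sd,
    idiosyncratic_noise_sd = idiosyncratic_noise_sd,
    rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
    confidence_levels = as.integer(confidence_levels),
    confidence_missing_fraction = confidence_missing_fraction,
    targets = targets, n_runs = as.integer(n_runs),
    n_trials_per_subject = if (!is.null(n_trials_per_subject))
      as.integer(n_trials_per_subject),
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  probs <- c("coupling_sparsity", "sign_mixture", "coupled_roi_fraction",
             "confidence_missing_fraction")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      abort(paste0(p, " must be in [0, 1]"), class = "decodr_validation_error")
  if (cfg$coupling_magnitude < 0 || cfg$coupling_magnitude >= 1)
    abort("coupling_magnitude must be in [0, 1)",
          class = "decodr_validation_error")
  if (cfg$shared_noise_sd < 0 || cfg$idiosyncratic_noise_sd < 0)
    abort("noise sds must be >= 0", class = "decodr_validation_error")
  if (cfg$n_trials < 4)
    abort("n_trials must be >= 4", class = "decodr_validation_error")
  if (!is.null(cfg$n_trials_per_subject)) {
    if (length(cfg$n_trials_per_subject) != cfg$n_subjects)
      abort("n_trials_per_subject must have one entry per subject",
            class = "decodr_validation_error")
    if (any(cfg$n_trials_per_subject < 4))
      abort("every subject needs >= 4 trials", class = "decodr_validation_error")
  }
  n2 <- cfg$shared_noise_sd^2 + cfg$idiosyncratic_noise_sd^2
  k <- length(cfg$targets) * cfg$coupling_magnitude^2
  if (n2 > 0 && k >= 1)
    abort("coupling_magnitude too large: sum of squared couplings must be < 1",
          class = "decodr_validation_error")
  invisible(cfg)
}

#' Simulate a cohort with planted couplings
#'
#' Generates one trial table per subject plus the planted truth. Per-subject
#' mean frame displacement is drawn independently of all couplings, so any
#' motion/performance association in the output is a false positive by
#' construction.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `cohort` (named list of `subject_data`
#'   tibbles), `truth` (tibble `subject_id`, `roi_id`, `target`, `coupling`
#'   of planted standardized slopes, 0 where uncoupled; class
#'   `synthetic_truth`), and `atlas` (a [synthetic_atlas()]).
#' @export
#' @examples
#' sim <- simulate_cohort(synthetic_config(n_subjects = 2, n_trials = 40,
#'                                         n_rois = 5, seed = 7))
#' names(sim$cohort)
simulate_cohort <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    sids <- sprintf("sub%03d", seq_len(cfg$n_subjects))
    roi_gate <- runif(cfg$n_rois) < cfg$coupled_roi_fraction
    n2 <- cfg$shared_noise_sd^2 + cfg$idiosyncratic_noise_sd^2

    sample_coupling <- function() {
      coupled <- roi_gate & (runif(cfg$n_rois) < cfg$coupling_sparsity)
      sgn <- ifelse(runif(cfg$n_rois) < cfg$sign_mixture, 1, -1)
      ifelse(coupled, sgn * cfg$coupling_magnitude, 0)
    }

    truth_rows <- list()
    cohort <- vector("list", cfg$n_subjects)
    names(cohort) <- sids
    for (s in seq_len(cfg$n_subjects)) {
      n <- if (!is.null(cfg$n_trials_per_subject))
        cfg$n_trials_per_subject[s] else cfg$n_trials
      rho_rt <- if ("rt" %in% cfg$targets) sample_coupling() else
        rep(0, cfg$n_rois)
      rho_cf <- if ("confidence" %in% cfg$targets) sample_coupling() else
        rep(0, cfg$n_rois)

      # raw loadings per parcel (cell-specific variance normalization)
      if (n2 > 0) {
        V <- n2 / (1 - rho_rt^2 - rho_cf^2)
        a_rt <- rho_rt * sqrt(V)
        a_cf <- rho_cf * sqrt(V)
      } else {
        a_rt <- rho_rt
        a_cf <- rho_cf
      }

      z_rt <- rnorm(n)
      z_cf <- rnorm(n)
      f <- rnorm(n)
      betas <- tcrossprod(z_rt, a_rt) + tcrossprod(z_cf, a_cf) +
        cfg$shared_noise_sd * f +
        matrix(rnorm(n * cfg$n_rois, sd = cfg$idiosyncratic_noise_sd),
               n, cfg$n_rois)
      colnames(betas) <- paste0("roi_", seq_len(cfg$n_rois))

      rt <- exp(cfg$rt_meanlog + cfg$rt_sdlog * z_rt)
      qs <- qnorm(seq(0, 1, length.out = cfg$confidence_levels + 1))
      confidence <- as.integer(cut(z_cf, breaks = qs, labels = FALSE,
                                   include.lowest = TRUE))
      n_miss <- round(cfg$confidence_missing_fraction * n)
      if (n_miss > 0) confidence[seq_len(n_miss)] <- NA_integer_

      run <- rep(seq_len(cfg$n_runs), length.out = cfg$n_runs *
                   ceiling(n / cfg$n_runs))[seq_len(n)]
      run <- sort(run)
      fd <- rlnorm(1, meanlog = log(0.15), sdlog = 0.4)

      cohort[[s]] <- new_subject_data(
        tibble(trial = seq_len(n), run = as.integer(run), rt = rt,
               confidence = confidence) |> bind_cols(as_tibble(betas)),
        subject_id = sids[s], mean_fd = fd)

      truth_rows[[s]] <- tibble(
        subject_id = sids[s],
        roi_id = rep(seq_len(cfg$n_rois), 2L),
        target = rep(c("rt", "confidence"), each = cfg$n_rois),
        coupling = c(rho_rt, rho_cf))
    }
    truth <- bind_rows(truth_rows)
    class(truth) <- c("synthetic_truth", class(truth))
    attr(truth, "config") <- cfg
    list(cohort = cohort, truth = truth, atlas = synthetic_atlas(cfg$n_rois))
  })
}

#' Closed-form attenuation of the latent correlation on the observed scale
#'
#' The generator plants couplings as correlations with a standard-normal
#' latent. Observed behavior is a monotone transform of that latent
#' (exponential for RT, equal-probability binning for confidence), so the
#' population correlation between activation and *observed* behavior is the
#' planted value times a known factor:
#' * RT: `cor(Z, exp(s Z)) = s / sqrt(exp(s^2) - 1)` for log-scale `s`;
#' * confidence: `cor(Z, bin(Z))` with K equal-probability bins, computed
#'   from the normal density at the bin boundaries.
#'
#' @param config a [synthetic_config()].
#' @param target `"rt"` or `"confidence"`.
#' @param log_rt if `TRUE`, the RT attenuation is 1 (decoding log RT
#'   recovers the latent scale exactly).
#' @return Scalar attenuation factor in `(0, 1]`.
#' @export
attenuation_factor <- function(config, target = c("rt", "confidence"),
                               log_rt = FALSE) {
  target <- match.arg(target)
  if (target == "rt") {
    if (log_rt) return(1)
    s <- config$rt_sdlog
    if (s == 0) return(1)
    return(s / sqrt(exp(s^2) - 1))
  }
  K <- config$confidence_levels
  q <- qnorm(seq(0, 1, length.out = K + 1))
  phi <- dnorm(q)                      # dnorm(+-Inf) = 0
  cov_bz <- sum(seq_len(K) * (phi[-(K + 1)] - phi[-1]))
  var_b <- mean(seq_len(K)^2) - mean(seq_len(K))^2
  cov_bz / sqrt(var_b)
}

#' Expected observed-scale correlation for a planted coupling
#'
#' @param config a [synthetic_config()].
#' @param target `"rt"` or `"confidence"`.
#' @param coupling planted standardized coupling(s); defaults to the config's
#'   `coupling_magnitude`.
#' @param log_rt whether RT is decoded on the log scale.
#' @return Expected population Pearson correlation between parcel activation
#'   and observed behavior (vectorized over `coupling`).
#' @export
#' @examples
#' cfg <- synthetic_config(coupling_magnitude = 0.5)
#' expected_correlation(cfg, "rt")
expected_correlation <- function(config, target = c("rt", "confidence"),
                                 coupling = config$coupling_magnitude,
                                 log_rt = FALSE) {
  target <- match.arg(target)
  coupling * attenuation_factor(config, target, log_rt = log_rt)
}

#' Per-parcel counts of planted coupling signs
#'
#' @param truth the `truth` tibble from [simulate_cohort()].
#' @return Tibble with one row per parcel and target: `n_pos`, `n_neg`,
#'   `n_zero` counts of subjects, summing to the cohort size.
#' @export
truth_sign_table <- function(truth) {
  truth |>
    group_by(.data$roi_id, .data$target) |>
    summarise(n_pos = sum(.data$coupling > 0),
              n_neg = sum(.data$coupling < 0),
              n_zero = sum(.data$coupling == 0), .groups = "drop")
}
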