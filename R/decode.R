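# Per-parcel repeated random-split decoding of one behavioral target for one
# subject, with Fisher-aggregated Pearson performance and a permutation null.

#' Split specification for repeated random splits
#'
#' @param n_train,n_test absolute trial counts for the training and testing
#'   bins (e.g. 350/350 for a 700-trial session, 301/101 for the
#'   reduced-confidence variant).
#' @param n_repeats number of random splits whose performance is aggregated
#'   (default 25).
#' @param seed seed of the split-generation stream.
#' @return A `split_spec` list.
#' @export
split_spec <- function(n_train, n_test, n_repeats = 25, seed = 1) {
  stopifnot(n_train >= 3, n_test >= 3, n_repeats >= 1)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "split_spec")
}

#' Draw one train/test partition
#'
#' Disjoint index sets of sizes `n_train` and `n_test`, sampled without
#' replacement; deterministic given `(spec$seed, repeat_index)`. Trials
#' beyond `n_train + n_test` are left unused for that repeat.
#'
#' @param n_trials number of available trials.
#' @param spec a [split_spec()].
#' @param repeat_index 1-based repeat number.
#' @return List with integer vectors `train` and `test`.
#' @export
split_trials <- function(n_trials, spec, repeat_index) {
  k <- spec$n_train + spec$n_test
  if (k > n_trials)
    abort(sprintf("split needs %d trials but only %d are available",
                  k, n_trials), class = "decodr_sizing_error")
  idx <- with_seed(derive_seed(spec$seed, "split", repeat_index),
                   sample.int(n_trials, k))
  list(train = idx[seq_len(spec$n_train)],
       test = idx[spec$n_train + seq_len(spec$n_test)])
}

#' Fisher-mean aggregation of correlations
#'
#' Correlations are clipped to `1 - 1e-12` in magnitude (so perfect
#' correlations stay finite), Fisher-transformed with `atanh`, averaged over
#' non-missing entries, and mapped back with `tanh`.
#'
#' @param r_values vector of correlations in `[-1, 1]`, possibly with `NA`s.
#' @return List with `r` (aggregated correlation) and `z` (its Fisher
#'   transform); both `NA` if every entry is missing.
#' @export
#' @examples
#' fisher_aggregate(c(0.3, 0.6))
fisher_aggregate <- function(r_values) {
  r <- r_values[!is.na(r_values)]
  if (length(r) == 0) return(list(r = NA_real_, z = NA_real_))
  z <- mean(atanh(clip_r(r)))
  list(r = tanh(z), z = z)
}

# Core repeated-split decode on bare vectors. Returns per-repeat r and slope
# plus the Fisher aggregate.
decode_xy <- function(x, y, spec, regressor = regressor_ols()) {
  n <- length(x)
  r <- slope <- rep(NA_real_, spec$n_repeats)
  for (i in seq_len(spec$n_repeats)) {
    idx <- split_trials(n, spec, i)
    xtr <- x[idx$train]
    if (!is.finite(var(xtr)) || var(xtr) == 0) next
    model <- regressor$fit(xtr, y[idx$train])
    yhat <- regressor$predict(model, x[idx$test])
    if (length(yhat) != length(idx$test))
      abort("regressor contract violation: prediction length != test size",
            class = "decodr_contract_error")
    r[i] <- safe_cor(y[idx$test], yhat)
    slope[i] <- if (!is.null(model$slope)) model$slope else {
      xt <- x[idx$test]
      if (var(xt) > 0) stats::cov(xt, yhat) / var(xt) else NA_real_
    }
  }
  agg <- fisher_aggregate(r)
  structure(list(r_per_repeat = r, slope_per_repeat = slope,
                 r_aggregated = agg$r, z_aggregated = agg$z,
                 n_trials = n, spec = spec),
            class = "repeat_set")
}

#' Decode one subject x parcel x target cell
#'
#' Trials with a missing target value are dropped before splitting. For each
#' repeat, the regressor is fit on the training bin, predicts the testing
#' bin, and performance is the Pearson correlation between empirical and
#' predicted behavior; repeats are combined with [fisher_aggregate()].
#'
#' @param subject a `subject_data` tibble.
#' @param roi_id parcel id.
#' @param target `"rt"` or `"confidence"`.
#' @param spec a [split_spec()].
#' @param regressor a `decodr_regressor` (default [regressor_ols()]).
#' @param log_rt decode RT on the log scale (off by default; raw seconds).
#' @return A `repeat_set` list: `r_per_repeat`, `slope_per_repeat`,
#'   `r_aggregated`, `z_aggregated`.
#' @export
decode_cell <- function(subject, roi_id, target, spec,
                        regressor = regressor_ols(), log_rt = FALSE) {
  y <- target_vector(subject, target, log_rt = log_rt)
  x <- subject[[paste0("roi_", roi_id)]]
  if (is.null(x))
    abort(paste0("no such ROI column: roi_", roi_id),
          class = "decodr_format_error")
  keep <- !is.na(y) & !is.na(x)
  decode_xy(x[keep], y[keep], spec, regressor)
}

# Permutation null on bare vectors. Each permutation shuffles y once
# globally, then reruns the repeated-split decode with n_null_repeats fresh
# splits; shuffles and splits are drawn sequentially from one cell-level
# stream seeded from (spec$seed, "null"), so the null is deterministic per
# cell without reseeding inside the hot loop. For the OLS decoder the
# per-repeat performance is computed through the exact identity
# r(y, a + b x) = sign(b) * r(y, x); other regressors go through their
# fit/predict contract.
perm_null_xy <- function(x, y, spec, n_perm, n_null_repeats, obs_r,
                         regressor = regressor_ols()) {
  stopifnot(n_perm >= 1)
  n <- length(x)
  k <- spec$n_train + spec$n_test
  if (k > n)
    abort("split larger than available trials", class = "decodr_sizing_error")
  tr_i <- seq_len(spec$n_train)
  te_i <- spec$n_train + seq_len(spec$n_test)
  fast <- identical(regressor$label, "ols")
  null_r <- with_seed(derive_seed(spec$seed, "null"), {
    out <- rep(NA_real_, n_perm)
    for (p in seq_len(n_perm)) {
      yp <- y[sample.int(n)]
      rs <- rep(NA_real_, n_null_repeats)
      for (j in seq_len(n_null_repeats)) {
        idx <- sample.int(n, k)
        xtr <- x[idx[tr_i]]
        if (xtr[1L] == xtr[spec$n_train] && all(xtr == xtr[1L])) next
        if (fast) {
          ytr <- yp[idx[tr_i]]
          b <- sum(xtr * ytr) - sum(xtr) * sum(ytr) / spec$n_train
          xte <- x[idx[te_i]]
          yte <- yp[idx[te_i]]
          m <- spec$n_test
          vx <- sum(xte * xte) - sum(xte)^2 / m
          vy <- sum(yte * yte) - sum(yte)^2 / m
          rs[j] <- if (vx > 0 && vy > 0)
            sign(b) * (sum(xte * yte) - sum(xte) * sum(yte) / m) /
              sqrt(vx * vy) else NA_real_
        } else {
          model <- regressor$fit(xtr, yp[idx[tr_i]])
          yhat <- regressor$predict(model, x[idx[te_i]])
          rs[j] <- safe_cor(yp[idx[te_i]], yhat)
        }
      }
      out[p] <- fisher_aggregate(rs)$r
    }
    out
  })
  used <- !is.na(null_r)
  p_perm <- (1 + sum(null_r[used] >= obs_r)) / (1 + sum(used))
  list(p_perm = p_perm, null_r = null_r, n_perm_used = sum(used))
}

#' Permutation-null p-value for one cell
#'
#' One-tailed test of positive decoding: the target vector is shuffled across
#' trials (one global shuffle per permutation), the repeated-split decode is
#' rerun under the null policy (`n_null_repeats` fresh splits per
#' permutation, default 5), and the add-one estimator
#' `p = (1 + #\{null r >= observed r\}) / (1 + n_perm)` is returned, with ties
#' counting against significance. Note a permutation p-value cannot fall
#' below `1 / (n_perm + 1)`; see `p_parametric` in [decode_all()] for the
#' parametric alternative.
#'
#' @inheritParams decode_cell
#' @param n_perm number of permutations (default 1000).
#' @param n_null_repeats splits per permutation (default 5; raise to
#'   `spec$n_repeats` to mirror the observed statistic exactly at 5x cost).
#' @param observed optional precomputed `repeat_set` from [decode_cell()].
#' @return List with `p_perm`, `obs_r`, `null_r`, `n_perm_used`.
#' @export
permutation_null <- function(subject, roi_id, target, spec, n_perm = 1000,
                             n_null_repeats = 5, regressor = regressor_ols(),
                             log_rt = FALSE, observed = NULL) {
  obs <- observed %||%
    decode_cell(subject, roi_id, target, spec, regressor, log_rt = log_rt)
  y <- target_vector(subject, target, log_rt = log_rt)
  x <- subject[[paste0("roi_", roi_id)]]
  keep <- !is.na(y) & !is.na(x)
  out <- perm_null_xy(x[keep], y[keep], spec, n_perm, n_null_repeats,
                      obs$r_aggregated, regressor)
  out$obs_r <- obs$r_aggregated
  out
}

# Parametric one-tailed p from the aggregated correlation, treating it as a
# correlation over n_test trials (r -> t conversion).
parametric_p <- function(r, n_test) {
  if (is.na(r) || n_test < 4) return(NA_real_)
  r <- clip_r(r)
  t <- r * sqrt((n_test - 2) / (1 - r^2))
  pt(t, df = n_test - 2, lower.tail = FALSE)
}

#' Decode every subject x parcel x target cell of a cohort
#'
#' Runs [decode_cell()] and [permutation_null()] for each cell, with
#' cell-level seeds derived from the master seed, subject id, parcel id and
#' target, so results are reproducible and independent of scheduling. Cells
#' that cannot be decoded (too few usable trials, zero-variance activation)
#' are flagged missing, never aborting the cohort.
#'
#' @param cohort named list of `subject_data` tibbles.
#' @param atlas optional atlas tibble; defaults to all `roi_<id>` columns of
#'   the first subject.
#' @param targets behavioral targets to decode.
#' @param splits named list mapping each target to `c(n_train, n_test)`;
#'   `NULL` (default) uses a 50/50 split of each subject's usable trials.
#' @param n_repeats splits per cell (default 25).
#' @param n_perm permutations per cell (default 1000); `0` skips the
#'   permutation test.
#' @param n_null_repeats splits per permutation (default 5).
#' @param regressor a `decodr_regressor`.
#' @param log_rt decode RT on the log scale.
#' @param seed master seed.
#' @param progress print per-subject progress lines.
#' @return A `decoding_result` tibble with one row per cell: `subject_id`,
#'   `roi_id`, `target`, `n_used`, `r_aggregated`, `z_aggregated`,
#'   `mean_slope`, `direction` (sign of `mean_slope`), `p_perm`,
#'   `p_parametric`, `missing`, `reason`.
#' @export
decode_all <- function(cohort, atlas = NULL,
                       targets = c("rt", "confidence"), splits = NULL,
                       n_repeats = 25, n_perm = 1000, n_null_repeats = 5,
                       regressor = regressor_ols(), log_rt = FALSE,
                       seed = 1, progress = FALSE) {
  stopifnot(length(cohort) >= 1)
  targets <- match.arg(targets, c("rt", "confidence"), several.ok = TRUE)
  roi_ids <- if (!is.null(atlas)) atlas$roi_id else
    sort(as.integer(sub("^roi_", "", roi_columns(cohort[[1]]))))

  rows <- list()
  k <- 0L
  for (subject in cohort) {
    sid <- subject_id(subject)
    if (isTRUE(progress))
      message(sprintf("decoding %s (%d trials)", sid, nrow(subject)))
    for (target in targets) {
      y_all <- target_vector(subject, target, log_rt = log_rt)
      for (roi in roi_ids) {
        k <- k + 1L
        x_all <- subject[[paste0("roi_", roi)]]
        keep <- !is.na(y_all) & !is.na(x_all)
        n_used <- sum(keep)
        sp <- splits[[target]]
        if (is.null(sp)) sp <- c(floor(n_used / 2), ceiling(n_used / 2))
        cell_seed <- derive_seed(seed, sid, roi, target, "decode")
        row <- tibble(subject_id = sid, roi_id = as.integer(roi),
                      target = target, n_used = n_used,
                      n_train = as.integer(sp[1]), n_test = as.integer(sp[2]),
                      r_aggregated = NA_real_, z_aggregated = NA_real_,
                      mean_slope = NA_real_, direction = NA_real_,
                      p_perm = NA_real_, p_parametric = NA_real_,
                      missing = TRUE, reason = NA_character_)
        if (n_used < sp[1] + sp[2] || sp[1] < 3 || sp[2] < 3) {
          row$reason <- "too few usable trials"
          rows[[k]] <- row
          next
        }
        spec <- split_spec(sp[1], sp[2], n_repeats, seed = cell_seed)
        obs <- decode_xy(x_all[keep], y_all[keep], spec, regressor)
        if (is.na(obs$r_aggregated)) {
          row$reason <- "degenerate fit (zero-variance activation)"
          rows[[k]] <- row
          next
        }
        row$r_aggregated <- obs$r_aggregated
        row$z_aggregated <- obs$z_aggregated
        row$mean_slope <- mean(obs$slope_per_repeat, na.rm = TRUE)
        row$direction <- sign(row$mean_slope)
        row$p_parametric <- parametric_p(obs$r_aggregated, spec$n_test)
        if (n_perm > 0) {
          null <- perm_null_xy(x_all[keep], y_all[keep], spec, n_perm,
                               n_null_repeats, obs$r_aggregated, regressor)
          row$p_perm <- null$p_perm
        }
        row$missing <- FALSE
        rows[[k]] <- row
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "params") <- list(targets = targets, splits = splits,
                              n_repeats = n_repeats, n_perm = n_perm,
                              n_null_repeats = n_null_repeats,
                              regressor = regressor$label, log_rt = log_rt,
                              seed = seed)
  class(out) <- c("decoding_result", class(out))
  out
}
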