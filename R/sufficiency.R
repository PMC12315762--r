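# Trial-number sufficiency test: whole-brain multilinear decoding performance
# and its across-repeat variability as a function of the training fraction.

#' Specification for the sufficiency sweep
#'
#' @param fractions ordered grid of training fractions in `[0.05, 0.95]`
#'   (default 5% steps, 19 points).
#' @param n_repeats random splits per fraction (default 25).
#' @param test_policy `"complement"` tests on all remaining trials;
#'   `"fixed"` tests on a fixed number of held-out trials (`test_count`,
#'   default 5% of trials) so performance is comparable across training sizes.
#' @param test_count held-out trial count for the `"fixed"` policy.
#' @param standardize z-score predictors within the training bin (off by
#'   default; slopes stay in activation units).
#' @param seed seed of the split stream.
#' @return A `sufficiency_spec` list.
#' @export
sufficiency_spec <- function(fractions = seq(0.05, 0.95, by = 0.05),
                             n_repeats = 25,
                             test_policy = c("complement", "fixed"),
                             test_count = NULL, standardize = FALSE,
                             seed = 1) {
  test_policy <- match.arg(test_policy)
  stopifnot(all(diff(fractions) > 0), all(fractions > 0), all(fractions < 1),
            n_repeats >= 1)
  structure(list(fractions = fractions, n_repeats = as.integer(n_repeats),
                 test_policy = test_policy, test_count = test_count,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "sufficiency_spec")
}

#' Minimum-norm multilinear least squares
#'
#' Fits `y ~ 1 + X` by the minimum-norm least-squares solution (SVD
#' pseudoinverse), which is the ordinary solution when the design has full
#' column rank and the canonical deterministic choice when there are fewer
#' training trials than predictors (e.g. 35 trials, 200 parcels).
#'
#' @param X predictor matrix (trials x parcels).
#' @param y response vector.
#' @return Coefficient vector of length `ncol(X) + 1` (intercept first).
#' @export
fit_minnorm <- function(X, y) {
  A <- cbind(1, X)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  drop(sv$v[, pos, drop = FALSE] %*%
         (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos]))
}

predict_minnorm <- function(coefs, X) drop(cbind(1, X) %*% coefs)

#' Sufficiency curve: performance and variability vs training fraction
#'
#' For each training fraction and repeat, fits a whole-brain multilinear
#' model (all parcels jointly, minimum-norm least squares) on
#' `round(f * n_trials)` randomly chosen trials and scores the held-out
#' trials by the Pearson correlation between empirical and predicted
#' behavior. Per subject, the mean and standard deviation of performance
#' across repeats are computed; the curve averages these across subjects.
#'
#' @param cohort named list of `subject_data` tibbles.
#' @param target `"rt"` or `"confidence"`.
#' @param spec a [sufficiency_spec()].
#' @param log_rt decode RT on the log scale.
#' @return A `sufficiency_curve` tibble: `fraction`, `mean_perf`, `sd_perf`,
#'   `n_train` (mean training trials). The per-subject table is attached as
#'   attribute `per_subject`; the two optima are available via
#'   [optimal_fractions()].
#' @export
sufficiency_curve <- function(cohort, target, spec = sufficiency_spec(),
                              log_rt = FALSE) {
  target <- match.arg(target, c("rt", "confidence"))
  rows <- list()
  for (sid in names(cohort)) {   # plain loops keep error classes unwrapped
    subject <- cohort[[sid]]
    y_all <- target_vector(subject, target, log_rt = log_rt)
    X_all <- beta_matrix(subject)
    keep <- !is.na(y_all) & complete.cases(X_all)
    y <- y_all[keep]
    X <- X_all[keep, , drop = FALSE]
    n <- length(y)
    for (fi in seq_along(spec$fractions)) {
      f <- spec$fractions[fi]
      n_train <- round(f * n)
      if (n_train < 3)
        abort(sprintf("fraction %.2f yields %d training trials (< 3)",
                      f, n_train), class = "decodr_sizing_error")
      n_hold <- n - n_train
      n_test <- if (spec$test_policy == "fixed")
        min(spec$test_count %||% max(3L, round(0.05 * n)), n_hold) else n_hold
      if (n_test < 3)
        abort(sprintf("fraction %.2f leaves %d test trials (< 3)", f, n_test),
              class = "decodr_sizing_error")
      r <- map_dbl(seq_len(spec$n_repeats), function(rep_i) {
        idx <- with_seed(derive_seed(spec$seed, sid, target, "suff", fi, rep_i),
                         sample.int(n, n_train + n_test))
        tr <- idx[seq_len(n_train)]
        te <- idx[n_train + seq_len(n_test)]
        Xtr <- X[tr, , drop = FALSE]
        Xte <- X[te, , drop = FALSE]
        if (spec$standardize) {
          mu <- colMeans(Xtr)
          sdv <- apply(Xtr, 2, sd)
          sdv[sdv == 0] <- 1
          Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
          Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
        }
        coefs <- fit_minnorm(Xtr, y[tr])
        safe_cor(y[te], predict_minnorm(coefs, Xte))
      })
      rows[[length(rows) + 1L]] <-
        tibble(subject_id = sid, fraction = f, n_train = n_train,
               n_test = n_test,
               mean_perf = mean(r, na.rm = TRUE),
               sd_perf = sd(r, na.rm = TRUE))
    }
  }
  per_subject <- bind_rows(rows)

  curve <- per_subject |>
    group_by(.data$fraction) |>
    summarise(mean_perf = mean(.data$mean_perf),
              sd_perf = mean(.data$sd_perf),
              n_train = mean(.data$n_train), .groups = "drop")
  attr(curve, "per_subject") <- per_subject
  attr(curve, "target") <- target
  attr(curve, "spec") <- spec
  class(curve) <- c("sufficiency_curve", class(curve))
  curve
}

#' Optimal training fractions from a sufficiency curve
#'
#' Two criteria: the fraction minimizing the across-repeat standard deviation
#' of performance, and the fraction maximizing performance minus that
#' standard deviation. Ties break toward the smaller fraction.
#'
#' @param curve a `sufficiency_curve`.
#' @return List with `min_variance_fraction` and `max_gap_fraction`.
#' @export
optimal_fractions <- function(curve) {
  stopifnot(all(c("fraction", "mean_perf", "sd_perf") %in% names(curve)))
  o <- order(curve$fraction)
  f <- curve$fraction[o]
  sdp <- curve$sd_perf[o]
  gap <- curve$mean_perf[o] - sdp
  list(min_variance_fraction = f[which.min(sdp)],
       max_gap_fraction = f[which.max(gap)])
}
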