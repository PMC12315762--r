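# Independent naive-loop implementations used as oracles. These share only
# the split-index streams with the package (so results are comparable cell
# by cell) and reimplement every fit, score, aggregation and count from the
# documented contracts via a different route (lm, t.test, MASS::ginv,
# explicit loops).

oracle_fisher <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0) return(NA_real_)
  tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))))
}

oracle_decode_cell <- function(subject, roi, target, spec) {
  y <- as.numeric(subject[[target]])
  x <- subject[[paste0("roi_", roi)]]
  keep <- !is.na(y) & !is.na(x)
  x <- x[keep]; y <- y[keep]
  rr <- rep(NA_real_, spec$n_repeats)
  for (i in seq_len(spec$n_repeats)) {
    idx <- split_trials(length(x), spec, i)
    d <- data.frame(xx = x[idx$train], yy = y[idx$train])
    fit <- lm(yy ~ xx, data = d)
    pred <- predict(fit, newdata = data.frame(xx = x[idx$test]))
    yt <- y[idx$test]
    rr[i] <- if (sd(pred) > 0 && sd(yt) > 0) cor(yt, pred) else NA_real_
  }
  oracle_fisher(rr)
}

oracle_group <- function(results, alpha = 0.05, n_rois = NULL) {
  results <- results[!results$missing, ]
  if (is.null(n_rois)) n_rois <- length(unique(results$roi_id))
  out <- list(); k <- 0
  for (tg in sort(unique(results$target))) {
    for (roi in sort(unique(results$roi_id))) {
      z <- results$z_aggregated[results$roi_id == roi & results$target == tg]
      z <- z[!is.na(z)]
      k <- k + 1
      if (length(z) < 3 || sd(z) == 0) {
        out[[k]] <- data.frame(roi_id = roi, target = tg, t = NA_real_,
                               p = NA_real_, r_group = tanh(mean(z)),
                               significant = FALSE)
        next
      }
      tt <- t.test(z, mu = 0, alternative = "greater")
      out[[k]] <- data.frame(roi_id = roi, target = tg,
                             t = unname(tt$statistic), p = tt$p.value,
                             r_group = tanh(mean(z)),
                             significant = tt$p.value < alpha / n_rois)
    }
  }
  do.call(rbind, out)
}

oracle_coverage_any <- function(ledger) {
  lv <- paste0("sig_", c("uncorrected", "by_subjects", "by_rois", "by_cells"))
  out <- list(); k <- 0
  for (tg in sort(unique(ledger$target))) {
    sub <- ledger[ledger$target == tg, ]
    rois <- sort(unique(sub$roi_id))
    for (l in lv) {
      hit <- 0
      for (roi in rois)
        if (any(sub[[l]][sub$roi_id == roi])) hit <- hit + 1
      k <- k + 1
      out[[k]] <- data.frame(target = tg, level = sub("sig_", "", l),
                             pct = 100 * hit / length(rois))
    }
  }
  do.call(rbind, out)
}

oracle_sign_counts <- function(results, ledger, level) {
  sig <- ledger[[paste0("sig_", level)]]
  out <- list(); k <- 0
  for (tg in sort(unique(results$target))) {
    for (roi in sort(unique(results$roi_id))) {
      sel <- results$roi_id == roi & results$target == tg
      np <- nn <- 0
      for (i in which(sel)) {
        if (!sig[i]) next
        d <- results$direction[i]
        if (!is.na(d) && d > 0) np <- np + 1
        if (!is.na(d) && d < 0) nn <- nn + 1
      }
      k <- k + 1
      out[[k]] <- data.frame(roi_id = roi, target = tg, n_pos = np, n_neg = nn)
    }
  }
  do.call(rbind, out)
}

oracle_sufficiency <- function(cohort, target, spec) {
  per <- list(); k <- 0
  for (sid in names(cohort)) {
    subject <- cohort[[sid]]
    y <- as.numeric(subject[[target]])
    X <- beta_matrix(subject)
    keep <- !is.na(y) & stats::complete.cases(X)
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    n <- length(y)
    for (fi in seq_along(spec$fractions)) {
      f <- spec$fractions[fi]
      n_train <- round(f * n)
      n_hold <- n - n_train
      n_test <- if (spec$test_policy == "fixed")
        min(if (is.null(spec$test_count)) max(3L, round(0.05 * n)) else
          spec$test_count, n_hold) else n_hold
      rr <- numeric(spec$n_repeats)
      for (rep_i in seq_len(spec$n_repeats)) {
        idx <- withr::with_seed(
          derive_seed(spec$seed, sid, target, "suff", fi, rep_i),
          sample.int(n, n_train + n_test))
        tr <- idx[seq_len(n_train)]
        te <- idx[n_train + seq_len(n_test)]
        A <- cbind(1, X[tr, , drop = FALSE])
        coefs <- MASS::ginv(A) %*% y[tr]
        pred <- cbind(1, X[te, , drop = FALSE]) %*% coefs
        rr[rep_i] <- if (sd(pred) > 0 && sd(y[te]) > 0)
          cor(y[te], as.numeric(pred)) else NA_real_
      }
      k <- k + 1
      per[[k]] <- data.frame(subject_id = sid, fraction = f,
                             mean_perf = mean(rr, na.rm = TRUE),
                             sd_perf = sd(rr, na.rm = TRUE))
    }
  }
  per <- do.call(rbind, per)
  agg <- aggregate(cbind(mean_perf, sd_perf) ~ fraction, data = per, FUN = mean)
  agg[order(agg$fraction), ]
}
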