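test_that("ledger thresholds implement the four Bonferroni levels exactly", {
  res <- random_results(2, 2, seed = 1, targets = "rt")
  res$p_perm <- c(0.0009, 0.04, 0.2, 1 / 1001)
  led <- build_ledger(res, alpha = 0.05, n_subjects = 50, n_rois = 200)
  expect_identical(unname(attr(led, "factors")), c(1, 50, 200, 10000))

  # p = 0.0009: < 0.05, < 0.001, not < 0.00025, not < 5e-6
  expect_identical(unlist(led[1, paste0("sig_", c("uncorrected", "by_subjects",
                                                  "by_rois", "by_cells"))],
                          use.names = FALSE),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(led$level[1], 2L)
  # the permutation floor 1/1001 shows the same pattern: alpha/10000 is
  # unreachable with 1000 permutations
  expect_identical(led$level[4], 2L)
  expect_identical(led$level[3], 0L)

  # missing cells are never significant
  res$missing[2] <- TRUE
  res$p_perm[2] <- NA_real_
  led2 <- build_ledger(res, n_subjects = 50, n_rois = 200)
  expect_identical(led2$level[2], 0L)
})

test_that("ledger nestedness holds for every cell on random tables", {
  for (seed in 1:5) {
    res <- random_results(8, 12, seed = seed)
    led <- build_ledger(res)
    sig <- as.matrix(led[paste0("sig_", c("uncorrected", "by_subjects",
                                          "by_rois", "by_cells"))])
    # significant at a stricter factor implies significant at all looser ones
    expect_true(all(sig[, 2] <= sig[, 1]))
    expect_true(all(sig[, 3] <= sig[, 2] | sig[, 3] <= sig[, 1]))
    expect_true(all(sig[, 4] <= sig[, 3]))
    expect_identical(led$level, as.integer(rowSums(sig)))
  }
})

test_that("group_decode matches the closed form and the t.test oracle", {
  res <- random_results(3, 1, seed = 2, targets = "rt")
  res$z_aggregated <- c(0.1, 0.2, 0.3)
  g <- group_decode(res, alpha = 0.05, n_rois = 200)
  expect_equal(g$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(g$p, pt(3.4641016, df = 2, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(g$r_group, tanh(0.2), tolerance = 1e-12)

  # degenerate: identical subjects
  res$z_aggregated <- rep(atanh(0.5), 3)
  gd <- group_decode(res)
  expect_true(gd$degenerate)
  expect_true(is.na(gd$t))

  # untestable: < 3 subjects
  gu <- group_decode(res[1:2, ])
  expect_true(gu$untestable)

  # oracle equivalence on a random table
  res2 <- random_results(9, 6, seed = 3)
  g2 <- group_decode(res2) |> dplyr::arrange(target, roi_id)
  o2 <- oracle_group(res2)
  o2 <- o2[order(o2$target, o2$roi_id), ]
  expect_equal(g2$t, o2$t, tolerance = 1e-10)
  expect_equal(g2$p, o2$p, tolerance = 1e-10)
  expect_identical(g2$significant, o2$significant)
})

test_that("coverage percentages are exact and monotone across levels", {
  res <- random_results(4, 5, seed = 4, targets = "rt")
  res$p_perm <- rep(1, nrow(res))
  res$p_perm[res$roi_id == 2 & res$subject_id == "s01"] <- 1e-9
  led <- build_ledger(res, n_subjects = 4, n_rois = 5)
  cov <- summarize_coverage(led)
  # exactly one significant cell -> one ROI of five at every level
  expect_true(all(cov$rois_any_subject$pct == 100 / 5))

  res$p_perm <- rep(1e-12, nrow(res))
  cov2 <- summarize_coverage(build_ledger(res, n_subjects = 4, n_rois = 5))
  expect_true(all(cov2$rois_any_subject$pct == 100))
  expect_true(all(cov2$subjects_per_roi$pct == 100))
  expect_true(all(cov2$rois_per_subject$pct == 100))

  for (seed in 5:8) {
    res <- random_results(6, 9, seed = seed)
    led <- build_ledger(res)
    cov <- summarize_coverage(led)
    expect_equal(
      cov$rois_any_subject |> dplyr::arrange(target, level) |> dplyr::pull(pct),
      {
        o <- oracle_coverage_any(led)
        o$level <- factor(o$level, levels = c("uncorrected", "by_subjects",
                                              "by_rois", "by_cells"))
        o[order(o$target, o$level), "pct"]
      },
      tolerance = 1e-12)
    # monotone non-increasing with stricter correction, per target
    for (tb in split(cov$rois_any_subject,
                     cov$rois_any_subject$target))
      expect_true(all(diff(tb$pct[order(tb$level)]) <= 1e-12))
  }
})

test_that("fd_qc recovers a perfect linear motion association and flags degenerate motion", {
  sim <- tiny_sim(5, 24, 2, seed = 9)
  res <- decode_all(sim$cohort, sim$atlas, targets = "rt",
                    splits = list(rt = c(10, 10)), n_repeats = 3, n_perm = 0,
                    seed = 10)
  # overwrite performance with an exact linear function of mean FD
  fd <- vapply(sim$cohort, mean_fd, numeric(1))
  res$z_aggregated <- 0.5 + 2 * fd[match(res$subject_id, names(fd))]
  qc <- suppressWarnings(fd_qc(sim$cohort, res))  # lm warns on a perfect fit
  expect_equal(qc$r_squared, 1, tolerance = 1e-9)
  expect_equal(qc$slope, 2, tolerance = 1e-9)

  # constant motion -> degenerate, not an error
  cohort2 <- lapply(sim$cohort, function(s) { attr(s, "mean_fd") <- 0.2; s })
  qc2 <- fd_qc(cohort2, res)
  expect_true(qc2$degenerate)

  # on simulated cohorts motion is independent of decoding by construction:
  # two-tailed p is non-degenerate
  qc3 <- fd_qc(sim$cohort, decode_all(sim$cohort, sim$atlas, targets = "rt",
                                      splits = list(rt = c(10, 10)),
                                      n_repeats = 3, n_perm = 0, seed = 11))
  expect_true(qc3$p > 0 && qc3$p <= 1)
})
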