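test_that("split_trials yields disjoint, deterministic partitions of the right size", {
  sp <- split_spec(350, 350, seed = 3)
  s1 <- split_trials(700, sp, 1)
  expect_length(s1$train, 350)
  expect_length(s1$test, 350)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), 1:700)   # 350/350 covers all trials

  expect_identical(split_trials(10, split_spec(5, 5, seed = 9), 2),
                   split_trials(10, split_spec(5, 5, seed = 9), 2))
  expect_false(identical(split_trials(10, split_spec(5, 5, seed = 9), 1),
                         split_trials(10, split_spec(5, 5, seed = 9), 2)))

  # reduced-confidence variant: 301 train / 101 test leaves 402 unused
  sp2 <- split_spec(301, 101, seed = 1)
  s2 <- split_trials(804, sp2, 1)
  expect_length(intersect(s2$train, s2$test), 0)
  expect_identical(804L - length(c(s2$train, s2$test)), 402L)

  expect_error(split_trials(10, split_spec(8, 3, seed = 1), 1),
               class = "decodr_sizing_error")
})

test_that("the linear decoder is exact ordinary least squares", {
  expect_equal(fit_linear_decoder(c(0, 1, 2), c(1, 3, 5)),
               c(intercept = 1, slope = 2))
  expect_equal(fit_linear_decoder(c(0, 1, 2, 5), rep(2, 4)),
               c(intercept = 2, slope = 0))
  # normal-equation oracle on random input
  withr::with_seed(5, {
    x <- rnorm(20); y <- 0.7 * x + rnorm(20)
  })
  ne <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(unname(fit_linear_decoder(x, y)), as.numeric(ne),
               tolerance = 1e-10)
  expect_true(all(is.na(fit_linear_decoder(rep(1, 5), rnorm(5)))))
})

test_that("fisher_aggregate matches the direct formula and handles edge cases", {
  expect_equal(fisher_aggregate(c(0.5, 0.5))$r, 0.5, tolerance = 1e-12)
  expect_equal(fisher_aggregate(0)$r, 0)
  expect_equal(fisher_aggregate(c(0.3, 0.6))$r,
               tanh((atanh(0.3) + atanh(0.6)) / 2), tolerance = 1e-12)
  expect_equal(fisher_aggregate(c(0.2, NA, 0.4))$r,
               tanh((atanh(0.2) + atanh(0.4)) / 2), tolerance = 1e-12)
  expect_true(is.na(fisher_aggregate(c(NA_real_, NA_real_))$r))
  expect_lt(fisher_aggregate(c(1, 1))$r, 1 + 1e-15)  # clipped, finite
  expect_gt(fisher_aggregate(c(1, 1))$r, 1 - 1e-11)
})

test_that("decode_cell: noiseless planted signal decodes perfectly; per-repeat identity holds", {
  sim <- tiny_sim(1, 40, 2, seed = 13, coupling_sparsity = 1, sign_mixture = 1,
                  coupling_magnitude = 0.5, shared_noise_sd = 0,
                  idiosyncratic_noise_sd = 0, targets = "rt")
  sp <- split_spec(20, 20, n_repeats = 5, seed = 2)
  # decode the latent (log RT): exact linear relation -> r = 1 each repeat
  rs <- decode_cell(sim$cohort[[1]], 1, "rt", sp, log_rt = TRUE)
  expect_equal(rs$r_per_repeat, rep(1, 5), tolerance = 1e-9)
  expect_gt(rs$r_aggregated, 1 - 1e-11)

  # identity r(y, yhat) = sign(slope) * r(y, x) on the test bin
  sim2 <- tiny_sim(1, 60, 2, seed = 14, coupling_sparsity = 1,
                   sign_mixture = 0, coupling_magnitude = 0.4, targets = "rt")
  subj <- sim2$cohort[[1]]
  sp2 <- split_spec(25, 25, n_repeats = 8, seed = 5)
  got <- decode_cell(subj, 1, "rt", sp2)
  for (i in 1:8) {
    idx <- split_trials(60, sp2, i)
    expect_equal(got$r_per_repeat[i],
                 sign(got$slope_per_repeat[i]) *
                   cor(subj$rt[idx$test], subj$roi_1[idx$test]),
                 tolerance = 1e-12)
  }
  expect_lt(mean(got$slope_per_repeat), 0)  # planted negative coupling
})

test_that("permutation p-values satisfy rank properties and the add-one floor", {
  sim <- tiny_sim(1, 60, 2, seed = 15, coupling_sparsity = 1, sign_mixture = 1,
                  coupling_magnitude = 0.6, idiosyncratic_noise_sd = 0.3,
                  shared_noise_sd = 0, targets = "rt")
  sp <- split_spec(25, 25, n_repeats = 5, seed = 6)
  strong <- permutation_null(sim$cohort[[1]], 1, "rt", sp, n_perm = 200)
  expect_equal(strong$p_perm, 1 / 201)     # exceeds every null draw

  # an uncoupled cell: p stays in (0, 1] and respects the rank property
  sim0 <- tiny_sim(1, 60, 1, seed = 16, coupling_magnitude = 0,
                   targets = "rt")
  null_cell <- permutation_null(sim0$cohort[[1]], 1, "rt", sp, n_perm = 100)
  expect_gt(null_cell$p_perm, 0.001)
  expect_lte(null_cell$p_perm, 1)
  med <- stats::median(null_cell$null_r, na.rm = TRUE)
  if (null_cell$obs_r < med) expect_gt(null_cell$p_perm, 0.5)
})

test_that("permutation p-values are uniform on a null cohort (KS over 2000 cells)", {
  sim <- simulate_cohort(synthetic_config(n_subjects = 20, n_trials = 30,
                                          n_rois = 100, coupling_magnitude = 0,
                                          targets = "rt", seed = 31))
  res <- decode_all(sim$cohort, sim$atlas, targets = "rt",
                    splits = list(rt = c(12, 12)), n_repeats = 5,
                    n_perm = 50, n_null_repeats = 5, seed = 32)
  expect_identical(nrow(res), 2000L)
  ks <- suppressWarnings(stats::ks.test(res$p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("decoding power is monotone in the planted coupling magnitude", {
  mags <- c(0, 0.2, 0.4, 0.6)
  means <- vapply(mags, function(m) {
    rs <- vapply(1:20, function(seed) {
      sim <- tiny_sim(1, 700, 1, seed = seed, coupling_sparsity = 1,
                      sign_mixture = 1, coupling_magnitude = m,
                      targets = "rt")
      sp <- split_spec(350, 350, n_repeats = 5,
                       seed = derive_seed(seed, m, "pow"))
      decode_cell(sim$cohort[[1]], 1, "rt", sp)$r_aggregated
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("decode_all enumerates cells, is reproducible, and flags degenerate cells", {
  sim <- tiny_sim(2, 30, 3, seed = 17)
  for (s in seq_along(sim$cohort)) sim$cohort[[s]]$roi_3 <- 7  # zero variance
  args <- list(sim$cohort, sim$atlas,
               splits = list(rt = c(12, 12), confidence = c(12, 12)),
               n_repeats = 4, n_perm = 25, n_null_repeats = 2, seed = 8)
  res <- do.call(decode_all, args)
  expect_identical(nrow(res), 2L * 3L * 2L)
  expect_true(all(res$missing[res$roi_id == 3]))
  expect_match(res$reason[res$roi_id == 3][1], "zero-variance")
  expect_false(any(res$missing[res$roi_id != 3]))
  res2 <- do.call(decode_all, args)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # too few usable trials -> flagged, not fatal
  short <- tiny_sim(1, 20, 2, seed = 18)
  res3 <- decode_all(short$cohort, short$atlas, targets = "rt",
                     splits = list(rt = c(15, 10)), n_repeats = 3,
                     n_perm = 10, seed = 9)
  expect_true(all(res3$missing))
  expect_match(res3$reason[1], "too few")
})

test_that("SVR and OLS regressors agree on strongly linear data; contract is enforced", {
  sim <- tiny_sim(1, 200, 1, seed = 19, coupling_sparsity = 1,
                  sign_mixture = 1, coupling_magnitude = 0.7,
                  idiosyncratic_noise_sd = 0.2, shared_noise_sd = 0,
                  targets = "rt")
  sp <- split_spec(100, 100, n_repeats = 5, seed = 3)
  r_ols <- decode_cell(sim$cohort[[1]], 1, "rt", sp)$r_aggregated
  r_svr <- decode_cell(sim$cohort[[1]], 1, "rt", sp,
                       regressor = regressor_svr())$r_aggregated
  expect_lt(abs(r_ols - r_svr), 0.05)

  broken <- new_regressor("broken", fit = function(x, y) list(),
                          predict = function(m, x) x[-1])
  expect_error(decode_cell(sim$cohort[[1]], 1, "rt", sp, regressor = broken),
               class = "decodr_contract_error")
})

test_that("the fast OLS permutation path equals the generic contract path", {
  sim <- tiny_sim(1, 40, 1, seed = 23, coupling_sparsity = 1,
                  coupling_magnitude = 0.4, targets = "rt")
  sp <- split_spec(16, 16, n_repeats = 4, seed = 7)
  # identical label-free regressor forces the generic path with OLS math
  generic_ols <- new_regressor("ols-generic",
                               fit = regressor_ols()$fit,
                               predict = regressor_ols()$predict)
  a <- permutation_null(sim$cohort[[1]], 1, "rt", sp, n_perm = 40)
  b <- permutation_null(sim$cohort[[1]], 1, "rt", sp, n_perm = 40,
                        regressor = generic_ols)
  expect_equal(a$null_r, b$null_r, tolerance = 1e-12)
  expect_identical(a$p_perm, b$p_perm)
})
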