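test_that("predicted trajectories honour the non-decision-time split", {
  params <- ref_params()
  trial <- tibble::tibble(pu = "low", au = "low", n_options = 1L, rt = 0.9)
  t0 <- params$t0[["low_low"]]

  # boundary split: tau1 = 0 puts all non-decision time after accumulation
  tr0 <- predict_activity(trial, params, tau1 = 0)
  expect_equal(attr(tr0, "tau2"), t0)
  # geometry: the winner reaches b exactly at rt - tau2
  dec_idx <- which.min(abs(tr0$time - (0.9 - t0)))
  expect_equal(tr0$activity[dec_idx], params$b[["low_low"]],
               tolerance = 1e-6)

  tr <- predict_activity(trial, params, tau1 = 0.2)
  expect_equal(attr(tr, "tau1") + attr(tr, "tau2"), t0)
  # flat before accumulation onset at the expected start level
  pre <- tr$activity[tr$time < 0.2 - 1e-9]
  expect_true(all(abs(pre - params$z[["low_low"]] / 2) < 1e-12))
  # flat after decision time
  post <- tr$activity[tr$time > 0.9 - attr(tr, "tau2") + 1e-9]
  expect_true(all(abs(diff(post)) < 1e-12))

  # 3-option value at decision time dominates the 1-option value
  trial3 <- tibble::tibble(pu = "low", au = "high", n_options = 3L, rt = 0.9)
  tr3 <- predict_activity(trial3, params, tau1 = 0.2)
  expect_gt(max(tr3$activity), max(tr$activity))

  expect_error(predict_activity(trial, params, tau1 = 0.5), "tau1")
})

test_that("lag search recovers an embedded negative signal", {
  co <- small_cohort(n_subjects = 1, trials_per_cell = 40, n_roi = 4,
                     snr = 4, seed = 21)
  env <- co$envelopes[[1]]
  trials <- co$behaviour$trials
  params <- co$behaviour$truth[[1]]
  truth <- env$truth$tau1
  for (r in seq_along(env$roi)) {
    res <- max_lagged_spearman(env, roi = r, trials = trials,
                               params = params)
    expect_lt(res$rho, 0)                       # desynchronization
    expect_lt(abs(res$tau1 - truth[[r]]), 0.021) # within ~2 lag steps
    expect_equal(res$tau1 + res$tau2, min(params$t0), tolerance = 1e-9)
  }
})

test_that("rank invariance and null behaviour of the lag search", {
  co <- small_cohort(n_subjects = 1, trials_per_cell = 20, n_roi = 1,
                     snr = 2, seed = 33)
  env <- co$envelopes[[1]]
  trials <- co$behaviour$trials
  params <- co$behaviour$truth[[1]]
  res <- max_lagged_spearman(env, 1, trials, params)
  # strictly increasing transform leaves the correlation untouched
  env2 <- env
  env2$data <- exp(env$data / 50) * 3 - 1
  res2 <- max_lagged_spearman(env2, 1, trials, params)
  expect_equal(res$rho, res2$rho, tolerance = 1e-12)
  expect_equal(res$tau1, res2$tau1)

  # pure white-noise envelopes: small |rho| on long concatenations
  set.seed(4)
  rhos <- replicate(40, {
    noise <- env
    noise$data[] <- rnorm(length(env$data))
    abs(max_lagged_spearman(noise, 1, trials, params)$rho)
  })
  expect_lt(mean(rhos), 0.1)
})

test_that("sign test matches the exact binomial", {
  # all 21 subjects negative: p = 2 * 0.5^21
  all_neg <- -abs(rnorm(21))
  st <- roi_sign_test(all_neg)
  exact <- 2 * 0.5^21
  expect_lt(abs(st$p - exact) / exact, 0.1)
  expect_lt(st$z, -4)

  # perfect balance
  bal <- c(rnorm(10, 5), rnorm(10, -5))
  bal <- c(abs(bal[1:10]), -abs(bal[11:20]))
  st2 <- roi_sign_test(bal)
  expect_equal(st2$z, 0)
  expect_equal(st2$p, 1)

  # sign flip mirrors Z, keeps p
  st3 <- roi_sign_test(-all_neg)
  expect_equal(st3$z, -st$z)
  expect_equal(st3$p, st$p)

  # zeros are dropped and counted
  st4 <- roi_sign_test(c(all_neg, 0, 0))
  expect_equal(st4$n_dropped, 2)
  expect_equal(st4$n, 21)
})

test_that("phase randomization preserves the amplitude spectrum", {
  set.seed(6)
  for (n in c(200, 201)) {          # even and odd lengths
    x <- as.numeric(arima.sim(list(ar = 0.8), n))
    y <- phase_randomize(x, seed = 3)
    expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-10)
    expect_equal(mean(y), mean(x), tolerance = 1e-10)
    expect_true(all(abs(Im(fft(y)[1])) < 1e-8))
    # Wiener-Khinchin: autocorrelation inherited from the spectrum
    acf_x <- acf(x, lag.max = 20, plot = FALSE,
                 demean = FALSE)$acf[, 1, 1]
    acf_y <- acf(y, lag.max = 20, plot = FALSE,
                 demean = FALSE)$acf[, 1, 1]
    # circular vs linear autocorrelation differ slightly at the edges
    expect_lt(max(abs(acf_x - acf_y)), 0.15)
    expect_gt(cor(acf_x, acf_y), 0.95)
  }
})

test_that("group latency map aggregates subjects per ROI", {
  co <- small_cohort(n_subjects = 5, trials_per_cell = 20, n_roi = 3,
                     snr = 4, seed = 41)
  lat <- subject_roi_latencies(co$envelopes, co$behaviour$trials,
                               co$behaviour$truth)
  expect_equal(nrow(lat), 15)
  expect_true(all(abs(lat$rho) <= 1))
  expect_true(all(lat$norm_latency >= 0 & lat$norm_latency <= 1))
  map <- latency_map(lat)
  expect_equal(nrow(map), 3)
  expect_true(all(map$n_subjects == 5))
  expect_true(all(map$sign_test_z < 0))   # consistent desynchronization
})

test_that("permutation null detects embedded signal and stays calibrated", {
  co <- small_cohort(n_subjects = 12, trials_per_cell = 15, n_roi = 2,
                     snr = 4, seed = 55)
  pp <- permutation_null_pvalues(co$envelopes, co$behaviour$trials,
                                 co$behaviour$truth, n_iter = 200, seed = 9)
  # strong embedded signal drives p to (near) the smallest attainable value
  expect_true(all(pp$p_perm <= 0.05))
  expect_lte(min(pp$p_perm), 2 / 201)
  expect_warning(
    permutation_null_pvalues(co$envelopes, co$behaviour$trials,
                             co$behaviour$truth, n_iter = 50, seed = 9),
    "coarse")
})

test_that("BH correction matches hand-computed q-values", {
  out <- fdr_correct(c(0.001, 0.02, 0.9))
  expect_equal(out$q_value, c(0.003, 0.03, 0.9))
  ties <- fdr_correct(rep(0.01, 10))
  expect_equal(ties$q_value, rep(0.01, 10))
  out2 <- fdr_correct(c(0.5, 0.01))
  expect_true(all(out2$q_value >= out2$p))
  expect_error(fdr_correct(c(-0.1, 0.5)), "0, 1")
})
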