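test_that("first-passage density integrates to the defective mass", {
  set.seed(3)
  for (i in 1:20) {
    v <- runif(1, 0.5, 5); b <- runif(1, 0.5, 3)
    z <- runif(1, 0.05, 0.9) * b; s <- runif(1, 0.5, 2)
    quad <- integrate(function(t) lba_fpt_pdf(t, v, s, b, z), 0, 100,
                      rel.tol = 1e-9)$value
    expect_equal(quad, lba_fpt_cdf(100, v, s, b, z), tolerance = 1e-6)
  }
})

test_that("density matches the empirical distribution of simulated races", {
  v <- 2.5; s <- 1; b <- 1.2; z <- 0.6
  set.seed(9)
  n <- 1e5
  starts <- runif(n, 0, z)
  drifts <- rnorm(n, v, s)
  hit <- drifts > 0
  t_emp <- (b - starts[hit]) / drifts[hit]
  # compare conditional-on-finishing distributions
  p_hit <- lba_fpt_cdf(1e6, v, s, b, z)
  grid <- seq(0.05, 5, by = 0.05)
  theo <- lba_fpt_cdf(grid, v, s, b, z) / p_hit
  emp <- ecdf(t_emp)(grid)
  expect_lt(max(abs(theo - emp)), 0.01)
})

test_that("degenerate limits concentrate mass at b/v", {
  # z -> 0, s -> 0: hitting time collapses to b/v
  t_star <- 1.2 / 2
  expect_lt(lba_fpt_cdf(t_star - 0.01, v = 2, s = 1e-6, b = 1.2, z = 1e-8),
            1e-6)
  expect_gt(lba_fpt_cdf(t_star + 0.01, v = 2, s = 1e-6, b = 1.2, z = 1e-8),
            1 - 1e-6)
  sim <- simulate_lba(
    lba_parameters(v = 2, b = 1.2, z = 1e-9, t0 = 0.3, s = 1e-9),
    make_design(5), seed = 1)
  expect_equal(sim$rt, rep(0.3 + t_star, nrow(sim)), tolerance = 1e-9)
})

test_that("race likelihood reduces correctly and matches Monte Carlo", {
  params <- ref_params()
  # race of one: likelihood is the bare first-passage density
  one <- tibble::tibble(pu = "low", au = "low", n_options = 1L,
                        rt = c(0.6, 0.8, 1.1))
  dt <- one$rt - params$t0[["low_low"]]
  manual <- sum(log(lba_fpt_pdf(dt, params$v[["low_low"]], 1,
                                params$b[["low_low"]],
                                params$z[["low_low"]]) /
                      (1 - pnorm(-params$v[["low_low"]]))))
  expect_equal(lba_race_loglik(one, params), manual, tolerance = 1e-12)

  # Monte-Carlo oracle for a 3-option cell: winner-time density from
  # kernel smoothing of simulated races
  cellp <- list(v = params$v[["low_high"]], b = params$b[["low_high"]],
                z = params$z[["low_high"]], t0 = params$t0[["low_high"]])
  set.seed(21)
  nmc <- 1e6
  win <- replicate(3, {
    d <- rnorm(nmc, cellp$v, 1)
    st <- runif(nmc, 0, cellp$z)
    ifelse(d > 0, (cellp$b - st) / d, Inf)
  })
  tmin <- apply(win, 1, min)
  tmin <- tmin[is.finite(tmin)]
  p_any <- 1 - pnorm(-cellp$v)^3
  dens <- density(tmin, n = 2048, from = 0, to = 4)
  test_rt <- c(0.5, 0.7, 0.9, 1.2)
  trials <- tibble::tibble(pu = "low", au = "high", n_options = 3L,
                           rt = test_rt)
  ll <- lba_race_loglik(trials, params)
  # the min-time density over 3 exchangeable accumulators is 3 f S^2, so a
  # specific winner's contribution is one third of it (renormalized)
  mc <- sum(log(approx(dens$x, dens$y, test_rt - cellp$t0)$y *
                  (length(tmin) / nmc) / (3 * p_any)))
  expect_lt(abs(ll - mc) / length(test_rt), 0.05)
})

test_that("simulated RTs respond to drift as the race predicts", {
  des <- make_design(2000)
  base <- simulate_lba(lba_parameters(v = 2, b = 1.2, z = 0.6, t0 = 0.35),
                       des, seed = 5)
  fast <- simulate_lba(lba_parameters(v = 3, b = 1.2, z = 0.6, t0 = 0.35),
                       des, seed = 5)
  expect_lt(mean(fast$rt), mean(base$rt))
  # all RTs exceed non-decision time
  expect_true(all(base$rt > 0.35))
  # seeded determinism
  again <- simulate_lba(lba_parameters(v = 2, b = 1.2, z = 0.6, t0 = 0.35),
                        des, seed = 5)
  expect_identical(base$rt, again$rt)
})

test_that("variant enumeration spans all non-empty parameter subsets", {
  v <- enumerate_variants()
  expect_equal(nrow(v), 15)
  expect_equal(anyDuplicated(v$variant), 0)
  sizes <- lengths(v$free)
  expect_equal(as.integer(table(sizes)), c(4L, 6L, 4L, 1L))
  expect_true("v" %in% v$variant)
  # fitted-scalar count: 4 per freed parameter + 1 per shared
  expect_equal(v$k, 4L * sizes + (4L - sizes))
})

test_that("BIC follows its definition", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-200, 5, 100), 5 * log(100) + 400)
})

test_that("fitting recovers drift-only structure and is seed-stable", {
  trials <- ref_trials(150, seed = 13)
  fit <- fit_lba(trials, "v", n_starts = 5, n_presearch = 20, seed = 2)

  # optimality: at least as good as the generating parameters
  kept <- trials[trials$rt >= 0.1 & trials$rt <= 2.1, ]
  expect_gte(fit$loglik + 1e-6, lba_race_loglik(kept, ref_params()))

  # per-cell drift recovery within 15%
  rel <- abs(fit$params$v - ref_params()$v) / ref_params()$v
  expect_lt(max(rel), 0.15)

  # multi-start stability across seeds
  refit <- fit_lba(trials, "v", n_starts = 5, n_presearch = 20, seed = 77)
  expect_lt(abs(fit$loglik - refit$loglik), 0.1)

  # trials outside the inclusion window are dropped
  padded <- rbind(trials, tibble::tibble(pu = "low", au = "low",
                                         n_options = 1L, response = 1L,
                                         rt = c(0.05, 3)))
  fit2 <- fit_lba(padded, "v", n_starts = 2, n_presearch = 10, seed = 2)
  expect_equal(fit2$n_trials, nrow(kept))
})

test_that("nested variants never lose likelihood but can lose BIC", {
  trials <- ref_trials(80, seed = 29)
  f_small <- fit_lba(trials, "v", n_starts = 4, n_presearch = 20, seed = 3)
  f_big <- fit_lba(trials, "v+b+z+t0", n_starts = 4, n_presearch = 20,
                   seed = 3)
  expect_gte(f_big$loglik + 0.1, f_small$loglik)
  expect_gt(f_big$bic, f_small$bic)  # 640 trials: penalty dominates
})
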