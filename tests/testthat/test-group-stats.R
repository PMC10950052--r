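test_that("cluster test localizes an injected desynchronization difference", {
  time <- seq(0, 1.2, by = 0.01)
  n <- 20
  set.seed(14)
  a <- matrix(rnorm(n * length(time), 0, 1), n)
  b <- matrix(rnorm(n * length(time), 0, 1), n)
  win <- time >= 0.3 & time <= 0.7
  a[, win] <- a[, win] - 2
  ct <- cluster_permutation_test(a, b, time, n_perm = 500, seed = 3)
  sig <- ct$clusters[ct$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(abs(sig$mass)), ]
  overlap <- min(main$t_end, 0.7) - max(main$t_start, 0.3)
  expect_gte(overlap / 0.4, 0.8)
  expect_lt(main$mass, 0)

  # label swap mirrors masses, keeps p
  ct2 <- cluster_permutation_test(b, a, time, n_perm = 500, seed = 3)
  expect_equal(ct2$clusters$mass, -ct$clusters$mass)
  expect_equal(ct2$clusters$p, ct$clusters$p)

  expect_error(cluster_permutation_test(a[1:4, ], b[1:4, ], time),
               "6 subjects")
})

test_that("cluster test type-I error stays near nominal", {
  time <- seq(0, 1.2, by = 0.02)
  fp <- 0
  n_sims <- 120
  for (i in seq_len(n_sims)) {
    set.seed(1000 + i)
    a <- matrix(rnorm(12 * length(time)), 12)
    b <- matrix(rnorm(12 * length(time)), 12)
    ct <- cluster_permutation_test(a, b, time, n_perm = 250, seed = i)
    fp <- fp + any(ct$clusters$p < 0.05)
  }
  rate <- fp / n_sims
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.1)
})

test_that("mixed model recovers the generating fixed effects", {
  gen <- function(seed) {
    set.seed(seed)
    df <- tidyr::expand_grid(subject = sprintf("s%02d", 1:16),
                             roi = sprintf("r%d", 1:4),
                             pu = c("low", "high"), au = c("low", "high"))
    df$group <- ifelse(as.integer(substr(df$subject, 2, 3)) <= 8,
                       "control", "patient")
    X <- with(df, cbind(1, pu == "high", au == "high", group == "patient",
                        (pu == "high") * (group == "patient"),
                        (au == "high") * (group == "patient")))
    beta <- c(0, 1.3, -2.73, 0.5, 0, 0.42)
    roi_int <- rnorm(4)[match(df$roi, sprintf("r%d", 1:4))]
    subj_int <- rnorm(64)[match(paste(df$roi, df$subject),
                               unique(paste(df$roi, df$subject)))]
    df$power <- as.numeric(X %*% beta) + roi_int + subj_int + rnorm(nrow(df))
    list(df = df, beta = beta)
  }
  covered <- matrix(0, 10, 6)
  for (s in 1:10) {
    g <- gen(s)
    m <- suppressWarnings(fit_power_lmm(g$df))
    covered[s, ] <- g$beta >= m$coefficients$conf_low &
      g$beta <= m$coefficients$conf_high
  }
  # each coefficient covered by its 95% CI in most runs
  expect_true(all(colMeans(covered) >= 0.7))

  # balanced design with no random variance: estimates match OLS
  g0 <- gen(3)
  df0 <- g0$df
  set.seed(5)
  X <- with(df0, cbind(1, pu == "high", au == "high", group == "patient",
                       (pu == "high") * (group == "patient"),
                       (au == "high") * (group == "patient")))
  df0$power <- as.numeric(X %*% g0$beta) + rnorm(nrow(df0))
  m0 <- suppressWarnings(fit_power_lmm(df0))
  ols <- lm(power ~ factor(pu, c("low", "high")) *
              factor(group, c("control", "patient")) +
              factor(au, c("low", "high")) *
              factor(group, c("control", "patient")), data = df0)
  expect_equal(sort(unname(coef(ols))),
               sort(m0$coefficients$estimate), tolerance = 1e-5)
  # degenerate nesting: conditional ~ marginal R2
  expect_equal(m0$r2_conditional, m0$r2_marginal, tolerance = 0.05)
})

test_that("latency gradient regression equals closed-form OLS", {
  rs <- tibble::tibble(roi = sprintf("roi%02d", 1:8), dorsal_path = TRUE,
                       caudo_rostral_position = 1:8)
  # perfectly linear latencies: exact slope, R2 = 1
  lat <- tidyr::expand_grid(subject = sprintf("s%d", 1:6),
                            roi = rs$roi)
  lat$norm_latency <- 0.1 + 0.05 * as.integer(substr(lat$roi, 4, 5))
  g <- latency_gradient(lat, rs, n_boot = 100, seed = 1)
  expect_equal(g$slope, 0.05, tolerance = 1e-10)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  expect_true(g$ci[1] <= g$slope && g$slope <= g$ci[2])

  # constant latencies: slope ~ 0, R2 ~ 0
  lat$norm_latency <- 0.4
  g0 <- latency_gradient(lat, rs, n_boot = 50, seed = 1)
  expect_equal(g0$slope, 0, tolerance = 1e-10)
  expect_lt(g0$r_squared, 1e-10)

  # noisy gradient: closed-form OLS agreement
  set.seed(8)
  lat$norm_latency <- 0.1 + 0.03 *
    as.integer(substr(lat$roi, 4, 5)) + rnorm(nrow(lat), 0, 0.05)
  g1 <- latency_gradient(lat, rs, n_boot = 200, seed = 2)
  mean_lat <- aggregate(norm_latency ~ roi, lat, mean)
  mean_lat$pos <- as.integer(substr(mean_lat$roi, 4, 5))
  ref <- lm(norm_latency ~ pos, mean_lat)
  expect_equal(g1$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(g1$r_squared, summary(ref)$r.squared, tolerance = 1e-10)

  expect_error(latency_gradient(lat[lat$roi %in% rs$roi[1:3], ], rs),
               "4 ROIs")
})

test_that("bootstrap CI covers a generated gradient slope", {
  rs <- tibble::tibble(roi = sprintf("roi%02d", 1:8), dorsal_path = TRUE,
                       caudo_rostral_position = 1:8)
  true_slope <- 0.02
  cover <- 0
  for (i in 1:30) {
    set.seed(200 + i)
    lat <- tidyr::expand_grid(subject = sprintf("s%d", 1:12), roi = rs$roi)
    subj_off <- rnorm(12, 0, 0.03)[match(lat$subject,
                                         sprintf("s%d", 1:12))]
    lat$norm_latency <- 0.2 + true_slope *
      as.integer(substr(lat$roi, 4, 5)) + subj_off +
      rnorm(nrow(lat), 0, 0.04)
    g <- latency_gradient(lat, rs, n_boot = 200, seed = i)
    cover <- cover + (g$ci[1] <= true_slope && true_slope <= g$ci[2])
  }
  expect_gte(cover / 30, 0.8)
})

test_that("rank-sum comparison behaves across regimes", {
  # identical samples: p = 1 under the midrank convention
  x <- c(1, 2, 3, 4, 5)
  res <- compare_group_latencies(x, x)
  expect_gt(res$p, 0.9)

  # clear shift is detected
  set.seed(10)
  res2 <- compare_group_latencies(rnorm(20), rnorm(20) + 5)
  expect_lt(res2$p, 0.001)

  # W matches the exhaustive rank computation on toy data
  a <- c(1.1, 2.3, 0.2, 4.4, 3.3); b <- c(2.0, 5.1, 0.9, 6.2, 7.7)
  r <- rank(c(a, b))
  w_manual <- sum(r[1:5]) - 5 * 6 / 2
  expect_equal(compare_group_latencies(a, b)$W, w_manual)

  expect_error(compare_group_latencies(numeric(0), b), "non-empty")
})

test_that("contingency odds ratio and Fisher test match enumeration", {
  # published-orientation check: second-group odds over first-group odds
  tab <- matrix(c(13, 8, 10, 7), 2, 2, byrow = TRUE)
  res <- contingency_odds_ratio(tab)
  expect_equal(res$odds_ratio, (10 / 7) / (13 / 8), tolerance = 1e-12)
  expect_equal(round(res$odds_ratio, 2), 0.88)

  res_id <- contingency_odds_ratio(matrix(5, 2, 2))
  expect_equal(res_id$odds_ratio, 1)
  expect_equal(res_id$fisher_p, 1)

  # Fisher p equals full hypergeometric enumeration over fixed margins
  enum_p <- function(tab) {
    a <- tab[1, 1]; m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ])
    cs <- sum(tab[, 1])
    support <- max(0, cs - m2):min(cs, m1)
    probs <- dhyper(support, m1, m2, cs)
    sum(probs[probs <= dhyper(a, m1, m2, cs) * (1 + 1e-7)])
  }
  for (tab in list(tab, matrix(c(2, 9, 8, 3), 2, byrow = TRUE),
                   matrix(c(1, 5, 7, 2), 2, byrow = TRUE))) {
    expect_equal(contingency_odds_ratio(tab)$fisher_p, enum_p(tab),
                 tolerance = 1e-9)
  }

  expect_warning(contingency_odds_ratio(matrix(c(0, 5, 0, 7), 2)),
                 "marginal")
})
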