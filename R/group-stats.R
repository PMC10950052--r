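#' Cluster-corrected paired permutation test on envelope time-courses
#'
#' Compares two within-subject conditions sample-by-sample with paired
#' t-statistics, forms clusters of contiguous samples exceeding the
#' two-tailed cluster-forming threshold, and evaluates each cluster's mass
#' (summed t) against the permutation distribution of the maximum absolute
#' cluster mass under random sign flips of the subject-wise condition
#' differences.
#'
#' @param cond_a,cond_b Numeric matrices, subjects x time, of trial-mean
#'   envelopes per condition (paired by row).
#' @param time Time axis in seconds matching the columns.
#' @param window Analysis window (s); samples outside are ignored.
#' @param n_perm Number of sign-flip permutations (study scale 10000).
#' @param cluster_alpha Two-tailed cluster-forming alpha on the t map.
#' @param seed Integer seed.
#' @return An object of class `cluster_test` with a tibble of clusters
#'   (`t_start`, `t_end`, `mass`, `p`) and the test settings.
#' @export
cluster_permutation_test <- function(cond_a, cond_b, time,
                                     window = c(0.1, 1.0), n_perm = 10000,
                                     cluster_alpha = 0.05, seed = 1) {
  stopifnot(all(dim(cond_a) == dim(cond_b)), ncol(cond_a) == length(time))
  n <- nrow(cond_a)
  if (n < 6) abort("need at least 6 subjects for a sign-flip permutation test")
  keep <- time >= window[1] & time <= window[2]
  D <- (cond_a - cond_b)[, keep, drop = FALSE]
  tvec <- time[keep]
  n_t <- ncol(D)

  t_crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  col_t <- function(mean_d, ss) {
    # ss = column sums of squares (invariant under sign flips)
    sd <- sqrt(pmax(ss / n - mean_d^2, 0) * n / (n - 1))
    ifelse(sd > 0, mean_d / (sd / sqrt(n)), 0)
  }
  ss <- colSums(D^2)

  clusters_of <- function(tstat) {
    above <- abs(tstat) > t_crit
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    idx <- which(r$values)
    lapply(idx, function(i) {
      span <- starts[i]:ends[i]
      list(start = span[1], end = span[length(span)],
           mass = sum(tstat[span]))
    })
  }

  t_obs <- col_t(colMeans(D), ss)
  obs <- clusters_of(t_obs)

  max_null <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    means <- (signs %*% D) / n
    vapply(seq_len(n_perm), function(i) {
      cl <- clusters_of(col_t(means[i, ], ss))
      if (is.null(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
    }, 0)
  })

  cl_tbl <- if (is.null(obs)) {
    tibble::tibble(t_start = numeric(), t_end = numeric(),
                   mass = numeric(), p = numeric())
  } else {
    tibble::tibble(
      t_start = vapply(obs, function(c) tvec[c$start], 0),
      t_end = vapply(obs, function(c) tvec[c$end], 0),
      mass = vapply(obs, `[[`, 0, "mass"),
      p = vapply(obs, function(c) {
        (1 + sum(max_null >= abs(c$mass))) / (n_perm + 1)
      }, 0))
  }
  structure(list(clusters = cl_tbl, window = window, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, t_crit = t_crit,
                 t_map = tibble::tibble(time = tvec, t = t_obs)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "Cluster permutation test (window %.2f..%.2f s, %d permutations)\n",
    x$window[1], x$window[2], x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no suprathreshold clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' Linear mixed model of condition and group effects on power
#'
#' Fits, by maximum likelihood, the model
#' `power ~ pu + au + group + pu:group + au:group` with random intercepts for
#' subjects nested within ROI. Treatment coding uses low uncertainty and the
#' control group as reference levels, so coefficients read as the change from
#' that reference. Conditional R-squared follows the variance-partition
#' convention (fixed + random over total).
#'
#' @param data Data frame with columns `power` (per subject x ROI x cell
#'   response, e.g. median over the analysis window), `pu`, `au`
#'   (`"low"`/`"high"`), `group` (`"control"`/`"patient"`), `subject`, `roi`.
#' @return An object of class `power_lmm` wrapping the `lmerMod` fit with a
#'   coefficient table, variance components and R-squared measures.
#' @export
fit_power_lmm <- function(data) {
  needed <- c("power", "pu", "au", "group", "subject", "roi")
  stopifnot(all(needed %in% names(data)))
  if (length(unique(data$roi)) < 2) abort("need at least 2 ROIs")
  data <- dplyr::mutate(
    data,
    pu = factor(.data$pu, levels = c("low", "high")),
    au = factor(.data$au, levels = c("low", "high")),
    group = factor(.data$group, levels = c("control", "patient")))
  fit <- lmerTest::lmer(
    power ~ pu + au + group + pu:group + au:group + (1 | roi / subject),
    data = data, REML = FALSE)
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warn("singular random-effects fit: a variance component is near zero")
  }
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(stats::confint(fit, parm = "beta_", method = "Wald"))
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    conf_low = unname(ci[, 1]), conf_high = unname(ci[, 2]),
    p_value = unname(sm[, "Pr(>|t|)"]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.numeric(stats::model.matrix(fit) %*%
                                       lme4::fixef(fit)))
  r2_marginal <- var_fixed / (var_fixed + var_random + var_resid)
  r2_conditional <- (var_fixed + var_random) /
    (var_fixed + var_random + var_resid)
  structure(list(fit = fit, coefficients = coefs,
                 r2_marginal = r2_marginal,
                 r2_conditional = r2_conditional,
                 varcorr = vc),
            class = "power_lmm")
}

#' @export
print.power_lmm <- function(x, ...) {
  cat("Linear mixed model of baseline-normalized power\n")
  print(x$coefficients)
  cat(sprintf("  marginal R2 %.3f, conditional R2 %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @method tidy power_lmm
#' @export
tidy.power_lmm <- function(x, ...) x$coefficients

#' @method glance power_lmm
#' @export
glance.power_lmm <- function(x, ...) {
  tibble::tibble(r2_marginal = x$r2_marginal,
                 r2_conditional = x$r2_conditional,
                 logLik = as.numeric(stats::logLik(x$fit)),
                 AIC = stats::AIC(x$fit), BIC = stats::BIC(x$fit))
}

#' Interaction contrast: condition effect difference between groups
#'
#' Post hoc contrast on a [fit_power_lmm()] result comparing the low-minus-
#' high difference of one uncertainty factor between groups (estimated
#' marginal means machinery).
#'
#' @param model A `power_lmm`.
#' @param factor `"au"` or `"pu"`.
#' @return A tibble with the contrast estimate, SE, z-ratio and p-value.
#' @export
lmm_interaction_contrast <- function(model, factor = "au") {
  stopifnot(inherits(model, "power_lmm"), factor %in% c("au", "pu"))
  emm <- emmeans::emmeans(model$fit, stats::as.formula(paste0("~ ", factor,
                                                              " | group")),
                          lmer.df = "asymptotic")
  con <- emmeans::contrast(emm, "pairwise")
  diff <- emmeans::contrast(con, "pairwise", by = NULL)
  out <- as.data.frame(summary(diff))
  tibble::as_tibble(out)
}

#' Regression of normalized accumulation latency on caudo-rostral position
#'
#' Ordinary least squares of per-ROI mean normalized latency on a
#' caudo-rostral position coordinate, with a bootstrap-over-subjects 95%
#' confidence interval for the slope.
#'
#' @param latencies Per-subject latencies (output of
#'   [subject_roi_latencies()]) restricted to the ROIs of interest.
#' @param roi_spec Data frame with `roi` and `caudo_rostral_position` (plus
#'   optionally `dorsal_path` to filter on).
#' @param n_boot Bootstrap resamples of subjects.
#' @param seed Integer seed.
#' @return An object of class `gradient_fit` with `slope`, `intercept`,
#'   `r_squared`, `p_value` and `ci` (bootstrap 95% for the slope).
#' @export
latency_gradient <- function(latencies, roi_spec, n_boot = 2000, seed = 1) {
  if ("dorsal_path" %in% names(roi_spec)) {
    roi_spec <- roi_spec[roi_spec$dorsal_path, , drop = FALSE]
  }
  df <- dplyr::inner_join(latencies, roi_spec, by = "roi")
  if (length(unique(df$roi)) < 4) {
    abort("need at least 4 ROIs with latencies for a gradient fit")
  }
  mean_lat <- dplyr::summarise(
    dplyr::group_by(df, .data$roi, .data$caudo_rostral_position),
    latency = mean(.data$norm_latency), .groups = "drop")
  fit <- stats::lm(latency ~ caudo_rostral_position, data = mean_lat)
  sm <- suppressWarnings(summary(fit))
  degenerate <- stats::var(mean_lat$latency) < 1e-16
  r2 <- if (degenerate) 0 else sm$r.squared
  adj_r2 <- if (degenerate) 0 else sm$adj.r.squared
  p_val <- if (degenerate) 1 else sm$coefficients[2, 4]
  subjects <- unique(df$subject)
  slopes <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      take <- sample(subjects, replace = TRUE)
      boot_df <- purrr::map_dfr(take, function(s) df[df$subject == s, ])
      bm <- dplyr::summarise(
        dplyr::group_by(boot_df, .data$roi, .data$caudo_rostral_position),
        latency = mean(.data$norm_latency), .groups = "drop")
      stats::coef(stats::lm(latency ~ caudo_rostral_position,
                            data = bm))[[2]]
    }, 0)
  })
  structure(
    list(slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
         r_squared = r2, adj_r_squared = adj_r2,
         p_value = p_val,
         ci = stats::quantile(slopes, c(0.025, 0.975), names = FALSE),
         mean_latencies = mean_lat, lm = fit),
    class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("Caudo-rostral latency gradient (OLS on ROI mean latencies)\n")
  cat(sprintf("  slope %.4f [boot 95%% CI %.4f, %.4f], R2 %.3f, p %.4g\n",
              x$slope, x$ci[1], x$ci[2], x$r_squared, x$p_value))
  invisible(x)
}

#' @method tidy gradient_fit
#' @export
tidy.gradient_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance gradient_fit
#' @export
glance.gradient_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, r_squared = x$r_squared,
                 adj_r_squared = x$adj_r_squared, p_value = x$p_value,
                 ci_low = x$ci[1], ci_high = x$ci[2])
}

#' Plot a latency gradient fit
#'
#' @param object A `gradient_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gradient_fit
#' @export
autoplot.gradient_fit <- function(object, ...) {
  ggplot2::ggplot(object$mean_latencies,
                  ggplot2::aes(x = .data$caudo_rostral_position,
                               y = .data$latency)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
    ggplot2::labs(x = "caudo-rostral position",
                  y = "normalized accumulation latency") +
    ggplot2::theme_minimal()
}

#' Wilcoxon rank-sum comparison of two latency samples
#'
#' @param latencies_a,latencies_b Independent numeric samples (e.g. pooled
#'   normalized latencies per group).
#' @param alternative Tail convention, as in [stats::wilcox.test()].
#' @return A tibble with `W` and `p`.
#' @export
compare_group_latencies <- function(latencies_a, latencies_b,
                                    alternative = "two.sided") {
  if (length(latencies_a) == 0 || length(latencies_b) == 0) {
    abort("both groups must be non-empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(latencies_a, latencies_b,
                       alternative = alternative, exact = NULL,
                       correct = TRUE))
  tibble::tibble(W = unname(wt$statistic), p = wt$p.value)
}

#' Odds ratio and Fisher exact p for a 2x2 contingency table
#'
#' Rows index the groups (reference group first), columns the attribute
#' (attribute-present first). The reported odds ratio is the sample
#' cross-product ratio of attribute-present odds in the second group relative
#' to the first; the p-value is the two-tailed Fisher exact test.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A tibble with `odds_ratio` and `fisher_p`. A zero marginal yields
#'   `NA` odds ratio with a warning.
#' @export
contingency_odds_ratio <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  odds1 <- table[1, 1] / table[1, 2]
  odds2 <- table[2, 1] / table[2, 2]
  or <- odds2 / odds1
  if (!is.finite(or)) {
    warn("zero marginal: odds ratio undefined")
    or <- NA_real_
  }
  ft <- stats::fisher.test(table)
  tibble::tibble(odds_ratio = or, fisher_p = ft$p.value)
}
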