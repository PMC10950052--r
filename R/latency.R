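#' Model-predicted accumulation trajectory for one trial
#'
#' Builds the deterministic activity path the fitted race model predicts for
#' an observed trial, given a split of the non-decision time into a
#' pre-accumulation latency `tau1` (sensory encoding) and a post-accumulation
#' latency `tau2 = t0 - tau1` (motor execution). Each engaged accumulator sits
#' at its expected start level `z/2` until `tau1`, rises linearly, and is
#' frozen at the decision time `rt - tau2`. The winner's slope is set so it
#' reaches the bound exactly at decision time; losers rise at the cell-mean
#' drift rate, capped at the bound. The trajectory is the sum over engaged
#' accumulators.
#'
#' @param trial One-row data frame with `pu`, `au`, `n_options`, `rt`.
#' @param params An [lba_parameters()] object (the subject's fitted model).
#' @param tau1 Pre-accumulation latency in seconds, within `[0, t0]`.
#' @param fs Sampling rate of the output grid (Hz).
#' @return A tibble with columns `time` (0 .. rt) and `activity`, carrying
#'   attributes `tau1` and `tau2`.
#' @export
predict_activity <- function(trial, params, tau1, fs = 100) {
  stopifnot(nrow(trial) == 1)
  ci <- match(cell_label(trial$pu, trial$au), CELL_LEVELS)
  t0 <- params$t0[ci]
  if (tau1 < 0 || tau1 > t0) abort("`tau1` must lie in [0, t0]")
  if (trial$rt <= t0) abort("trial RT does not exceed the non-decision time")
  time <- seq(0, trial$rt, by = 1 / fs)
  act <- predicted_trajectory(time, rt = trial$rt, tau1 = tau1,
                              m = trial$n_options,
                              v = params$v[ci], b = params$b[ci],
                              z = params$z[ci], t0 = t0)
  out <- tibble::tibble(time = time, activity = act)
  attr(out, "tau1") <- unname(tau1)
  attr(out, "tau2") <- unname(t0 - tau1)
  out
}

# vectorized trajectory over a time grid (internal)
predicted_trajectory <- function(time, rt, tau1, m, v, b, z, t0) {
  dt <- rt - t0                      # accumulation duration
  z0 <- z / 2                        # expected start level
  u <- pmin(pmax(time - tau1, 0), dt)
  winner <- z0 + (b - z0) / dt * u
  if (m > 1) {
    loser <- pmin(z0 + v * u, b)
    winner + (m - 1) * loser
  } else {
    winner
  }
}

normalize_ranks <- function(x) {
  r <- rank(x)
  r <- r - mean(r)
  nrm <- sqrt(sum(r^2))
  if (nrm == 0) return(rep(0, length(r)))
  r / nrm
}

# Precompute, for one subject/ROI-set, everything the lag search reuses:
# the tau1 grid, per-trial envelope segment indices, and the normalized rank
# matrix of concatenated predictions (one column per candidate tau1).
prediction_rank_basis <- function(trials, params, env_time, fs,
                                  lag_step = 0.01) {
  idx <- match(cell_label(trials$pu, trials$au), CELL_LEVELS)
  t0 <- params$t0[idx]
  t0_grid <- min(t0)
  taus <- seq(0, t0_grid, by = lag_step)
  keep <- which(trials$rt > t0 & trials$rt <= max(env_time))
  if (length(keep) == 0) abort("no usable trials for the lag search")
  seg_idx <- lapply(keep, function(i) {
    which(env_time >= 0 & env_time <= trials$rt[i])
  })
  n_seg <- lengths(seg_idx)
  starts <- cumsum(c(1, n_seg[-length(n_seg)]))
  N <- sum(n_seg)
  if (N < 30) abort("fewer than 30 concatenated samples")
  P <- matrix(0, N, length(taus))
  for (j in seq_along(taus)) {
    pred <- numeric(N)
    for (kk in seq_along(keep)) {
      i <- keep[kk]
      tt <- env_time[seg_idx[[kk]]]
      pred[starts[kk]:(starts[kk] + n_seg[kk] - 1)] <-
        predicted_trajectory(tt, rt = trials$rt[i], tau1 = taus[j],
                             m = trials$n_options[i], v = params$v[idx[i]],
                             b = params$b[idx[i]], z = params$z[idx[i]],
                             t0 = t0[i])
    }
    P[, j] <- normalize_ranks(pred)
  }
  list(taus = taus, keep = keep, seg_idx = seg_idx, starts = starts,
       n_seg = n_seg, N = N, P = P, t0 = t0_grid)
}

concat_env <- function(env_mat, basis) {
  e <- numeric(basis$N)
  for (kk in seq_along(basis$keep)) {
    e[basis$starts[kk]:(basis$starts[kk] + basis$n_seg[kk] - 1)] <-
      env_mat[basis$keep[kk], basis$seg_idx[[kk]]]
  }
  e
}

best_lag <- function(env_concat, basis) {
  re <- normalize_ranks(env_concat)
  rho <- as.numeric(crossprod(basis$P, re))
  j <- which.max(abs(rho))          # ties resolve toward smaller tau1
  list(rho = rho[j], tau1 = basis$taus[j], tau2 = basis$t0 - basis$taus[j],
       rho_by_lag = rho)
}

#' Maximum lagged Spearman correlation between envelopes and predictions
#'
#' For each candidate pre-accumulation latency `tau1` on a grid from 0 to the
#' subject's non-decision time (step `lag_step`), all trial predictions are
#' rebuilt, trials are concatenated over the segment from coherence onset to
#' each RT, and the Spearman correlation with the identically concatenated
#' envelope is computed. Returns the `tau1` maximizing the absolute
#' correlation (ties toward smaller `tau1`), with `tau2 = t0 - tau1`.
#'
#' @param env An [envelope_array()] (or a trial x time matrix with a matching
#'   `time` attribute via `env_time`).
#' @param roi ROI name or index selecting one region from `env`.
#' @param trials Data frame of the subject's trials (`pu`, `au`, `n_options`,
#'   `rt`), row-aligned with the trial axis of `env`.
#' @param params The subject's fitted [lba_parameters()].
#' @param lag_step Lag grid step in seconds (default one envelope sample,
#'   0.01 s).
#' @return A list with `rho` (signed, at the maximizing lag), `tau1`, `tau2`
#'   and `rho_by_lag`.
#' @export
max_lagged_spearman <- function(env, roi = 1, trials, params,
                                lag_step = 0.01) {
  stopifnot(inherits(env, "envelope_array"))
  basis <- prediction_rank_basis(trials, params, env$time, env$fs, lag_step)
  env_mat <- env$data[, , roi, drop = TRUE]
  best_lag(concat_env(env_mat, basis), basis)
}

#' One-sample sign test on per-subject correlation values
#'
#' Applied to Fisher-transformed per-subject correlations: counts the
#' positive signs among non-zero values, forms a Z-score from the normal
#' approximation to the binomial with continuity correction, and reports the
#' exact two-tailed binomial p-value. Exact zeros are dropped (their count is
#' returned).
#'
#' @param x Numeric vector (one value per subject), typically `atanh(rho)`.
#' @return A list with `z`, `p`, `n_pos`, `n` (non-zero count) and
#'   `n_dropped`.
#' @export
roi_sign_test <- function(x) {
  assert_finite(x, "x")
  nz <- x[x != 0]
  n <- length(nz)
  if (n < 5) abort("need at least 5 non-zero values for the sign test")
  k <- sum(nz > 0)
  centred <- k - n / 2
  cc <- 0.5 * sign(centred)
  z <- if (centred == 0) 0 else (centred - cc) / (sqrt(n) / 2)
  p <- min(1, 2 * stats::pbinom(min(k, n - k), n, 0.5))
  list(z = z, p = p, n_pos = k, n = n, n_dropped = length(x) - n)
}

#' Phase-randomized surrogate of a time-series
#'
#' Preserves the amplitude spectrum (hence mean and autocorrelation) exactly
#' while replacing the phases of the positive frequencies with i.i.d. uniform
#' draws; conjugate symmetry keeps the output real.
#'
#' @param x Real series, length >= 16.
#' @param seed Integer seed.
#' @return Surrogate series, same length as `x`.
#' @export
phase_randomize <- function(x, seed = 1) {
  if (length(x) < 16) abort("series too short to phase-randomize")
  with_seed(seed, phase_randomize_matrix(matrix(x, ncol = 1))[, 1])
}

# Columns of `m` are independent series; randomizes each column with phases
# from the current RNG stream.
phase_randomize_matrix <- function(m) {
  n <- nrow(m)
  X <- stats::mvfft(m)
  half <- if (n %% 2 == 0) (n / 2 - 1) else ((n - 1) / 2)
  if (half > 0) {
    ph <- matrix(runif(half * ncol(m), 0, 2 * pi), half, ncol(m))
    rot <- exp(1i * ph)
    X[2:(half + 1), ] <- X[2:(half + 1), , drop = FALSE] * rot
    X[n:(n - half + 1), ] <- Conj(X[2:(half + 1), , drop = FALSE])
  }
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Per-subject, per-ROI latency estimates
#'
#' Runs the lag search of [max_lagged_spearman()] for every ROI of every
#' subject and returns one tidy row per (subject, ROI).
#'
#' @param envelopes Named list of [envelope_array()] objects, one per subject.
#' @param behaviour Trial table with a `subject` column plus `pu`, `au`,
#'   `n_options`, `rt`; rows per subject must align with the trial axis of
#'   that subject's envelope array.
#' @param fits Named list of [fit_lba()] results (or `lba_parameters`), one
#'   per subject.
#' @param lag_step Lag grid step (s).
#' @return A tibble: `subject`, `roi`, `rho`, `fisher_z`, `tau1`, `tau2`,
#'   `t0`, `norm_latency` (`tau1 / t0`).
#' @export
subject_roi_latencies <- function(envelopes, behaviour, fits,
                                  lag_step = 0.01) {
  purrr::map_dfr(names(envelopes), function(sid) {
    env <- envelopes[[sid]]
    trials <- behaviour[behaviour$subject == sid, , drop = FALSE]
    fit <- fits[[sid]]
    params <- if (inherits(fit, "lba_fit")) fit$params else fit
    basis <- prediction_rank_basis(trials, params, env$time, env$fs, lag_step)
    purrr::map_dfr(seq_along(env$roi), function(r) {
      res <- best_lag(concat_env(env$data[, , r, drop = TRUE], basis), basis)
      tibble::tibble(subject = sid, roi = env$roi[r], rho = res$rho,
                     fisher_z = atanh(pmin(pmax(res$rho, -1 + 1e-12),
                                           1 - 1e-12)),
                     tau1 = res$tau1, tau2 = res$tau2, t0 = basis$t0,
                     norm_latency = res$tau1 / basis$t0)
    })
  })
}

#' Group-level latency map
#'
#' Aggregates per-subject latency estimates into one row per ROI: the mean
#' signed correlation, the sign-test Z and p on the Fisher-transformed
#' correlations, and mean latencies.
#'
#' @param latencies Output of [subject_roi_latencies()].
#' @return A tibble keyed by `roi` with `n_subjects`, `mean_rho`,
#'   `sign_test_z`, `p_sign`, `mean_tau1`, `mean_norm_latency`.
#' @export
latency_map <- function(latencies) {
  dplyr::summarise(
    dplyr::group_by(latencies, .data$roi),
    n_subjects = dplyr::n(),
    mean_rho = mean(.data$rho),
    sign_test_z = roi_sign_test(.data$fisher_z)$z,
    p_sign = roi_sign_test(.data$fisher_z)$p,
    mean_tau1 = mean(.data$tau1),
    mean_norm_latency = mean(.data$norm_latency),
    .groups = "drop")
}

#' Phase-randomization permutation p-values for a latency map
#'
#' Repeats the full latency analysis `n_iter` times on phase-randomized
#' surrogates of the envelope signal, rebuilding the group sign-test Z per
#' ROI each time, and reports the two-tailed permutation p-value: the
#' (+1-smoothed) proportion of null |Z| at least as large as the observed
#' |Z|. Each surrogate randomizes the phases of the concatenated per-ROI
#' envelope series, preserving its amplitude spectrum while destroying both
#' within-trial and across-trial alignment with the model predictions.
#'
#' @inheritParams subject_roi_latencies
#' @param n_iter Number of surrogate iterations (study scale 10000).
#' @param seed Integer seed.
#' @return A tibble `roi`, `observed_z`, `p_perm`.
#' @export
permutation_null_pvalues <- function(envelopes, behaviour, fits,
                                     n_iter = 10000, seed = 1,
                                     lag_step = 0.01) {
  if (n_iter < 100) warn("fewer than 100 iterations: p-values will be coarse")
  subjects <- names(envelopes)
  prep <- lapply(subjects, function(sid) {
    env <- envelopes[[sid]]
    trials <- behaviour[behaviour$subject == sid, , drop = FALSE]
    fit <- fits[[sid]]
    params <- if (inherits(fit, "lba_fit")) fit$params else fit
    basis <- prediction_rank_basis(trials, params, env$time, env$fs, lag_step)
    list(env = env, basis = basis)
  })
  names(prep) <- subjects
  rois <- prep[[1]]$env$roi
  n_roi <- length(rois)

  observed <- matrix(0, length(subjects), n_roi,
                     dimnames = list(subjects, rois))
  for (si in seq_along(subjects)) {
    p <- prep[[si]]
    for (r in seq_len(n_roi)) {
      res <- best_lag(concat_env(p$env$data[, , r, drop = TRUE], p$basis),
                      p$basis)
      observed[si, r] <- atanh(pmin(pmax(res$rho, -1 + 1e-12), 1 - 1e-12))
    }
  }
  obs_z <- apply(observed, 2, function(col) roi_sign_test(col)$z)

  # concatenated observed envelopes, fixed across iterations
  concat <- lapply(seq_along(subjects), function(si) {
    p <- prep[[si]]
    vapply(seq_len(n_roi), function(r) {
      concat_env(p$env$data[, , r, drop = TRUE], p$basis)
    }, numeric(p$basis$N))
  })

  null_z <- matrix(0, n_iter, n_roi)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      fz <- matrix(0, length(subjects), n_roi)
      for (si in seq_along(subjects)) {
        p <- prep[[si]]
        sur <- phase_randomize_matrix(concat[[si]])
        for (r in seq_len(n_roi)) {
          res <- best_lag(sur[, r], p$basis)
          fz[si, r] <- atanh(pmin(pmax(res$rho, -1 + 1e-12), 1 - 1e-12))
        }
      }
      null_z[it, ] <- apply(fz, 2, function(col) roi_sign_test(col)$z)
    }
  })
  p_perm <- vapply(seq_len(n_roi), function(r) {
    (1 + sum(abs(null_z[, r]) >= abs(obs_z[r]))) / (n_iter + 1)
  }, 0)
  tibble::tibble(roi = rois, observed_z = unname(obs_z), p_perm = p_perm)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control across ROIs (and bands, when the
#' input pools several maps).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q Target FDR level for the discovery flags.
#' @return A tibble with `p`, `q_value` (monotone BH-adjusted values) and
#'   `discovery`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(pvals, method = "BH")
  tibble::tibble(p = pvals, q_value = qv, discovery = qv <= q)
}
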