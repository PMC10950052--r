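#' Specification of a synthetic cohort
#'
#' Bundles every ground-truth quantity the generators need: group sizes, the
#' 2x2 trial design, group-level LBA parameters, the per-ROI accumulation-
#' onset (tau1) profiles along the caudo-rostral axis, and the envelope noise
#' model. Defaults mirror the study design this package targets: 160 trials
#' per condition cell (640 per subject), drift rates that fall with either
#' kind of uncertainty, a patient-like group with blunted drift reactivity to
#' action uncertainty, a 150 ms caudo-rostral tau1 span over 8 dorsal-path
#' ROIs for the control-like profile and a flat profile for the patient-like
#' one.
#'
#' @param n_controls,n_patients Subjects per group.
#' @param trials_per_cell Trials in each of the four condition cells.
#' @param control_v,patient_v Named length-4 drift vectors (cells
#'   low_low, low_high, high_low, high_high; perceptual uncertainty first).
#' @param b,z,t0,s Shared LBA parameters (drift-only variant generates the
#'   data).
#' @param subject_cv Between-subject lognormal coefficient of variation
#'   applied to v, b, z, t0.
#' @param n_roi Total ROIs; the first `n_dorsal` form the dorsal-path subset.
#' @param n_dorsal Dorsal-path ROIs carrying the latency profile.
#' @param control_tau1_range Caudal-to-rostral tau1 range (s) for the
#'   control-like profile.
#' @param patient_tau1 Flat tau1 (s) for the patient-like profile.
#' @param desync_amplitude Peak desynchronization depth in percent-change
#'   units (negative-going ramps of this magnitude).
#' @param embed_signal If `FALSE`, envelopes contain noise only (the
#'   no-signal null condition); the noise level is still set by
#'   `desync_amplitude / snr`.
#' @param snr Ramp amplitude over noise-envelope SD in the baseline window.
#' @param oneoverf_exponent Spectral exponent of the 1/f noise component.
#' @param fs,epoch Envelope sampling rate (Hz) and epoch (s).
#' @param seed Master seed; all generators derive their streams from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 21, n_patients = 17,
                        trials_per_cell = 160,
                        control_v = c(low_low = 3.5, low_high = 2.5,
                                      high_low = 3.0, high_high = 2.0),
                        patient_v = c(low_low = 2.6, low_high = 2.3,
                                      high_low = 2.2, high_high = 1.8),
                        b = 1.2, z = 0.6, t0 = 0.35, s = 1,
                        subject_cv = 0.1,
                        n_roi = 16, n_dorsal = 8,
                        control_tau1_range = c(0.05, 0.20),
                        patient_tau1 = 0.08,
                        desync_amplitude = 20, snr = 2,
                        embed_signal = TRUE,
                        oneoverf_exponent = 1,
                        fs = 100, epoch = c(-0.5, 1.5), seed = 1) {
  stopifnot(n_controls >= 0, n_patients >= 0,
            n_controls + n_patients >= 1, trials_per_cell >= 1,
            snr > 0, n_dorsal <= n_roi)
  if (max(control_tau1_range) >= t0 || patient_tau1 >= t0) {
    abort("tau1 profiles must stay below the non-decision time")
  }
  structure(
    list(n_controls = n_controls, n_patients = n_patients,
         trials_per_cell = trials_per_cell,
         control_v = control_v, patient_v = patient_v,
         b = b, z = z, t0 = t0, s = s, subject_cv = subject_cv,
         n_roi = n_roi, n_dorsal = n_dorsal,
         control_tau1_range = control_tau1_range,
         patient_tau1 = patient_tau1,
         desync_amplitude = desync_amplitude, snr = snr,
         embed_signal = embed_signal,
         oneoverf_exponent = oneoverf_exponent,
         fs = fs, epoch = epoch, seed = seed),
    class = "cohort_spec")
}

#' ROI metadata table for a cohort spec
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `roi`, `hemisphere`, `dorsal_path` and
#'   `caudo_rostral_position` (dorsal-path ROIs are strictly ordered along
#'   the axis).
#' @export
roi_table <- function(spec) {
  n <- spec$n_roi
  tibble::tibble(
    roi = sprintf("roi%02d", seq_len(n)),
    hemisphere = "L",
    dorsal_path = seq_len(n) <= spec$n_dorsal,
    caudo_rostral_position = ifelse(seq_len(n) <= spec$n_dorsal,
                                    seq_len(n), NA_real_))
}

# true tau1 per ROI for one group profile
true_tau1_profile <- function(spec, group) {
  rt <- roi_table(spec)
  tau1 <- numeric(spec$n_roi)
  if (group == "control") {
    tau1[rt$dorsal_path] <- seq(spec$control_tau1_range[1],
                                spec$control_tau1_range[2],
                                length.out = spec$n_dorsal)
  } else {
    tau1[rt$dorsal_path] <- spec$patient_tau1
  }
  mid <- mean(if (group == "control") spec$control_tau1_range
              else rep(spec$patient_tau1, 2))
  tau1[!rt$dorsal_path] <- mid
  stats::setNames(tau1, rt$roi)
}

subject_params <- function(spec, group, jit) {
  v <- if (group == "control") spec$control_v else spec$patient_v
  lba_parameters(v = v * jit[1:4], b = spec$b * jit[5],
                 z = min(spec$z * jit[6], spec$b * jit[5] * 0.95),
                 t0 = spec$t0 * jit[7], s = spec$s)
}

# lognormal multiplicative jitter with a given CV
lognormal_jitter <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate cohort behaviour from the drift-only LBA variant
#'
#' Simulates the full 2x2 design for every subject of both groups, with
#' subject-level lognormal parameter jitter. The output uses the same schema
#' the fitting stage reads.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `trials` (tibble: `subject`, `group`, `pu`, `au`,
#'   `n_options`, `response`, `rt`) and `truth` (per-subject generating
#'   parameters).
#' @export
generate_cohort_behaviour <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  design <- tidyr::expand_grid(pu = c("low", "high"), au = c("low", "high"),
                               rep = seq_len(spec$trials_per_cell))
  design$n_options <- ifelse(design$au == "low", 1L, 3L)
  design$rep <- NULL

  subjects <- c(sprintf("ctrl%02d", seq_len(spec$n_controls)),
                sprintf("pat%02d", seq_len(spec$n_patients)))
  groups <- rep(c("control", "patient"),
                c(spec$n_controls, spec$n_patients))

  truth <- list()
  trials <- purrr::map_dfr(seq_along(subjects), function(i) {
    jit <- with_seed(derive_seed(spec$seed, 1000 + i),
                     lognormal_jitter(7, spec$subject_cv))
    params <- subject_params(spec, groups[i], jit)
    truth[[subjects[i]]] <<- params
    sim <- simulate_lba(params, design,
                        seed = derive_seed(spec$seed, 2000 + i))
    sim$subject <- subjects[i]
    sim$group <- groups[i]
    sim[, c("subject", "group", "pu", "au", "n_options", "response", "rt")]
  })
  list(trials = trials, truth = truth)
}

# 1/f noise via spectral shaping of white noise (Hermitian-symmetric shape)
oneoverf_noise <- function(n, exponent) {
  white <- rnorm(n)
  X <- stats::fft(white)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k)
  freq[1] <- 1                          # avoid division by zero at DC
  shape <- 1 / (freq^(exponent / 2))
  shaped <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Generate ROI power envelopes with embedded accumulation ramps
#'
#' For every subject, trial and ROI the synthetic envelope is baseline noise
#' plus a negative-going copy of the model-predicted accumulation trajectory
#' (the subject's true generating parameters, shifted by the ROI's true
#' tau1), scaled to the requested desynchronization depth. Noise is 1/f plus
#' band-limited Gaussian noise, scaled so that the ramp amplitude over the
#' noise SD in the baseline window equals `spec$snr`. The true tau1 map is
#' stored as ground-truth metadata only.
#'
#' @param spec A [cohort_spec()].
#' @param behaviour Output of [generate_cohort_behaviour()] from the same
#'   spec.
#' @return Named list of [envelope_array()] objects, one per subject, each
#'   carrying `truth$tau1` (per-ROI seconds) and `truth$params`.
#' @export
generate_envelopes <- function(spec, behaviour) {
  stopifnot(inherits(spec, "cohort_spec"))
  time <- seq(spec$epoch[1], spec$epoch[2], by = 1 / spec$fs)
  n_time <- length(time)
  base_idx <- time >= -0.4 & time <= -0.1
  rt_meta <- roi_table(spec)
  subjects <- unique(behaviour$trials$subject)

  out <- lapply(subjects, function(sid) {
    trials <- behaviour$trials[behaviour$trials$subject == sid, ,
                               drop = FALSE]
    params <- behaviour$truth[[sid]]
    group <- trials$group[1]
    tau1_map <- true_tau1_profile(spec, group)
    if (any(tau1_map >= min(params$t0))) {
      abort("tau1 profile reaches the subject's non-decision time")
    }
    n_trial <- nrow(trials)
    idx <- match(cell_label(trials$pu, trials$au), CELL_LEVELS)

    arr <- with_seed(derive_seed(spec$seed, 3000 + match(sid, subjects)), {
      a <- array(0, c(n_trial, n_time, spec$n_roi),
                 dimnames = list(NULL, NULL, rt_meta$roi))
      noise_sd <- spec$desync_amplitude / spec$snr
      for (r in seq_len(spec$n_roi)) {
        tau1 <- tau1_map[r]
        # one global (per-ROI) gain keeps the envelope a single monotone
        # transform of the predicted activity across all trials
        trajs <- vector("list", n_trial)
        for (tr in seq_len(n_trial)) {
          rt_i <- trials$rt[tr]
          t0_i <- params$t0[idx[tr]]
          if (isTRUE(spec$embed_signal) && rt_i > t0_i && tau1 < t0_i) {
            on <- which(time >= 0 & time <= rt_i)
            traj <- predicted_trajectory(
              time[on], rt = rt_i, tau1 = tau1, m = trials$n_options[tr],
              v = params$v[idx[tr]], b = params$b[idx[tr]],
              z = params$z[idx[tr]], t0 = t0_i)
            trajs[[tr]] <- list(on = on, traj = traj)
          }
        }
        peaks <- vapply(trajs, function(x) {
          if (is.null(x)) NA_real_ else diff(range(x$traj))
        }, 0)
        gain <- if (all(is.na(peaks))) 0 else
          spec$desync_amplitude / mean(peaks, na.rm = TRUE)
        for (tr in seq_len(n_trial)) {
          noise <- oneoverf_noise(n_time, spec$oneoverf_exponent) +
            rnorm(n_time, 0, 0.5)
          noise <- noise / stats::sd(noise[base_idx])
          sig <- numeric(n_time)
          if (!is.null(trajs[[tr]])) {
            on <- trajs[[tr]]$on
            # one shared negative scaling of the predicted activity (no
            # per-trial offset), so the envelope is a single monotone
            # transform of the prediction across the whole concatenation
            sig[on] <- -gain * trajs[[tr]]$traj
            # hold the post-decision level to the end of the epoch
            sig[time > trials$rt[tr]] <- sig[on[length(on)]]
          }
          a[tr, , r] <- sig + noise_sd * noise
        }
      }
      a
    })
    envelope_array(arr, time = time, fs = spec$fs, band = "beta",
                   subject = sid,
                   truth = list(tau1 = tau1_map, params = params,
                                group = group))
  })
  names(out) <- subjects
  out
}

#' Generate psychophysics count data from a Log-Quick observer
#'
#' Binomial draws at each coherence level with success probability given by
#' the psychometric function.
#'
#' @param fit A [psychometric_fit()] describing the observer.
#' @param levels Coherence levels (linear units); default 8 log-spaced
#'   levels in (0, 0.9].
#' @param n_per_level Trials per level (study scale 32).
#' @param seed Integer seed.
#' @return A tibble `level`, `n_correct`, `n_total`.
#' @export
generate_psychophysics <- function(fit,
                                   levels = 10^seq(log10(0.05), log10(0.9),
                                                   length.out = 8),
                                   n_per_level = 32, seed = 1) {
  stopifnot(inherits(fit, "psychometric_fit"))
  p <- logquick_probability(log10(levels), fit)
  k <- with_seed(seed, rbinom(length(levels), n_per_level, p))
  tibble::tibble(level = levels, n_correct = k, n_total = n_per_level)
}
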