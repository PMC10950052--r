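FREQ_BANDS <- list(beta = c(13, 30), gamma = c(31, 90))

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' giving approximately unit pass-band gain with no phase delay.
#'
#' @param x Numeric time-series.
#' @param band Length-2 numeric `(lo, hi)` in Hz, or a band name
#'   (`"beta"` = 13-30 Hz, `"gamma"` = 31-90 Hz).
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @param order Filter order (per pass).
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, band, fs, order = 4) {
  band <- resolve_band(band)
  if (fs <= 2 * band[2]) abort("band must lie below the Nyquist frequency")
  assert_finite(x, "x")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

resolve_band <- function(band) {
  if (is.character(band)) {
    if (!band %in% names(FREQ_BANDS)) {
      abort(sprintf("unknown band '%s'; use %s or numeric (lo, hi)",
                    band, paste(names(FREQ_BANDS), collapse = "/")))
    }
    band <- FREQ_BANDS[[band]]
  }
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  band
}

#' Instantaneous amplitude via the analytic signal
#'
#' Modulus of the analytic signal, computed by zeroing the negative-frequency
#' half of the discrete Fourier transform and doubling the positive half.
#'
#' @param x Real time-series, length >= 16.
#' @return Envelope (non-negative), same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 16) abort("series too short for an envelope (need >= 16 samples)")
  assert_finite(x, "x")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' First principal component of an ROI's vertices
#'
#' Reduces a vertices x time matrix to one time-course: the scores of the
#' leading principal component across vertices, sign-aligned to correlate
#' positively with the vertex mean.
#'
#' @param mat Numeric matrix, vertices in rows, time in columns.
#' @return A list with `scores` (time-course), `loadings` (unit-norm vertex
#'   weights) and `explained` (fraction of variance carried).
#' @export
roi_first_pc <- function(mat) {
  mat <- as.matrix(mat)
  assert_finite(mat, "mat")
  if (all(mat == 0)) abort("all-zero input has no principal component")
  # time points are observations, vertices are variables
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  vm <- colMeans(mat)
  if (stats::sd(vm) > 0 && stats::cor(scores, vm) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = as.numeric(scores), loadings = as.numeric(loadings),
       explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

# Anti-aliased resampling onto a (possibly non-integer-ratio) coarser grid:
# zero-phase Butterworth low-pass below the target Nyquist, then linear
# interpolation onto the new time axis.
resample_series <- function(x, time_in, time_out, fs_out) {
  fs_in <- 1 / stats::median(diff(time_in))
  if (fs_in > fs_out) {
    bf <- signal::butter(4, (0.8 * fs_out / 2) / (fs_in / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  stats::approx(time_in, x, xout = time_out, rule = 2)$y
}

#' Construct an envelope array
#'
#' Container for trial-wise, baseline-normalized band power: a 3-D numeric
#' array (trial x time x ROI) with its time axis and processing metadata.
#'
#' @param data 3-D array, trial x time x ROI (dimnames on the ROI axis label
#'   the regions).
#' @param time Time axis in seconds relative to coherence onset.
#' @param fs Sampling rate of `time` in Hz.
#' @param band Band name or `(lo, hi)` Hz.
#' @param baseline_window Length-2 window (s) used for normalization.
#' @param subject Subject identifier.
#' @param truth Optional list of generator ground truth (kept as metadata,
#'   never consumed by analysis functions).
#' @return An object of class `envelope_array`.
#' @export
envelope_array <- function(data, time, fs = 100, band = "beta",
                           baseline_window = c(-0.4, -0.1),
                           subject = NA_character_, truth = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(time))
  if (max(abs(diff(time) - 1 / fs)) > 1e-6) {
    abort("`time` must be uniformly sampled at `fs`")
  }
  if (anyNA(data)) abort("envelope data must not contain NAs")
  structure(
    list(data = data, time = time, fs = fs, band = band,
         baseline_window = baseline_window, subject = subject,
         roi = dimnames(data)[[3]] %||% paste0("roi", seq_len(dim(data)[3])),
         truth = truth),
    class = "envelope_array")
}

#' @export
print.envelope_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Envelope array: %d trials x %d samples x %d ROIs (%s band, %g Hz)\n",
    d[1], d[2], d[3], if (is.character(x$band)) x$band else "custom", x$fs))
  cat(sprintf("  epoch %.2f..%.2f s, baseline %.2f..%.2f s, subject %s\n",
              min(x$time), max(x$time), x$baseline_window[1],
              x$baseline_window[2], x$subject))
  invisible(x)
}

#' @method as_tibble envelope_array
#' @export
as_tibble.envelope_array <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    subject = x$subject,
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(rep(x$time, each = d[1]), times = d[3]),
    roi = rep(x$roi, each = d[1] * d[2]),
    power = as.numeric(x$data)
  )
}

#' Turn raw ROI time-series into baseline-normalized power envelopes
#'
#' The processing chain applied per trial and ROI: band-pass filter at the
#' native rate, analytic-signal amplitude, anti-aliased resampling to the
#' target rate, then per-trial percent change against the baseline-window
#' mean: `100 * (x - mu_base) / mu_base`.
#'
#' @param raw 3-D array (trial x time x ROI) of raw ROI series.
#' @param time_in Time axis of `raw` in seconds (coherence onset at 0).
#' @param band Band name or `(lo, hi)` Hz.
#' @param fs_in Native sampling rate (Hz).
#' @param fs_out Output rate (default 100 Hz).
#' @param baseline_window Window (s) whose mean amplitude anchors the percent
#'   change; must be covered by the epoch and yield positive means.
#' @param subject Subject identifier carried into the result.
#' @return An [envelope_array()].
#' @export
preprocess_envelopes <- function(raw, time_in, band = "beta", fs_in,
                                 fs_out = 100,
                                 baseline_window = c(-0.4, -0.1),
                                 subject = NA_character_) {
  stopifnot(length(dim(raw)) == 3, dim(raw)[2] == length(time_in))
  if (min(time_in) > baseline_window[1] || max(time_in) < baseline_window[2]) {
    abort("epoch does not cover the baseline window")
  }
  n_trial <- dim(raw)[1]; n_roi <- dim(raw)[3]
  time_out <- seq(min(time_in), max(time_in), by = 1 / fs_out)
  base_idx <- time_out >= baseline_window[1] & time_out <= baseline_window[2]
  out <- array(0, c(n_trial, length(time_out), n_roi),
               dimnames = list(NULL, NULL, dimnames(raw)[[3]]))
  for (r in seq_len(n_roi)) {
    for (tr in seq_len(n_trial)) {
      env <- hilbert_envelope(bandpass(raw[tr, , r], band, fs_in))
      env <- resample_series(env, time_in, time_out, fs_out)
      mu <- mean(env[base_idx])
      if (mu <= 0) abort("baseline mean power must be positive")
      out[tr, , r] <- 100 * (env - mu) / mu
    }
  }
  envelope_array(out, time = time_out, fs = fs_out, band = band,
                 baseline_window = baseline_window, subject = subject)
}

#' Write / read an envelope array as plain text
#'
#' Serializes the 3-D array to a CSV of long-format values plus a JSON
#' metadata sidecar, a text-only interchange format.
#'
#' @param x An `envelope_array`.
#' @param path Base path (without extension); writes `<path>.csv` and
#'   `<path>.json`.
#' @return `write_envelope_array` returns `path` invisibly;
#'   `read_envelope_array` returns the reconstructed `envelope_array`.
#' @export
write_envelope_array <- function(x, path) {
  stopifnot(inherits(x, "envelope_array"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required for envelope serialization")
  }
  utils::write.csv(as_tibble(x)[, c("trial", "time", "roi", "power")],
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- list(fs = x$fs, band = x$band, baseline_window = x$baseline_window,
               subject = x$subject, time = range(x$time), truth = x$truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname write_envelope_array
#' @export
read_envelope_array <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required for envelope serialization")
  }
  df <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rois <- unique(df$roi)
  times <- sort(unique(df$time))
  trials <- sort(unique(df$trial))
  arr <- array(NA_real_, c(length(trials), length(times), length(rois)),
               dimnames = list(NULL, NULL, rois))
  arr[cbind(match(df$trial, trials), match(df$time, times),
            match(df$roi, rois))] <- df$power
  envelope_array(arr, time = times, fs = meta$fs, band = meta$band,
                 baseline_window = meta$baseline_window,
                 subject = meta$subject, truth = meta$truth)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Plot trial-averaged envelopes per ROI
#'
#' @param object An `envelope_array`.
#' @param rois Optional subset of ROI names.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot envelope_array
#' @export
autoplot.envelope_array <- function(object, rois = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(rois)) df <- dplyr::filter(df, .data$roi %in% rois)
  df <- dplyr::summarise(dplyr::group_by(df, .data$roi, .data$time),
                         power = mean(.data$power), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$power,
                                   colour = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time from coherence onset (s)",
                  y = "power (% change from baseline)") +
    ggplot2::theme_minimal()
}
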