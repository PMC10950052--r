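#' Construct a Log-Quick psychometric fit object
#'
#' The Log-Quick function describes the probability of a correct response as a
#' function of stimulus strength on a log axis,
#' \deqn{F_{\log}(x) = 1 - 2^{-10^{\beta (x - \alpha)}},}
#' scaled to the task's guess and lapse rates,
#' \deqn{P(x) = \gamma + (1 - \gamma - \lambda) F_{\log}(x).}
#' Here `x` is log10 motion coherence, `alpha` the threshold on that axis,
#' `beta` the (dimensionless) slope, `gamma` the guess rate and `lamda` the
#' lapse rate.
#'
#' @param alpha Threshold on the log10-coherence axis.
#' @param beta Slope, must be positive.
#' @param gamma Guess rate in `[0, 1)`.
#' @param lamda Lapse rate in `[0, 1)`; `gamma + lamda` must be below 1.
#' @param chance Task chance level in `(0, 1)` (e.g. 0.25 for a 4-alternative
#'   task); used for bounding `gamma` during fitting and kept as metadata.
#' @param loglik Optional achieved log-likelihood (filled by
#'   [fit_psychometric()]).
#' @param boundary Logical flag marking a fit that ended on a parameter bound.
#' @return An object of class `psychometric_fit`.
#' @export
psychometric_fit <- function(alpha, beta, gamma = 0, lamda = 0, chance = 0.25,
                             loglik = NA_real_, boundary = FALSE) {
  for (nm in c("alpha", "beta", "gamma", "lamda", "chance")) {
    assert_finite(get(nm), nm)
  }
  if (beta <= 0) abort("`beta` must be positive")
  if (gamma < 0 || gamma >= 1 || lamda < 0 || lamda >= 1) {
    abort("`gamma` and `lamda` must lie in [0, 1)")
  }
  if (gamma + lamda >= 1) abort("`gamma` + `lamda` must be below 1")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lamda = lamda,
         chance = chance, loglik = loglik, boundary = boundary),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Log-Quick psychometric fit\n")
  cat(sprintf("  alpha (log10 threshold): %.4f  (coherence %.4f)\n",
              x$alpha, 10^x$alpha))
  cat(sprintf("  beta: %.3f  gamma: %.3f  lamda: %.3f\n",
              x$beta, x$gamma, x$lamda))
  if (is.finite(x$loglik)) cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  if (isTRUE(x$boundary)) cat("  note: fit ended on a parameter bound\n")
  invisible(x)
}

#' Log-Quick probability of a correct response
#'
#' Evaluates the scaled Log-Quick function at `x` (log10 coherence).
#'
#' @param x Numeric vector on the log10-coherence axis.
#' @param fit A [psychometric_fit()] object.
#' @return Probabilities in `[gamma, 1 - lamda]`, same length as `x`.
#' @examples
#' f <- psychometric_fit(alpha = -0.5, beta = 2, gamma = 0.25, lamda = 0.02)
#' logquick_probability(f$alpha, f)  # 0.25 + 0.73 * 0.5
#' @export
logquick_probability <- function(x, fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  assert_finite(x, "x")
  flog <- 1 - 2^(-(10^(fit$beta * (x - fit$alpha))))
  fit$gamma + (1 - fit$gamma - fit$lamda) * flog
}

#' Invert the psychometric function at a target accuracy
#'
#' Analytic inversion of the Log-Quick function: returns the log10 coherence
#' `x` at which the predicted probability of a correct response equals
#' `p_target`. The companion coherence-domain value is `10^x`.
#'
#' @param fit A [psychometric_fit()] object.
#' @param p_target Probabilities strictly inside `(gamma, 1 - lamda)`. The
#'   defaults `c(0.75, 0.90)` are the two percentiles used to set high and low
#'   perceptual-uncertainty stimulus levels.
#' @return A tibble with columns `p_target`, `x` (log10 coherence) and
#'   `coherence`.
#' @export
coherence_for_accuracy <- function(fit, p_target = c(0.75, 0.90)) {
  stopifnot(inherits(fit, "psychometric_fit"))
  lo <- fit$gamma
  hi <- 1 - fit$lamda
  if (any(p_target <= lo | p_target >= hi)) {
    abort(sprintf(
      "`p_target` must lie strictly inside the attainable range (%.4f, %.4f)",
      lo, hi))
  }
  flog <- (p_target - fit$gamma) / (1 - fit$gamma - fit$lamda)
  x <- fit$alpha + log10(-log2(1 - flog)) / fit$beta
  tibble::tibble(p_target = p_target, x = x, coherence = 10^x)
}

logquick_negll <- function(par, x, k, n) {
  # par = (alpha, beta, gamma, lamda) on the natural scale
  flog <- 1 - 2^(-(10^(par[2] * (x - par[1]))))
  p <- par[3] + (1 - par[3] - par[4]) * flog
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

#' Fit the Log-Quick psychometric function by maximum likelihood
#'
#' Maximizes the binomial log-likelihood of per-level correct counts over
#' `(alpha, beta, gamma, lamda)` with box constraints, restarting from a
#' Latin-hypercube of initial values for robustness.
#'
#' @param data Data frame with columns `level` (coherence, linear units),
#'   `n_correct` and `n_total`.
#' @param chance Task chance level; `gamma` is bounded to
#'   `[0, chance + 0.1]` and `lamda` to `[0, 0.1]`.
#' @param n_starts Number of Latin-hypercube restarts.
#' @param seed Integer seed making the restarts reproducible.
#' @return A `psychometric_fit` with the achieved log-likelihood; a
#'   `boundary = TRUE` flag (with a warning) marks degenerate data that pushed
#'   a parameter onto a bound.
#' @export
fit_psychometric <- function(data, chance = 0.25, n_starts = 10, seed = 1) {
  stopifnot(all(c("level", "n_correct", "n_total") %in% names(data)))
  x <- log10(data$level)
  k <- data$n_correct
  n <- data$n_total
  assert_finite(x, "log10(level)")
  assert_finite(k, "n_correct")
  assert_finite(n, "n_total")
  if (any(k > n) || any(k < 0)) abort("`n_correct` must lie in [0, n_total]")
  if (length(unique(x)) < 4) abort("need at least 4 distinct stimulus levels")

  lower <- c(alpha = min(x) - 1, beta = 0.05, gamma = 0, lamda = 0)
  upper <- c(alpha = max(x) + 1, beta = 20, gamma = chance + 0.1, lamda = 0.1)

  starts <- with_seed(seed, lhs::randomLHS(n_starts, 4))
  starts <- sweep(sweep(starts, 2, upper - lower, `*`), 2, lower, `+`)
  # always include a sensible centre start
  starts <- rbind(c(stats::median(x), 2, chance, 0.02), starts)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], logquick_negll, x = x, k = k, n = n,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("all optimization starts failed")

  on_bound <- any(abs(best$par - lower) < 1e-6 | abs(best$par - upper) < 1e-6)
  degenerate <- all(k == n) || all(k == 0)
  if (on_bound && degenerate) {
    warn("psychometric fit hit a parameter bound on degenerate data")
  }
  psychometric_fit(alpha = best$par[[1]], beta = best$par[[2]],
                   gamma = best$par[[3]], lamda = best$par[[4]],
                   chance = chance, loglik = -best$value,
                   boundary = on_bound)
}

#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "gamma", "lamda"),
    estimate = c(x$alpha, x$beta, x$gamma, x$lamda)
  )
}

#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, chance = x$chance,
                 boundary = x$boundary)
}

#' Plot a psychometric fit over its data
#'
#' @param object A `psychometric_fit`.
#' @param data Optional data frame with `level`, `n_correct`, `n_total` to
#'   overlay observed proportions.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, data = NULL, ...) {
  rng <- if (!is.null(data)) range(log10(data$level)) else object$alpha + c(-1, 1)
  grid <- tibble::tibble(x = seq(rng[1], rng[2], length.out = 200))
  grid$p <- logquick_probability(grid$x, object)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "log10 coherence", y = "P(correct)") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    obs <- tibble::tibble(x = log10(data$level),
                          p = data$n_correct / data$n_total)
    p <- p + ggplot2::geom_point(data = obs)
  }
  p
}
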