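#' Linear ballistic accumulator parameters
#'
#' In the LBA, each response option has an independent accumulator whose
#' activation starts at a level drawn from Uniform\[0, z\], then rises linearly
#' at a rate drawn from Normal(v, s). A response is triggered when the fastest
#' engaged accumulator reaches the bound `b`; observed RT adds a constant
#' non-decision time `t0`. Condition-cell-dependent parameters (`v`, `b`, `z`,
#' `t0`) carry either a single shared value or one value per cell of the 2x2
#' design (cells `r paste(CELL_LEVELS, collapse = ", ")`, perceptual
#' uncertainty first).
#'
#' @param v Mean drift rate(s), length 1 or 4, positive.
#' @param b Decision bound(s), length 1 or 4.
#' @param z Upper bound(s) of the uniform start-point distribution; must be
#'   below the corresponding `b`.
#' @param t0 Non-decision time(s) in seconds, non-negative.
#' @param s Drift-rate standard deviation, the fixed scaling constant
#'   (default 1).
#' @return An object of class `lba_parameters` whose cell-indexed fields are
#'   length-4 named vectors.
#' @export
lba_parameters <- function(v, b, z, t0, s = 1) {
  expand <- function(p, name) {
    if (!length(p) %in% c(1L, 4L)) {
      abort(sprintf("`%s` must have length 1 or 4", name))
    }
    assert_finite(p, name)
    p <- rep(p, length.out = 4L)
    names(p) <- CELL_LEVELS
    p
  }
  v <- expand(v, "v"); b <- expand(b, "b"); z <- expand(z, "z")
  t0 <- expand(t0, "t0")
  if (s <= 0) abort("`s` must be positive")
  if (any(v <= 0)) abort("`v` must be positive")
  if (any(z < 0) || any(b <= z)) abort("need b > z >= 0 in every cell")
  if (any(t0 < 0)) abort("`t0` must be non-negative")
  structure(list(v = v, b = b, z = z, t0 = t0, s = s),
            class = "lba_parameters")
}

#' @export
print.lba_parameters <- function(x, ...) {
  cat("LBA parameters (cells: pu_au)\n")
  print(round(rbind(v = x$v, b = x$b, z = x$z, t0 = x$t0), 4))
  cat(sprintf("  s (fixed scaling): %g\n", x$s))
  invisible(x)
}

#' @method tidy lba_parameters
#' @export
tidy.lba_parameters <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(c(list(cell = CELL_LEVELS),
                        lapply(x[c("v", "b", "z", "t0")], unname))),
    -"cell", names_to = "parameter", values_to = "value")
}

#' First-passage density and distribution of one LBA accumulator
#'
#' Closed-form density/distribution of the time at which a single accumulator
#' (start Uniform\[0, z\], drift Normal(v, s), bound `b`) first reaches the
#' bound. The distribution is defective: a negative drift draw may never reach
#' the bound, so `lba_fpt_cdf` tends to `P(hit)` < 1 as `t` grows.
#'
#' @param t Decision time(s) in seconds (excluding non-decision time);
#'   non-positive times return 0.
#' @param v,s,b,z Scalar accumulator parameters (see [lba_parameters()]).
#' @return Density (`lba_fpt_pdf`) or probability (`lba_fpt_cdf`) at `t`.
#' @export
lba_fpt_pdf <- function(t, v, s, b, z) {
  if (s <= 0 || b <= z || z < 0 || v <= 0) abort("invalid LBA parameters")
  out <- numeric(length(t))
  ok <- t > 0
  tt <- t[ok]
  if (z < 1e-9) {
    # degenerate start point: T = b / drift
    out[ok] <- (b / (s * tt^2)) * dnorm((b / tt - v) / s)
  } else {
    ts <- tt * s
    z1 <- (b - z - tt * v) / ts
    z2 <- (b - tt * v) / ts
    out[ok] <- (-v * pnorm(z1) + s * dnorm(z1) +
                  v * pnorm(z2) - s * dnorm(z2)) / z
  }
  pmax(out, 0)
}

#' @rdname lba_fpt_pdf
#' @export
lba_fpt_cdf <- function(t, v, s, b, z) {
  if (s <= 0 || b <= z || z < 0 || v <= 0) abort("invalid LBA parameters")
  out <- numeric(length(t))
  ok <- t > 0
  tt <- t[ok]
  if (z < 1e-9) {
    out[ok] <- pnorm((v - b / tt) / s)
  } else {
    ts <- tt * s
    z1 <- (b - z - tt * v) / ts
    z2 <- (b - tt * v) / ts
    out[ok] <- 1 + ((b - z - tt * v) / z) * pnorm(z1) -
      ((b - tt * v) / z) * pnorm(z2) +
      (ts / z) * dnorm(z1) - (ts / z) * dnorm(z2)
  }
  pmin(pmax(out, 0), 1)
}

#' Enumerate the 15 parameter-freedom variants of the LBA
#'
#' Each variant frees a non-empty subset of `{v, b, z, t0}` to take distinct
#' values in each of the four condition cells; the remaining parameters are
#' shared across cells. The ordering is canonical: singletons in the order
#' v, b, z, t0, then pairs, triples, and the full set.
#'
#' @return A tibble with columns `variant` (label such as `"v"` or `"v+b"`),
#'   `free` (list-column of freed parameter names) and `k` (number of fitted
#'   scalars, the shared drift SD excluded).
#' @export
enumerate_variants <- function() {
  pars <- c("v", "b", "z", "t0")
  sets <- unlist(lapply(1:4, function(m) utils::combn(pars, m, simplify = FALSE)),
                 recursive = FALSE)
  tibble::tibble(
    variant = vapply(sets, paste, "", collapse = "+"),
    free = sets,
    k = vapply(sets, function(s) 4L * length(s) + (4L - length(s)), 0L)
  )
}

#' Bayesian Information Criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of trials.
#' @return `k * log(n) - 2 * loglik`.
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * loglik
}

# P(an accumulator's drift draw is negative)
p_neg_drift <- function(v, s) pnorm(-v / s)

#' Log-likelihood of choices and RTs under the LBA race
#'
#' Each trial contributes the first-passage density of the chosen accumulator
#' at `rt - t0`, times the survival probability of every other engaged
#' accumulator, renormalized by the probability that at least one engaged
#' drift draw is positive. Only the accumulators of the available response
#' options are engaged (one in low action-uncertainty trials, three in high).
#' Trials whose RT does not exceed the cell's `t0` contribute a fixed floor
#' penalty of -20 so the objective stays finite during optimization.
#'
#' @param trials Data frame with columns `pu`, `au` (`"low"`/`"high"`),
#'   `n_options` (1 or 3) and `rt` (seconds). (Which specific option won does
#'   not alter the likelihood because engaged accumulators share cell
#'   parameters.)
#' @param params An [lba_parameters()] object.
#' @return The summed log-likelihood (scalar).
#' @export
lba_race_loglik <- function(trials, params) {
  stopifnot(inherits(params, "lba_parameters"))
  if (nrow(trials) == 0) abort("`trials` is empty")
  cell <- cell_label(trials$pu, trials$au)
  idx <- match(cell, CELL_LEVELS)
  if (anyNA(idx)) abort("`pu`/`au` must be 'low' or 'high'")
  v <- params$v[idx]; b <- params$b[idx]; z <- params$z[idx]
  t0 <- params$t0[idx]; s <- params$s
  if (!all(is.finite(c(v, b, z, t0, s)))) abort("non-finite parameter")
  m <- trials$n_options
  if (!all(m %in% c(1L, 3L))) abort("`n_options` must be 1 or 3")

  dt <- trials$rt - t0
  ll <- rep(-20, nrow(trials))          # floor for rt <= t0
  ok <- dt > 0
  if (any(ok)) {
    # parameters vary only by cell, so evaluate per (cell, m) block
    key <- paste0(idx, "_", m)
    for (k in unique(key[ok])) {
      sel <- ok & key == k
      i <- idx[which(sel)[1]]
      mm <- m[which(sel)[1]]
      f <- lba_fpt_pdf(dt[sel], v = params$v[i], s = s,
                       b = params$b[i], z = params$z[i])
      lik <- f
      if (mm > 1) {
        surv <- 1 - lba_fpt_cdf(dt[sel], v = params$v[i], s = s,
                                b = params$b[i], z = params$z[i])
        lik <- lik * surv^(mm - 1)
      }
      lik <- lik / (1 - p_neg_drift(params$v[i], s)^mm)
      ll[sel] <- pmax(log(lik), -20)
    }
  }
  sum(ll)
}

#' Simulate choices and reaction times from the LBA race
#'
#' Draws start points from Uniform\[0, z\] and drifts from Normal(v, s) for
#' every engaged accumulator (trials where all engaged drifts come out
#' non-positive are redrawn); the winner is the accumulator reaching the bound
#' first and the RT adds the cell's non-decision time.
#'
#' @param params An [lba_parameters()] object.
#' @param design Data frame with one row per trial: columns `pu`, `au` and
#'   `n_options` (1 or 3). Extra columns are carried through.
#' @param seed Integer seed.
#' @return A tibble: the design plus `response` (index of the winning option)
#'   and `rt` (seconds).
#' @export
simulate_lba <- function(params, design, seed = 1) {
  stopifnot(inherits(params, "lba_parameters"))
  idx <- match(cell_label(design$pu, design$au), CELL_LEVELS)
  if (anyNA(idx)) abort("`pu`/`au` must be 'low' or 'high'")
  m <- design$n_options
  if (!all(m %in% c(1L, 3L))) abort("`n_options` must be 1 or 3")
  n <- nrow(design)

  with_seed(seed, {
    rt <- numeric(n)
    response <- integer(n)
    for (i in seq_len(n)) {
      ci <- idx[i]
      repeat {
        drifts <- rnorm(m[i], params$v[ci], params$s)
        if (any(drifts > 0)) break
      }
      starts <- runif(m[i], 0, params$z[ci])
      finish <- ifelse(drifts > 0, (params$b[ci] - starts) / drifts, Inf)
      w <- which.min(finish)
      response[i] <- w
      rt[i] <- finish[w] + params$t0[ci]
    }
    out <- tibble::as_tibble(design)
    out$response <- response
    out$rt <- rt
    out
  })
}

# ---- fitting ----------------------------------------------------------------

# Pack/unpack: free parameters get 4 slots (one per cell), shared ones 1.
# z is parameterized as a fraction of the corresponding b so b > z always
# holds during the search.
variant_layout <- function(free) {
  pars <- c("v", "b", "zfrac", "t0")
  n_per <- ifelse(c("v", "b", "z", "t0") %in% free, 4L, 1L)
  names(n_per) <- pars
  n_per
}

unpack_params <- function(theta, layout) {
  splits <- rep(names(layout), layout)
  vals <- split(theta, factor(splits, levels = names(layout)))
  v <- rep(vals$v, length.out = 4)
  b <- rep(vals$b, length.out = 4)
  z <- rep(vals$zfrac, length.out = 4) * b
  t0 <- rep(vals$t0, length.out = 4)
  lba_parameters(v = v, b = b, z = z, t0 = t0, s = 1)
}

lba_bounds <- function(min_rt) {
  list(lower = c(v = 0.1, b = 0.1, zfrac = 0.01, t0 = 0.05),
       upper = c(v = 10, b = 5, zfrac = 0.95,
                 t0 = max(min_rt - 0.01, 0.06)))
}

# logistic transform between natural bounds and the unconstrained scale
to_unconstrained <- function(x, lo, hi) stats::qlogis((x - lo) / (hi - lo))
to_natural <- function(u, lo, hi) lo + (hi - lo) * stats::plogis(u)

#' Fit the LBA to one subject's trials by multi-start maximum likelihood
#'
#' Parameters freed by the variant take one value per condition cell; the rest
#' are shared. Each optimization run starts from the best of `n_presearch`
#' random parameter draws and refines it with Nelder-Mead on a
#' logistic-transformed (hence bounded) scale; the best of `n_starts` runs is
#' returned. Trials outside the RT inclusion window are dropped first.
#'
#' @param trials Data frame with columns `pu`, `au`, `n_options`, `rt`.
#' @param variant Variant label (see [enumerate_variants()]), e.g. `"v"`.
#' @param n_starts,n_presearch Multi-start budget; the study-scale defaults
#'   are 25 runs x 100 presearch draws.
#' @param rt_window Inclusion window in seconds; trials outside are omitted.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `lba_fit`: parameters, `loglik`, `bic`, counts
#'   and the variant.
#' @export
fit_lba <- function(trials, variant = "v", n_starts = 25, n_presearch = 100,
                    rt_window = c(0.1, 2.1), seed = 1) {
  keep <- trials$rt >= rt_window[1] & trials$rt <= rt_window[2]
  trials <- trials[keep, , drop = FALSE]
  n <- nrow(trials)
  if (n < 50) warn(sprintf("only %d valid trials; fit may be unstable", n))
  if (n == 0) abort("no trials inside the RT inclusion window")

  variants <- enumerate_variants()
  row <- match(variant, variants$variant)
  if (is.na(row)) abort(sprintf("unknown variant '%s'", variant))
  free <- variants$free[[row]]
  layout <- variant_layout(free)
  bounds <- lba_bounds(min(trials$rt))
  lo <- rep(bounds$lower, layout)
  hi <- rep(bounds$upper, layout)

  # map theta positions to per-cell scalars: slot[[par]][cell] -> index in theta
  offs <- cumsum(c(0, layout))[seq_along(layout)]
  slot <- lapply(seq_along(layout), function(j) {
    if (layout[j] == 4L) offs[j] + 1:4 else rep(offs[j] + 1L, 4)
  })
  names(slot) <- names(layout)

  cell_idx <- match(cell_label(trials$pu, trials$au), CELL_LEVELS)
  if (anyNA(cell_idx)) abort("`pu`/`au` must be 'low' or 'high'")
  if (!all(trials$n_options %in% c(1L, 3L))) {
    abort("`n_options` must be 1 or 3")
  }
  rt <- trials$rt
  mvec <- trials$n_options
  n_all <- length(rt)

  # compiled objective over all trials (s = 1); per-trial likelihoods are
  # floored at exp(-20) to keep the search objective finite
  mvec <- as.integer(mvec)
  cell_int <- as.integer(cell_idx)
  negll <- function(theta) {
    b <- theta[slot$b]
    val <- lba_negll_cpp(rt, cell_int, mvec,
                         v = theta[slot$v], b = b,
                         z = theta[slot$zfrac] * b, t0 = theta[slot$t0])
    if (!is.finite(val)) 1e10 else val
  }
  negll_u <- function(u) negll(to_natural(u, lo, hi))

  d <- length(lo)
  runs <- with_seed(seed, {
    lapply(seq_len(n_starts), function(run) {
      draws <- matrix(runif(n_presearch * d), n_presearch, d)
      draws <- sweep(sweep(draws, 2, hi - lo, `*`), 2, lo, `+`)
      vals <- apply(draws, 1, negll)
      u0 <- to_unconstrained(draws[which.min(vals), ], lo, hi)
      tryCatch({
        res <- optim(u0, negll_u, method = "Nelder-Mead",
                     control = list(maxit = 30 * d, reltol = 1e-6))
        # quasi-Newton polish escapes simplex stagnation near the optimum
        polish <- optim(res$par, negll_u, method = "BFGS",
                        control = list(maxit = 50, reltol = 1e-8))
        if (polish$value < res$value) polish else res
      },
      error = function(e) list(value = Inf, error = conditionMessage(e)))
    })
  })
  vals <- vapply(runs, function(r) r$value, 0)
  if (!any(is.finite(vals))) {
    abort(paste("all optimization runs failed:",
                paste(unique(vapply(runs, function(r)
                  r$error %||% "?", "")), collapse = "; ")))
  }
  best <- runs[[which.min(vals)]]
  params <- unpack_params(to_natural(best$par, lo, hi), layout)
  loglik <- -best$value
  k <- variants$k[[row]]
  structure(
    list(params = params, variant = variant, free = free,
         loglik = loglik, k = k, n_trials = n,
         bic = bic(loglik, k, n)),
    class = "lba_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lba_fit <- function(x, ...) {
  cat(sprintf("LBA fit, variant '%s' (%d free scalars, %d trials)\n",
              x$variant, x$k, x$n_trials))
  cat(sprintf("  loglik %.2f, BIC %.2f\n", x$loglik, x$bic))
  print(x$params)
  invisible(x)
}

#' @method tidy lba_fit
#' @export
tidy.lba_fit <- function(x, ...) {
  out <- tidy(x$params)
  out$free <- out$parameter %in% x$free
  out
}

#' @method glance lba_fit
#' @export
glance.lba_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, logLik = x$loglik, k = x$k,
                 n = x$n_trials, BIC = x$bic)
}

#' Fit every parameter-freedom variant to one subject
#'
#' @inheritParams fit_lba
#' @param variants Character vector of variant labels; defaults to all 15.
#' @return A tibble with one row per variant: `variant`, `loglik`, `k`, `n`,
#'   `bic` and the fitted parameter object in a list-column `fit`.
#' @export
fit_lba_variants <- function(trials, variants = enumerate_variants()$variant,
                             n_starts = 25, n_presearch = 100,
                             rt_window = c(0.1, 2.1), seed = 1) {
  purrr::map_dfr(seq_along(variants), function(i) {
    f <- fit_lba(trials, variants[i], n_starts = n_starts,
                 n_presearch = n_presearch, rt_window = rt_window,
                 seed = derive_seed(seed, i))
    tibble::tibble(variant = f$variant, loglik = f$loglik, k = f$k,
                   n = f$n_trials, bic = f$bic, fit = list(f))
  })
}
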