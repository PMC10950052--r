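#' Random-effects Bayesian model selection across subjects
#'
#' Variational treatment of the hierarchical model in which each subject's
#' data are generated by one of K models drawn from population frequencies r
#' with a Dirichlet prior. Given per-subject log model evidence (here
#' typically `-BIC/2`), the Dirichlet concentration is iterated to
#' convergence; exceedance probabilities (the probability that each model is
#' more frequent than every competitor) are estimated by Monte-Carlo sampling
#' of the Dirichlet posterior.
#'
#' @param log_evidence Numeric matrix, subjects x models; column names (if
#'   any) label the models.
#' @param alpha0 Prior Dirichlet concentration per model (default 1, the flat
#'   prior).
#' @param tol Convergence tolerance on the largest concentration change.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @param n_samples Dirichlet draws for the exceedance estimate.
#' @param seed Integer seed for the exceedance sampling.
#' @return An object of class `bms_result` with fields `alpha` (posterior
#'   concentrations), `expected_frequencies`, `exceedance`, `free_energy`
#'   (variational bound on the group log evidence) and `models`.
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, tol = 1e-8, max_iter = 10000,
                    n_samples = 1e6, seed = 1) {
  le <- as.matrix(log_evidence)
  if (!all(is.finite(le))) abort("`log_evidence` must be finite")
  n <- nrow(le); K <- ncol(le)
  if (K < 2) abort("need at least 2 models")
  if (n < 2) warn("single subject: the random-effects posterior is degenerate")
  models <- colnames(le) %||% paste0("m", seq_len(K))

  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  g <- matrix(0, n, K)
  for (iter in seq_len(max_iter)) {
    w <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    g <- exp(w) / rowSums(exp(w))
    alpha_new <- a0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
    if (iter == max_iter) {
      abort(sprintf(
        "variational update did not converge in %d iterations (last delta %.3g)",
        max_iter, delta))
    }
  }

  # variational free energy: E_q[log p(y|m)] + E_q[log p(m|r)] - KL(q(r)||p(r))
  # - E_q[log q(m)]
  psi <- digamma(alpha) - digamma(sum(alpha))
  e_data <- sum(g * le)
  e_assign <- sum(sweep(g, 2, psi, `*`))
  entropy_g <- -sum(g[g > 0] * log(g[g > 0]))
  kl <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * psi)
  free_energy <- e_data + e_assign + entropy_g - kl

  exceedance <- exceedance_probability(alpha, n_samples = n_samples, seed = seed)

  structure(
    list(alpha = stats::setNames(alpha, models),
         expected_frequencies = stats::setNames(alpha / sum(alpha), models),
         exceedance = stats::setNames(exceedance, models),
         free_energy = free_energy,
         assignments = g, models = models, n_subjects = n),
    class = "bms_result")
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Monte-Carlo estimate of `P(r_k > r_j for all j != k)` under
#' `r ~ Dirichlet(alpha)`, sampled in chunks via independent gamma draws.
#'
#' @param alpha Positive concentration vector.
#' @param n_samples Number of draws.
#' @param seed Integer seed.
#' @return Probability vector summing to 1.
#' @export
exceedance_probability <- function(alpha, n_samples = 1e6, seed = 1) {
  K <- length(alpha)
  stopifnot(K >= 2, all(alpha > 0))
  counts <- integer(K)
  with_seed(seed, {
    remaining <- n_samples
    chunk <- 1e5
    while (remaining > 0) {
      m <- min(chunk, remaining)
      draw <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      win <- max.col(draw, ties.method = "first")
      counts <- counts + tabulate(win, K)
      remaining <- remaining - m
    }
  })
  counts / n_samples
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("Random-effects BMS (%d subjects, %d models)\n",
              x$n_subjects, length(x$models)))
  print(round(rbind(frequency = x$expected_frequencies,
                    exceedance = x$exceedance), 4))
  cat(sprintf("  free energy: %.3f\n", x$free_energy))
  invisible(x)
}

#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(model = x$models,
                 alpha = unname(x$alpha),
                 expected_frequency = unname(x$expected_frequencies),
                 exceedance = unname(x$exceedance))
}

#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy, n_subjects = x$n_subjects,
                 n_models = length(x$models))
}

#' Plot expected frequencies and exceedance probabilities
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
                            c("expected_frequency", "exceedance"),
                            names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal()
}

#' Posterior probability that two groups share the same model
#'
#' Compares the hypothesis that one set of model frequencies generated both
#' groups (pooled random-effects analysis) against group-specific frequencies
#' (separate analyses, whose log evidences add). The posterior of the shared
#' hypothesis is the logistic of the log-evidence difference,
#' \deqn{P(H_= | Data) = 1 / (1 + \exp(\log p(Data|H_{\neq}) -
#'   \log p(Data|H_=))).}
#'
#' @param log_evidence_a,log_evidence_b Subjects x models log-evidence
#'   matrices for the two groups, sharing the model axis.
#' @param ... Passed to [rfx_bms()].
#' @return An object of class `group_bms` with the pooled and split evidence
#'   bounds, `posterior_same_model`, and the three underlying `bms_result`
#'   objects.
#' @export
group_model_posterior <- function(log_evidence_a, log_evidence_b, ...) {
  a <- as.matrix(log_evidence_a); b <- as.matrix(log_evidence_b)
  if (ncol(a) != ncol(b)) abort("groups must share the model axis")
  pooled <- rfx_bms(rbind(a, b), ...)
  fit_a <- rfx_bms(a, ...)
  fit_b <- rfx_bms(b, ...)
  le_pooled <- pooled$free_energy
  le_split <- fit_a$free_energy + fit_b$free_energy
  post <- 1 / (1 + exp(le_split - le_pooled))
  structure(
    list(log_evidence_pooled = le_pooled,
         log_evidence_split = le_split,
         posterior_same_model = post,
         pooled = pooled, group_a = fit_a, group_b = fit_b),
    class = "group_bms")
}

#' @export
print.group_bms <- function(x, ...) {
  cat("Between-group model comparison\n")
  cat(sprintf("  log evidence pooled (H=): %.3f\n", x$log_evidence_pooled))
  cat(sprintf("  log evidence split (H!=): %.3f\n", x$log_evidence_split))
  cat(sprintf("  P(same model | data): %.4f\n", x$posterior_same_model))
  invisible(x)
}

#' @method glance group_bms
#' @export
glance.group_bms <- function(x, ...) {
  tibble::tibble(log_evidence_pooled = x$log_evidence_pooled,
                 log_evidence_split = x$log_evidence_split,
                 posterior_same_model = x$posterior_same_model)
}
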