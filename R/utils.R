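#' @importFrom rlang .data abort warn
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom optim
#' @importFrom Rcpp sourceCpp
#' @useDynLib lbacascade, .registration = TRUE
NULL

# Canonical labels for the four condition cells of the 2x2 design,
# perceptual uncertainty (pu) crossed with action uncertainty (au).
CELL_LEVELS <- c("low_low", "low_high", "high_low", "high_high")

cell_label <- function(pu, au) paste(pu, au, sep = "_")

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) abort(sprintf("`%s` must be finite", name))
  invisible(x)
}

# Derive a stream-specific 31-bit seed from a master seed, so independent
# generators never share a stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
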