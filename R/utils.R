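#' Numerically stable sigmoid
#'
#' Elementwise logistic function \eqn{\sigma(z) = 1/(1+e^{-z})}, evaluated
#' without overflow for arguments of any magnitude.
#'
#' @param z numeric vector or matrix.
#' @return object of the same shape as `z` with values in \[0, 1\].
#' @keywords internal
sigmoid <- function(z) stats::plogis(z)

#' Numerically stable softplus
#'
#' Elementwise \eqn{\log(1 + e^{z})}, computed as
#' \eqn{\max(z, 0) + \log(1 + e^{-|z|})} so large positive arguments do not
#' overflow and large negative arguments do not underflow to -Inf.
#'
#' @param z numeric vector or matrix.
#' @return object of the same shape as `z`.
#' @keywords internal
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# first and second derivatives of the sigmoid, from sigma itself
dsigmoid  <- function(s) s * (1 - s)
d2sigmoid <- function(s) s * (1 - s) * (1 - 2 * s)

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# package-local mutable state: counts Gibbs-sampler invocations so tests can
# assert that score-matching training never samples
.crossrbm_state <- new.env(parent = emptyenv())
.crossrbm_state$gibbs_calls <- 0L

#' Gibbs sampler call counter
#'
#' The package counts every draw from the visible conditional so that the
#' claim "score-matching training never runs the Gibbs sampler" can be
#' verified by instrumentation rather than by reading the code.
#'
#' @param reset logical; if `TRUE` the counter is zeroed before returning the
#'   previous value.
#' @return integer count of visible-conditional sampling calls since the last
#'   reset (invisibly the old value when resetting).
#' @export
#' @examples
#' gibbs_call_count(reset = TRUE)
gibbs_call_count <- function(reset = FALSE) {
  n <- .crossrbm_state$gibbs_calls
  if (reset) .crossrbm_state$gibbs_calls <- 0L
  n
}

bump_gibbs_counter <- function() {
  .crossrbm_state$gibbs_calls <- .crossrbm_state$gibbs_calls + 1L
  invisible(NULL)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# derive independent sub-seeds from one master seed, staying inside the
# 32-bit integer range R requires of set.seed()
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
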