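#' Gauss-Bernoulli RBM parameter set
#'
#' Container for the parameters of a Gauss-Bernoulli restricted Boltzmann
#' machine: continuous visible units \eqn{x \in R^D} with diagonal precision
#' \eqn{\Lambda = dg(\lambda)}, binary hidden units \eqn{h \in \{0,1\}^H},
#' and energy
#' \deqn{E(x, h) = \tfrac12 (x-c)^\top \Lambda (x-c) - h^\top W \Lambda x - b^\top h.}
#'
#' @param W numeric H x D matrix of hidden-visible couplings.
#' @param b numeric length-H hidden bias.
#' @param c numeric length-D visible bias.
#' @param lam numeric length-D strictly positive visible precision diagonal.
#' @return object of class `rbm_params` (a validated list with elements
#'   `W`, `b`, `c`, `lam` and integer sizes `H`, `D`).
#' @export
#' @examples
#' p <- rbm_params(W = matrix(0, 2, 3), b = rep(0, 2), c = rep(0, 3),
#'                 lam = rep(1, 3))
#' rbm_free_energy(c(0, 0, 0), p)  # equals -2 * log(2)
rbm_params <- function(W, b, c, lam) {
  W <- as.matrix(W)
  b <- as.numeric(b); c <- as.numeric(c); lam <- as.numeric(lam)
  H <- nrow(W); D <- ncol(W)
  if (length(b) != H) stop("length(b) must equal nrow(W)")
  if (length(c) != D) stop("length(c) must equal ncol(W)")
  if (length(lam) != D) stop("length(lam) must equal ncol(W)")
  if (!all(is.finite(W)) || !all(is.finite(b)) || !all(is.finite(c)) ||
      !all(is.finite(lam))) stop("RBM parameters must be finite")
  if (any(lam <= 0)) stop("visible precisions lam must be strictly positive")
  structure(list(W = W, b = b, c = c, lam = lam, H = H, D = D),
            class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("Gauss-Bernoulli RBM parameters: D = %d visible, H = %d hidden\n",
              x$D, x$H))
  cat(sprintf("  |W| range [%.3g, %.3g], lam range [%.3g, %.3g]\n",
              min(x$W), max(x$W), min(x$lam), max(x$lam)))
  invisible(x)
}

check_visible <- function(x, params) {
  x <- as.numeric(x)
  if (length(x) != params$D)
    stop(sprintf("visible vector has length %d, model expects D = %d",
                 length(x), params$D))
  x
}

check_hidden <- function(h, params) {
  h <- as.numeric(h)
  if (length(h) != params$H)
    stop(sprintf("hidden vector has length %d, model expects H = %d",
                 length(h), params$H))
  if (!all(h %in% c(0, 1))) stop("hidden vector must be binary (0/1)")
  h
}

# hidden pre-activation(s) W Lam x + b; X may be a vector or an n x D matrix,
# result is a vector of length H or an n x H matrix
hidden_preact <- function(X, params) {
  if (is.matrix(X)) {
    sweep(X, 2, params$lam, "*") %*% t(params$W) +
      matrix(params$b, nrow(X), params$H, byrow = TRUE)
  } else {
    drop(params$W %*% (params$lam * X)) + params$b
  }
}

#' Joint energy of a visible/hidden configuration
#'
#' Evaluates \eqn{E(x,h) = \tfrac12 (x-c)^\top \Lambda (x-c)
#' - h^\top W \Lambda x - b^\top h}.
#'
#' @param x numeric length-D visible vector.
#' @param h binary length-H hidden vector.
#' @param params an [rbm_params] object.
#' @return finite numeric scalar.
#' @export
rbm_energy <- function(x, h, params) {
  x <- check_visible(x, params)
  h <- check_hidden(h, params)
  dx <- x - params$c
  0.5 * sum(params$lam * dx^2) -
    sum(h * drop(params$W %*% (params$lam * x))) -
    sum(params$b * h)
}

#' Free energy of a visible vector
#'
#' The negative log of the unnormalised visible marginal obtained by summing
#' the Boltzmann factor over all \eqn{2^H} hidden configurations:
#' \deqn{F(x) = \tfrac12 (x-c)^\top \Lambda (x-c)
#'   - \sum_j \mathrm{softplus}\big((W \Lambda x + b)_j\big),}
#' so that \eqn{e^{-F(x)} = \sum_h e^{-E(x,h)}} exactly.
#'
#' @param x numeric length-D visible vector, or an n x D matrix of rows.
#' @param params an [rbm_params] object.
#' @return numeric scalar (or length-n vector for matrix input).
#' @export
rbm_free_energy <- function(x, params) {
  if (is.matrix(x)) {
    if (ncol(x) != params$D) stop("x must have D columns")
    dx <- sweep(x, 2, params$c, "-")
    0.5 * drop(dx^2 %*% params$lam) - rowSums(softplus(hidden_preact(x, params)))
  } else {
    x <- check_visible(x, params)
    dx <- x - params$c
    0.5 * sum(params$lam * dx^2) - sum(softplus(hidden_preact(x, params)))
  }
}

#' Hidden-unit activation probabilities given the visible layer
#'
#' The hidden conditional factorises into independent Bernoulli units with
#' \eqn{p(h_j = 1 | x) = \sigma\big((W \Lambda x + b)_j\big)}.
#'
#' @inheritParams rbm_free_energy
#' @return numeric vector of length H (or n x H matrix) of probabilities.
#' @export
rbm_cond_hidden <- function(x, params) {
  if (!is.matrix(x)) x <- matrix(check_visible(x, params), 1)
  p <- sigmoid(hidden_preact(x, params))
  if (nrow(p) == 1L) drop(p) else p
}

#' Visible conditional distribution given the hidden layer
#'
#' Given hidden configuration h, the visible units are independent Gaussians
#' with mean \eqn{W^\top h + c} and diagonal precision \eqn{\lambda}.
#'
#' @param h binary length-H hidden vector.
#' @param params an [rbm_params] object.
#' @return list with elements `mean` (length D) and `precision_diag`
#'   (length D, the diagonal of \eqn{\Lambda}; the covariance is its
#'   elementwise reciprocal).
#' @export
rbm_cond_visible <- function(h, params) {
  h <- check_hidden(h, params)
  list(mean = drop(crossprod(params$W, h)) + params$c,
       precision_diag = params$lam)
}

#' Sample the hidden layer given the visible layer
#'
#' @param x numeric length-D visible vector or n x D matrix.
#' @param params an [rbm_params] object.
#' @return binary vector of length H (or n x H matrix). Reproducible under
#'   `set.seed()`.
#' @export
rbm_sample_hidden <- function(x, params) {
  p <- rbm_cond_hidden(x, params)
  if (is.matrix(p)) {
    matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p))
  } else {
    stats::rbinom(length(p), 1L, p)
  }
}

#' Sample the visible layer given the hidden layer
#'
#' @param h binary length-H hidden vector or n x H matrix.
#' @param params an [rbm_params] object.
#' @return numeric vector of length D (or n x D matrix). Reproducible under
#'   `set.seed()`.
#' @export
rbm_sample_visible <- function(h, params) {
  bump_gibbs_counter()
  if (is.matrix(h)) {
    mu <- h %*% params$W + matrix(params$c, nrow(h), params$D, byrow = TRUE)
    mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) /
      matrix(sqrt(params$lam), nrow(mu), params$D, byrow = TRUE)
  } else {
    cv <- rbm_cond_visible(h, params)
    cv$mean + stats::rnorm(params$D) / sqrt(cv$precision_diag)
  }
}

#' One full Gibbs sweep (hidden then visible)
#'
#' Advances a Markov chain on the visible layer by sampling
#' \eqn{h \sim p(h|x)} then \eqn{x \sim p(x|h)}.
#'
#' @param chain a `gibbs_chain` as returned by [gibbs_chain()] or a previous
#'   sweep.
#' @param params an [rbm_params] object.
#' @return the updated `gibbs_chain` with `step_count` incremented by 1.
#' @export
rbm_gibbs_sweep <- function(chain, params) {
  stopifnot(inherits(chain, "gibbs_chain"))
  h <- rbm_sample_hidden(chain$x, params)
  chain$x <- rbm_sample_visible(h, params)
  chain$step_count <- chain$step_count + 1L
  chain
}

#' Construct a Gibbs chain state
#'
#' @param x numeric visible state (vector or matrix of parallel chains).
#' @return object of class `gibbs_chain` with fields `x` and `step_count`.
#' @export
gibbs_chain <- function(x) {
  if (!all(is.finite(x))) stop("chain state must be finite")
  structure(list(x = x, step_count = 0L), class = "gibbs_chain")
}

#' Run k Gibbs sweeps from a starting visible state
#'
#' @param x0 numeric length-D start state (or n x D matrix of parallel
#'   chains).
#' @param k positive integer number of full (hidden, visible) sweeps.
#' @param params an [rbm_params] object.
#' @return the visible state after `k` sweeps, same shape as `x0`.
#' @export
rbm_gibbs_run <- function(x0, k, params) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer")
  chain <- gibbs_chain(x0)
  for (i in seq_len(k)) chain <- rbm_gibbs_sweep(chain, params)
  chain$x
}

#' Score function of the visible marginal
#'
#' The gradient of the log marginal density,
#' \eqn{\nabla_x \log p(x) = \Lambda(c - x) + \Lambda W^\top \sigma(W\Lambda x + b)},
#' which equals \eqn{-\nabla_x F(x)}.
#'
#' @inheritParams rbm_free_energy
#' @return numeric length-D vector (or n x D matrix for matrix input).
#' @export
rbm_score <- function(x, params) {
  if (is.matrix(x)) {
    s <- sigmoid(hidden_preact(x, params))
    sweep(sweep(-x, 2, params$c, "+") + s %*% params$W, 2, params$lam, "*")
  } else {
    x <- check_visible(x, params)
    s <- sigmoid(hidden_preact(x, params))
    params$lam * (params$c - x + drop(crossprod(params$W, s)))
  }
}

#' Exact log partition function (small models)
#'
#' Enumerates all \eqn{2^H} hidden configurations and integrates the visible
#' Gaussian in closed form:
#' \deqn{\log Z = \tfrac12 \sum_d \log(2\pi/\lambda_d) +
#'   \mathrm{logsumexp}_h\big(b^\top h + a_h^\top \Lambda c +
#'   \tfrac12 a_h^\top \Lambda a_h\big), \quad a_h = W^\top h.}
#' Intended as a test oracle for exact small-model densities; refuses models
#' with more than 12 hidden units.
#'
#' @param params an [rbm_params] object with `H <= 12`.
#' @return numeric scalar log Z.
#' @export
rbm_log_partition <- function(params) {
  if (params$H > 12L)
    stop("exact enumeration is limited to H <= 12 hidden units")
  Hm <- hidden_configs(params$H)                  # 2^H x H
  A <- Hm %*% params$W                            # 2^H x D, rows a_h
  expo <- drop(Hm %*% params$b) +
    drop(A %*% (params$lam * params$c)) +
    0.5 * drop(A^2 %*% params$lam)
  0.5 * sum(log(2 * pi / params$lam)) + logsumexp(expo)
}

# all binary configurations of H units as a 2^H x H matrix
hidden_configs <- function(H) {
  if (H == 0L) return(matrix(0, 1, 0))
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), H)))
  dimnames(m) <- NULL
  m
}
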