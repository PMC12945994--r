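#' Hyvarinen score of a visible vector
#'
#' The pointwise score-matching objective
#' \eqn{s_F(x) = \tfrac12 \|\nabla_x \log p(x)\|^2 + \Delta_x \log p(x)},
#' which for the Gauss-Bernoulli RBM has the closed form
#' \deqn{s_F(x) = \tfrac12\|\Lambda(W^\top\sigma + c - x)\|^2
#'   + \mathrm{tr}\big(-\Lambda + \Lambda W^\top dg(\sigma') W \Lambda\big)}
#' with \eqn{\sigma = \sigma(W \Lambda x + b)}. Averaging over data and
#' minimising fits the model by Fisher-divergence minimisation without ever
#' evaluating the partition function.
#'
#' @param x numeric length-D vector or n x D matrix.
#' @param params an [rbm_params] object.
#' @return numeric scalar (or length-n vector).
#' @export
rbm_hyvarinen_score <- function(x, params) {
  single <- !is.matrix(x)
  if (single) x <- matrix(check_visible(x, params), 1)
  s  <- sigmoid(hidden_preact(x, params))              # n x H
  sp <- dsigmoid(s)
  R  <- s %*% params$W +
    matrix(params$c, nrow(x), params$D, byrow = TRUE) - x   # W^T sigma + c - x
  q  <- drop((params$W^2) %*% params$lam^2)            # q_j = sum_d lam_d^2 W_jd^2
  val <- 0.5 * drop(R^2 %*% params$lam^2) - sum(params$lam) + drop(sp %*% q)
  if (single) val[1] else val
}

#' Closed-form gradients of the batch-mean Hyvarinen score
#'
#' Returns the exact gradient of `mean(rbm_hyvarinen_score(batch))` with
#' respect to every parameter block, obtained by differentiating the
#' closed-form score. These are the score-matching training gradients; they
#' require no sampling.
#'
#' @param batch numeric n x D matrix of visible vectors (n >= 1).
#' @param params an [rbm_params] object.
#' @return list with elements `dW` (H x D), `db` (H), `dc` (D), `dlam` (D).
#' @export
rbm_fd_gradients <- function(batch, params) {
  if (!is.matrix(batch)) batch <- matrix(batch, 1)
  n <- nrow(batch)
  if (n < 1L) stop("batch must be non-empty")
  if (ncol(batch) != params$D) stop("batch must have D columns")
  W <- params$W; lam <- params$lam
  lam2 <- lam^2

  s   <- sigmoid(hidden_preact(batch, params))         # n x H
  sp  <- dsigmoid(s)
  spp <- d2sigmoid(s)
  R   <- s %*% W + matrix(params$c, n, params$D, byrow = TRUE) - batch
  q   <- drop((W^2) %*% lam2)                          # length H
  RL2 <- sweep(R, 2, lam2, "*")                        # R Lam^2, n x D
  V   <- sp * (RL2 %*% t(W))                           # n x H: sigma' .* (W Lam^2 r)
  Sq  <- sweep(spp, 2, q, "*")                         # n x H: sigma'' .* q
  XL  <- sweep(batch, 2, lam, "*")                     # n x D: lam .* x

  dc <- colMeans(RL2)
  db <- colMeans(V) + colMeans(Sq)
  dW <- (t(s) %*% RL2 + t(V) %*% XL + t(Sq) %*% XL) / n +
    2 * sweep(colMeans(sp) * W, 2, lam2, "*")
  dlam <- lam * colMeans(R^2) +
    colMeans(batch * ((V + Sq) %*% W)) - 1 +
    2 * lam * drop(colMeans(sp) %*% (W^2))
  list(dW = dW, db = db, dc = dc, dlam = dlam)
}

#' Gradient of the free energy with respect to the parameters
#'
#' Batch-mean analytic gradient of \eqn{F(x)} for each parameter block; the
#' building block of the contrastive-divergence update
#' \eqn{\nabla_\theta F(x_{data}) - E_{model}[\nabla_\theta F(x)]}.
#'
#' @param batch numeric n x D matrix of visible vectors.
#' @param params an [rbm_params] object.
#' @return list with elements `dW`, `db`, `dc`, `dlam`.
#' @export
rbm_free_energy_grad <- function(batch, params) {
  if (!is.matrix(batch)) batch <- matrix(batch, 1)
  n <- nrow(batch)
  if (ncol(batch) != params$D) stop("batch must have D columns")
  s  <- sigmoid(hidden_preact(batch, params))          # n x H
  dx <- sweep(batch, 2, params$c, "-")
  XL <- sweep(batch, 2, params$lam, "*")
  list(dW   = -(t(s) %*% XL) / n,
       db   = -colMeans(s),
       dc   = -params$lam * colMeans(dx),
       dlam = 0.5 * colMeans(dx^2) - colMeans(batch * (s %*% params$W)))
}

#' k-step contrastive-divergence gradients
#'
#' Estimates the negative log-likelihood gradient as the difference between
#' the data term (batch-mean analytic free-energy gradient) and the model
#' term (the same gradient evaluated at chain states obtained by `k_cd`
#' Gibbs sweeps started from the batch).
#'
#' @param batch numeric n x D matrix of visible vectors.
#' @param params an [rbm_params] object.
#' @param k_cd positive integer number of Gibbs sweeps (default 1).
#' @return list with elements `dW`, `db`, `dc`, `dlam`.
#' @export
rbm_cd_gradients <- function(batch, params, k_cd = 1L) {
  if (!is.matrix(batch)) batch <- matrix(batch, 1)
  if (k_cd < 1) stop("k_cd must be >= 1")
  data_term  <- rbm_free_energy_grad(batch, params)
  fantasy    <- rbm_gibbs_run(batch, k_cd, params)
  model_term <- rbm_free_energy_grad(fantasy, params)
  Map(`-`, data_term, model_term)
}
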