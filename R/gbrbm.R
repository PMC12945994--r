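#' Fit a Gauss-Bernoulli restricted Boltzmann machine
#'
#' Fits the joint density of a set of continuous feature vectors with a
#' Gauss-Bernoulli RBM, by one of two estimators:
#' \describe{
#'   \item{`"fd"`}{Fisher-divergence minimisation (score matching): minimise
#'     the batch-mean Hyvarinen score with its closed-form gradients. No
#'     sampling is involved at any point of training.}
#'   \item{`"cd"`}{k-step contrastive divergence: approximate the maximum
#'     likelihood gradient with `k_cd` Gibbs sweeps started at the data.}
#' }
#' Optimisation is minibatch Adam (or plain SGD) over a fixed epoch budget.
#' The visible precisions are optimised on the log scale so they remain
#' strictly positive.
#'
#' @param x numeric n x D matrix of training vectors (rows are trials). When
#'   the columns are the concatenated feature blocks of several subjects,
#'   pass `layout` so the fitted model can be used for cross-subject mapping
#'   with [predict.gbrbm()].
#' @param hidden number of binary hidden units H (default 15).
#' @param method `"fd"` (score matching, default) or `"cd"` (contrastive
#'   divergence).
#' @param epochs training epochs (default 350). `epochs = 0` returns the
#'   initialisation unchanged.
#' @param learning_rate optimizer step size (default 0.005).
#' @param batch_size minibatch size (default 150); must not exceed n.
#'   Minibatches are drawn without replacement and reshuffled every epoch.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param k_cd Gibbs steps per CD gradient (default 1); ignored for `"fd"`.
#' @param freeze_lambda logical; if `TRUE` the visible precisions stay at
#'   their initial value (the unit-variance textbook model is obtained with
#'   `freeze_lambda = TRUE` and `init = list(lam = rep(1, D))`).
#' @param freeze character subset of `c("W", "b", "c", "lambda")` naming
#'   parameter blocks to hold fixed during training.
#' @param init optional named list overriding the default initialisation of
#'   any of `W`, `b`, `c`, `lam`. Defaults: `W ~ N(0, 0.01^2)`, `b = 0`,
#'   `c` = column means of `x`, `lam` = 1 / column variances (clipped to
#'   `[1e-3, 1e3]`), i.e. the Gaussian part starts at the moment-matched
#'   solution.
#' @param layout optional [subject_layout()] describing how the columns of
#'   `x` split into per-subject blocks.
#' @param seed optional integer seed controlling initialisation, batch
#'   shuffling and (for CD) the Gibbs chains.
#' @param trace_every compute the epoch-level objective every this many
#'   epochs (default 1). The objective is the full-data mean Hyvarinen score
#'   for `"fd"`; for `"cd"`, whose true objective is implicit, the one-sweep
#'   reconstruction mean squared error is logged together with the free
#'   energy gap between data and model samples (monitoring only, never
#'   optimised).
#' @param verbose logical; print progress every 50 epochs.
#' @return An object of class `"gbrbm"`: a list with elements `params`
#'   ([rbm_params]), `config`, `trace` (data frame of epoch, objective and
#'   cumulative seconds, plus `recon_mse`/`fe_gap` for CD), `init`
#'   (the initial parameters), `layout` and `data_dim`.
#' @seealso [predict.gbrbm()] for cross-subject mapping,
#'   [simulate.gbrbm()] for drawing from the fitted density.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600, sd = 2), 200, 3)
#' fit <- gbrbm(x, hidden = 4, epochs = 30, batch_size = 50, seed = 1)
#' fit
#' coef(fit)$lam   # close to 1/4
gbrbm <- function(x, hidden = 15L, method = c("fd", "cd"), epochs = 350L,
                  learning_rate = 0.005, batch_size = 150L,
                  optimizer = c("adam", "sgd"), k_cd = 1L,
                  freeze_lambda = FALSE, freeze = character(),
                  init = NULL, layout = NULL, seed = NULL,
                  trace_every = 1L, verbose = FALSE) {
  method <- match.arg(method)
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  n <- nrow(x); D <- ncol(x); H <- as.integer(hidden)
  if (!all(is.finite(x))) stop("training data must be finite")
  if (H < 1L) stop("hidden must be >= 1")
  if (epochs > 0 && n < batch_size)
    stop(sprintf("n = %d rows but batch_size = %d; need n >= batch_size",
                 n, batch_size))
  if (k_cd < 1L) stop("k_cd must be >= 1")
  if (!is.null(layout) && layout$D != D)
    stop("layout dimension does not match ncol(x)")
  if (freeze_lambda) freeze <- union(freeze, "lambda")
  bad <- setdiff(freeze, c("W", "b", "c", "lambda"))
  if (length(bad)) stop("unknown freeze blocks: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  v <- apply(x, 2, stats::var)
  params <- rbm_params(
    W   = init$W   %||% matrix(stats::rnorm(H * D, sd = 0.01), H, D),
    b   = init$b   %||% rep(0, H),
    c   = init$c   %||% colMeans(x),
    lam = init$lam %||% pmin(pmax(1 / pmax(v, .Machine$double.eps), 1e-3), 1e3))
  init_params <- params

  cfg <- list(method = method, hidden = H, epochs = as.integer(epochs),
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              optimizer = optimizer, k_cd = as.integer(k_cd),
              freeze = freeze, seed = seed)

  # Adam state per block (lambda handled on the log scale)
  opt <- list()
  blocks <- c("W", "b", "c", "lam")
  for (bl in blocks) opt[[bl]] <- list(m = 0, v = 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L

  trace <- vector("list", max(epochs, 0L))
  t0 <- proc.time()[["elapsed"]]

  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + batch_size - 1L, n)]
      batch <- x[idx, , drop = FALSE]
      g <- if (method == "fd") rbm_fd_gradients(batch, params)
           else rbm_cd_gradients(batch, params, k_cd)
      # chain rule for the log-precision parameterisation
      g$dlam <- g$dlam * params$lam
      names(g) <- blocks
      if ("W" %in% freeze) g$W[] <- 0
      if ("b" %in% freeze) g$b[] <- 0
      if ("c" %in% freeze) g$c[] <- 0
      if ("lambda" %in% freeze) g$lam[] <- 0
      t_step <- t_step + 1L
      for (bl in blocks) {
        gb <- g[[bl]]
        if (optimizer == "adam") {
          opt[[bl]]$m <- beta1 * opt[[bl]]$m + (1 - beta1) * gb
          opt[[bl]]$v <- beta2 * opt[[bl]]$v + (1 - beta2) * gb^2
          mhat <- opt[[bl]]$m / (1 - beta1^t_step)
          vhat <- opt[[bl]]$v / (1 - beta2^t_step)
          step <- learning_rate * mhat / (sqrt(vhat) + adam_eps)
        } else {
          step <- learning_rate * gb
        }
        if (bl == "lam") {
          params$lam <- params$lam * exp(-step)
        } else {
          params[[bl]] <- params[[bl]] - step
        }
      }
    }
    if (ep %% trace_every == 0L || ep == epochs) {
      row <- data.frame(epoch = ep, objective = NA_real_,
                        seconds = proc.time()[["elapsed"]] - t0)
      if (method == "fd") {
        row$objective <- mean(rbm_hyvarinen_score(x, params))
      } else {
        hmean <- sigmoid(hidden_preact(x, params))
        recon <- hmean %*% params$W + matrix(params$c, n, D, byrow = TRUE)
        row$objective <- row$recon_mse <- mean((x - recon)^2)
        fant <- rbm_gibbs_run(x[sample.int(n, min(n, 200L)), , drop = FALSE],
                              k_cd, params)
        row$fe_gap <- mean(rbm_free_energy(x, params)) -
          mean(rbm_free_energy(fant, params))
      }
      if (!is.finite(row$objective))
        stop(sprintf("training objective became non-finite at epoch %d; ",
                     ep), "reduce the learning rate or check the data scale")
      trace[[ep]] <- row
      if (verbose && ep %% 50L == 0L)
        message(sprintf("epoch %4d  objective %.5f", ep, row$objective))
    }
  }
  trace <- if (epochs > 0) do.call(rbind, trace[!vapply(trace, is.null, TRUE)])
           else data.frame(epoch = integer(), objective = numeric(),
                           seconds = numeric())

  structure(list(params = params, config = cfg, trace = trace,
                 init = init_params, layout = layout, data_dim = c(n = n, D = D)),
            class = "gbrbm")
}

#' @export
print.gbrbm <- function(x, ...) {
  cat(sprintf("Gauss-Bernoulli RBM (%s), D = %d visible, H = %d hidden\n",
              toupper(x$config$method), x$params$D, x$params$H))
  cat(sprintf("  trained %d epochs on %d rows (batch %d, %s, lr %g)\n",
              x$config$epochs, x$data_dim[["n"]], x$config$batch_size,
              x$config$optimizer, x$config$learning_rate))
  if (nrow(x$trace))
    cat(sprintf("  final objective: %.5f\n", utils::tail(x$trace$objective, 1)))
  if (!is.null(x$layout))
    cat(sprintf("  layout: %d subjects (%s)\n", length(x$layout$subjects),
                paste(x$layout$subjects, collapse = ", ")))
  invisible(x)
}

#' @export
summary.gbrbm <- function(object, ...) {
  out <- list(config = object$config, data_dim = object$data_dim,
              params = object$params,
              trace_head = utils::head(object$trace, 3),
              trace_tail = utils::tail(object$trace, 3),
              layout = object$layout)
  class(out) <- "summary.gbrbm"
  out
}

#' @export
print.summary.gbrbm <- function(x, ...) {
  cat(sprintf("Gauss-Bernoulli RBM fitted by %s\n", toupper(x$config$method)))
  cat(sprintf("  visible D = %d, hidden H = %d, n = %d training rows\n",
              x$params$D, x$params$H, x$data_dim[["n"]]))
  cat(sprintf("  optimizer %s, lr %g, batch %d, epochs %d\n",
              x$config$optimizer, x$config$learning_rate,
              x$config$batch_size, x$config$epochs))
  cat(sprintf("  lam range [%.3g, %.3g]; |W| max %.3g; |b| max %.3g\n",
              min(x$params$lam), max(x$params$lam),
              max(abs(x$params$W)), max(abs(x$params$b))))
  if (nrow(x$trace_tail)) {
    cat("  objective trace (last epochs):\n")
    print(x$trace_tail, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.gbrbm <- function(object, ...) {
  object$params[c("W", "b", "c", "lam")]
}

#' Draw visible samples from a fitted RBM
#'
#' Runs `nsim` parallel Gibbs chains initialised at standard normal noise
#' for `burnin` sweeps and returns the final visible states.
#'
#' @param object a fitted [gbrbm] model.
#' @param nsim number of samples (default 1).
#' @param seed optional integer seed.
#' @param burnin Gibbs sweeps per chain (default 100).
#' @param ... unused.
#' @return numeric `nsim` x D matrix.
#' @export
simulate.gbrbm <- function(object, nsim = 1, seed = NULL, burnin = 100L, ...) {
  if (!is.null(seed)) set.seed(seed)
  x0 <- matrix(stats::rnorm(nsim * object$params$D), nsim, object$params$D)
  rbm_gibbs_run(x0, burnin, object$params)
}

#' Mean-field reconstruction residuals
#'
#' For each row of `newdata`, the residual against its one-sweep mean-field
#' reconstruction \eqn{W^\top \sigma(W \Lambda x + b) + c}. Useful as a
#' coarse goodness-of-fit diagnostic.
#'
#' @param object a fitted [gbrbm] model.
#' @param newdata numeric n x D matrix (defaults to nothing; required).
#' @param ... unused.
#' @return numeric n x D matrix of residuals.
#' @export
residuals.gbrbm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$params$D) stop("newdata must have D columns")
  hmean <- sigmoid(hidden_preact(newdata, object$params))
  recon <- hmean %*% object$params$W +
    matrix(object$params$c, nrow(newdata), object$params$D, byrow = TRUE)
  newdata - recon
}

#' Plot the training trace of a fitted RBM
#'
#' @param x a fitted [gbrbm] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gbrbm <- function(x, ...) {
  if (!nrow(x$trace)) {
    warning("no trace recorded (epochs = 0)")
    return(invisible(x))
  }
  ylab <- if (x$config$method == "fd") "mean Hyvarinen score"
          else "reconstruction MSE"
  graphics::plot(x$trace$epoch, x$trace$objective, type = "l",
                 xlab = "epoch", ylab = ylab, ...)
  invisible(x)
}
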