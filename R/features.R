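#' The ten-muscle roster
#'
#' Fixed canonical ordering of the ten flight muscles whose motor units are
#' recorded: power muscles (dorsolongitudinal DLM, dorsoventral DVM) and
#' steering muscles (third axillary 3AX, basalar BA, subalar SA), on the left
#' and right side. All trial assembly uses this order regardless of input
#' row order.
#'
#' @return character vector of length 10.
#' @export
muscle_roster <- function() {
  c("L-DLM", "L-DVM", "L-3AX", "L-BA", "L-SA",
    "R-DLM", "R-DVM", "R-3AX", "R-BA", "R-SA")
}

#' Gaussian-kernel smoothing of a spike train
#'
#' Converts a variable-length list of spike times into a fixed-length
#' continuous trace by centring a Gaussian kernel at each spike and summing:
#' \deqn{x(t) = \sum_n \exp\big(-(t - t_n)^2 / (2 \sigma^2)\big),
#'   \quad 0 \le t \le \tau,}
#' evaluated on the grid \eqn{t \in \{0, 1/f_s, \ldots,
#' (\mathrm{round}(\tau f_s) - 1)/f_s\}}. Spikes later than the cut-off
#' (\eqn{t_n > \tau}) are excluded before summation.
#'
#' @param spike_times numeric vector of spike times in ms (may be empty).
#'   Unsorted input is sorted with a warning.
#' @param tau trial cut-off in ms (default 60).
#' @param sigma Gaussian kernel bandwidth in ms (default 2.5).
#' @param fs sampling frequency in kHz (default 1, i.e. a 1 ms grid).
#' @return nonnegative numeric vector of length `round(tau * fs)`.
#' @export
#' @examples
#' v <- smooth_spikes(c(10, 30), tau = 60, sigma = 2.5)
#' v[11]  # exactly 1 at the 10 ms grid point
smooth_spikes <- function(spike_times, tau = 60, sigma = 2.5, fs = 1) {
  if (tau <= 0 || sigma <= 0 || fs <= 0)
    stop("tau, sigma and fs must all be positive")
  L <- round(tau * fs)
  grid <- (seq_len(L) - 1) / fs
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) == 0L) return(numeric(L))
  if (is.unsorted(spike_times)) {
    warning("spike times were not sorted; sorting")
    spike_times <- sort(spike_times)
  }
  spike_times <- spike_times[spike_times <= tau]
  if (length(spike_times) == 0L) return(numeric(L))
  d <- outer(grid, spike_times, "-")
  rowSums(exp(-d^2 / (2 * sigma^2)))
}

#' Assemble one trial into a flattened multi-muscle feature vector
#'
#' Smooths the spike train of every muscle in the fixed roster order and
#' concatenates the traces. Muscles that are absent from the trial (or
#' declared missing) contribute exact zero vectors.
#'
#' @param spikes_by_muscle named list mapping muscle identifiers (a subset of
#'   [muscle_roster()]) to numeric spike-time vectors in ms.
#' @param missing character vector of muscle identifiers known to be missing
#'   (zero-filled; must not also carry spikes).
#' @inheritParams smooth_spikes
#' @return numeric vector of length `10 * round(tau * fs)`.
#' @export
assemble_trial <- function(spikes_by_muscle, missing = character(),
                           tau = 60, sigma = 2.5, fs = 1) {
  roster <- muscle_roster()
  unknown <- setdiff(union(names(spikes_by_muscle), missing), roster)
  if (length(unknown))
    stop("unknown muscle identifier(s): ", paste(unknown, collapse = ", "))
  clash <- intersect(names(spikes_by_muscle)[
    vapply(spikes_by_muscle, length, 0L) > 0L], missing)
  if (length(clash))
    stop("muscle(s) declared missing but carrying spikes: ",
         paste(clash, collapse = ", "))
  L <- round(tau * fs)
  out <- numeric(length(roster) * L)
  for (i in seq_along(roster)) {
    m <- roster[i]
    if (m %in% missing) next
    ts <- spikes_by_muscle[[m]]
    if (is.null(ts) || length(ts) == 0L) next
    out[((i - 1L) * L + 1L):(i * L)] <- smooth_spikes(ts, tau, sigma, fs)
  }
  out
}

#' Fit a PCA basis on a training matrix
#'
#' Principal component analysis retaining the first `P` modes, with a
#' deterministic sign convention: each component is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param train_matrix numeric n x d matrix (training split only).
#' @param P number of principal modes to retain.
#' @return list of class `pca_basis` with `rotation` (d x P, orthonormal
#'   columns), `center` (length d), `sdev` (length P, decreasing) and `P`.
#' @export
fit_pca <- function(train_matrix, P) {
  train_matrix <- as.matrix(train_matrix)
  n <- nrow(train_matrix)
  if (n <= P) stop(sprintf("need more rows (%d) than modes P = %d", n, P))
  pr <- stats::prcomp(train_matrix, center = TRUE, scale. = FALSE)
  if (P > ncol(pr$rotation) || pr$sdev[P] < 1e-12 * max(pr$sdev, 1e-300))
    stop(sprintf("P = %d exceeds the effective rank of the training matrix", P))
  rot <- pr$rotation[, seq_len(P), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(P)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(rotation = rot, center = pr$center,
                 sdev = pr$sdev[seq_len(P)], P = P),
            class = "pca_basis")
}

#' Project data onto a fitted PCA basis
#'
#' @param x numeric n x d matrix (d matching the basis).
#' @param basis a [fit_pca()] result.
#' @return numeric n x P score matrix.
#' @export
apply_pca <- function(x, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  x <- as.matrix(x)
  if (ncol(x) != length(basis$center))
    stop("column count does not match the PCA basis")
  sweep(x, 2, basis$center, "-") %*% basis$rotation
}

#' Featurize a spike table into per-subject feature datasets
#'
#' Full feature pipeline: per trial, smooth every muscle's spike train,
#' zero-fill missing muscles, flatten across the roster; then per subject,
#' fit PCA on the (training) trials and keep the first `P` modes.
#'
#' @param spikes a spike table as returned by [read_spike_table()] or
#'   [synth_spikes()]: a data frame with columns `subject_id`, `trial_id`,
#'   `label`, `muscle_id`, `spike_time_ms`, optionally carrying a `missing`
#'   attribute (data frame with `subject_id`, `muscle_id`).
#' @param P number of principal modes (default 10).
#' @inheritParams smooth_spikes
#' @return named list of per-subject feature datasets, each a list with
#'   `X` (trials x P), `y` (labels), `trial_id`, `pca` (the [fit_pca()]
#'   basis) and `raw_dim`.
#' @export
featurize_spikes <- function(spikes, P = 10, tau = 60, sigma = 2.5, fs = 1) {
  missing_tab <- attr(spikes, "missing") %||%
    data.frame(subject_id = character(), muscle_id = character())
  L <- round(tau * fs)
  out <- list()
  for (s in unique(spikes$subject_id)) {
    sub <- spikes[spikes$subject_id == s, , drop = FALSE]
    miss <- missing_tab$muscle_id[missing_tab$subject_id == s]
    trials <- unique(sub$trial_id)
    raw <- matrix(0, length(trials), 10L * L)
    y <- character(length(trials))
    for (i in seq_along(trials)) {
      tr <- sub[sub$trial_id == trials[i], , drop = FALSE]
      y[i] <- as.character(tr$label[1])
      by_muscle <- split(tr$spike_time_ms, tr$muscle_id)
      raw[i, ] <- assemble_trial(by_muscle, missing = miss,
                                 tau = tau, sigma = sigma, fs = fs)
    }
    pca <- fit_pca(raw, P)
    out[[as.character(s)]] <- list(X = apply_pca(raw, pca), y = y,
                                   trial_id = trials, pca = pca,
                                   raw_dim = ncol(raw))
  }
  out
}

# z-scoring helper used by the evaluation harness: statistics come from the
# training split only and are reapplied to the test split
zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(x, zs) {
  sweep(sweep(x, 2, zs$mu, "-"), 2, zs$sd, "/")
}
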