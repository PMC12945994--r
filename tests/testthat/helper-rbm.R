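# shared fixtures and independent oracles used across test files

# random RBM instance with O(1) parameter scales
random_rbm <- function(D, H, w_sd = 0.5) {
  rbm_params(W = matrix(rnorm(H * D, sd = w_sd), H, D),
             b = rnorm(H, sd = 0.5),
             c = rnorm(D),
             lam = exp(rnorm(D, sd = 0.3)))
}

# independent term-by-term transcription of the energy (no shared code with
# rbm_energy beyond base R)
energy_oracle <- function(x, h, p) {
  acc <- 0
  for (d in seq_len(p$D)) acc <- acc + 0.5 * p$lam[d] * (x[d] - p$c[d])^2
  for (j in seq_len(p$H)) {
    for (d in seq_len(p$D)) acc <- acc - h[j] * p$W[j, d] * p$lam[d] * x[d]
    acc <- acc - p$b[j] * h[j]
  }
  acc
}

# brute-force visible marginal: log sum over all hidden configurations
log_marginal_enum <- function(x, p) {
  hm <- crossrbm:::hidden_configs(p$H)
  e <- apply(hm, 1, function(h) rbm_energy(x, h, p))
  m <- max(-e)
  m + log(sum(exp(-e - m)))
}

# central finite-difference gradient of a scalar function of x
fd_grad_x <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# central finite-difference Laplacian of a scalar function of x
fd_laplacian_x <- function(f, x, h = 1e-4) {
  f0 <- f(x)
  sum(vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - 2 * f0 + f(x - e)) / h^2
  }, 0))
}

# central finite-difference gradient of obj(params) for each parameter block
fd_grad_params <- function(obj, p, h = 1e-5) {
  out <- list()
  for (f in c("W", "b", "c", "lam")) {
    v <- p[[f]]
    g <- v
    for (i in seq_along(v)) {
      p1 <- p; p1[[f]][i] <- v[i] + h
      p2 <- p; p2[[f]][i] <- v[i] - h
      g[i] <- (obj(p1) - obj(p2)) / (2 * h)
    }
    out[[f]] <- g
  }
  out
}

rel_err <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))

# exact moments of the visible marginal for small H: mixture of Gaussians
# over hidden configurations with closed-form weights
exact_visible_moments <- function(p) {
  hm <- crossrbm:::hidden_configs(p$H)
  A <- hm %*% p$W
  logw <- drop(hm %*% p$b) + drop(A %*% (p$lam * p$c)) +
    0.5 * drop(A^2 %*% p$lam)
  w <- exp(logw - max(logw)); w <- w / sum(w)
  means <- sweep(A, 2, p$c, "+")
  mu <- drop(w %*% means)
  second <- diag(1 / p$lam, p$D) + t(means) %*% (w * means)
  list(mean = mu, cov = second - outer(mu, mu), weights = w, means = means)
}

# small two-subject feature roster for end-to-end tests
tiny_roster <- function(seed = 1, subjects = 2, tpc = 30) {
  synth_features(n_subjects = subjects, trials_per_class = tpc, seed = seed)
}
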