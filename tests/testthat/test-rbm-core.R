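test_that("energy matches its definition on anchor cases and a literal oracle", {
  p <- rbm_params(W = matrix(0, 2, 2), b = c(0, 0), c = c(0, 0),
                  lam = c(1, 1))
  expect_identical(rbm_energy(c(0, 0), c(0, 0), p), 0)
  expect_equal(rbm_energy(c(1, 1), c(1, 0), p), 1.0)  # 0.5 * ||x||^2

  p2 <- rbm_params(W = matrix(1:4 / 2, 2, 2), b = c(0.3, -0.1),
                   c = c(0.5, 0.5), lam = c(2, 0.7))
  expect_equal(rbm_energy(p2$c, c(0, 0), p2), 0)

  set.seed(101)
  for (i in 1:10) {
    p3 <- random_rbm(3, 2)
    x <- rnorm(3); h <- rbinom(2, 1, 0.5)
    expect_equal(rbm_energy(x, h, p3), energy_oracle(x, h, p3),
                 tolerance = 1e-12)
  }
})

test_that("energy validates shapes and binary hidden states", {
  p <- random_rbm(3, 2)
  expect_error(rbm_energy(rnorm(4), c(0, 1), p), "length 4")
  expect_error(rbm_energy(rnorm(3), c(0.5, 1), p), "binary")
  expect_error(rbm_params(matrix(0, 2, 2), c(0, 0), c(0, 0), c(1, -1)),
               "strictly positive")
  expect_error(rbm_params(matrix(NA_real_, 1, 1), 0, 0, 1), "finite")
})

test_that("free energy marginalises the hidden layer exactly", {
  # W = 0, b = 0, x = c: each hidden unit contributes softplus(0) = log 2
  for (H in c(1, 4, 9)) {
    p <- rbm_params(matrix(0, H, 2), rep(0, H), c(1, -1), c(1, 2))
    expect_equal(rbm_free_energy(c(1, -1), p), -H * log(2))
  }
  p1 <- rbm_params(matrix(0, 1, 1), 0, 0, 2)
  expect_equal(rbm_free_energy(1, p1), 1 - log(2))

  set.seed(77)
  for (i in 1:25) {
    D <- sample(2:4, 1); H <- sample(1:10, 1)
    p <- random_rbm(D, H)
    x <- rnorm(D)
    lhs <- -rbm_free_energy(x, p)
    rhs <- log_marginal_enum(x, p)
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-10)
  }
})

test_that("free energy accepts matrix input row-wise", {
  set.seed(5)
  p <- random_rbm(3, 4)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(rbm_free_energy(X, p),
               apply(X, 1, rbm_free_energy, params = p))
})

test_that("hidden conditional is the sigmoid of W Lam x + b and matches enumeration", {
  p <- rbm_params(matrix(0, 3, 2), rep(0, 3), c(0, 0), c(1, 1))
  expect_equal(rbm_cond_hidden(c(2, -1), p), rep(0.5, 3))

  p_sat <- rbm_params(matrix(0, 2, 2), c(20, -20), c(0, 0), c(1, 1))
  probs <- rbm_cond_hidden(c(0, 0), p_sat)
  expect_gte(probs[1], 1 - 3e-9)
  expect_lte(probs[2], 3e-9)

  set.seed(13)
  for (i in 1:8) {
    p <- random_rbm(2, 2)
    x <- rnorm(2)
    hm <- crossrbm:::hidden_configs(2)
    wts <- exp(-apply(hm, 1, function(h) rbm_energy(x, h, p)))
    enum <- vapply(1:2, function(j) sum(wts[hm[, j] == 1]) / sum(wts), 0)
    expect_equal(rbm_cond_hidden(x, p), enum, tolerance = 1e-10)
  }
})

test_that("visible conditional is Gaussian with mean W^T h + c and precision lam", {
  p <- random_rbm(3, 2)
  cv <- rbm_cond_visible(c(0, 0), p)
  expect_equal(cv$mean, p$c)
  expect_equal(cv$precision_diag, p$lam)

  p1 <- rbm_params(matrix(c(1.5, -2, 0.5), 1, 3), 0, rep(0, 3),
                   rep(1, 3))
  expect_equal(rbm_cond_visible(1, p1)$mean, drop(p1$W[1, ]))

  # Monte-Carlo check of the sampler against the declared Gaussian
  set.seed(99)
  p <- random_rbm(3, 2)
  h <- c(1, 0)
  mu <- rbm_cond_visible(h, p)$mean
  H <- matrix(rep(h, 1e5), ncol = 2, byrow = TRUE)
  draws <- rbm_sample_visible(H, p)
  sd_mean <- sqrt(1 / p$lam) / sqrt(1e5)
  expect_true(all(abs(colMeans(draws) - mu) < 4 * sd_mean))
  expect_true(all(abs(apply(draws, 2, var) * p$lam - 1) < 0.05))
})

test_that("sampling is bit-reproducible under a fixed seed", {
  p <- random_rbm(4, 3)
  set.seed(123); h1 <- rbm_sample_hidden(rep(1, 4), p)
  set.seed(123); h2 <- rbm_sample_hidden(rep(1, 4), p)
  expect_identical(h1, h2)
  set.seed(321); x1 <- rbm_sample_visible(c(1, 0, 1), p)
  set.seed(321); x2 <- rbm_sample_visible(c(1, 0, 1), p)
  expect_identical(x1, x2)
  set.seed(7); g1 <- rbm_gibbs_run(rnorm(4), 5, p)
  set.seed(7); g2 <- rbm_gibbs_run(rnorm(4), 5, p)
  expect_identical(g1, g2)
})

test_that("decoupled hidden units are fair coins", {
  p <- rbm_params(matrix(0, 3, 2), rep(0, 3), c(0, 0), c(1, 1))
  set.seed(11)
  X <- matrix(rnorm(2e4), 1e4, 2)
  draws <- rbm_sample_hidden(X, p)
  # binomial CI: 0.5 +/- 3 * sqrt(0.25 / n)
  expect_true(all(abs(colMeans(draws) - 0.5) < 3 * sqrt(0.25 / 1e4)))
})

test_that("gibbs_run composes sweeps and validates k", {
  p <- random_rbm(3, 2)
  expect_error(rbm_gibbs_run(rnorm(3), 0, p), "positive integer")

  set.seed(42)
  out_run <- rbm_gibbs_run(c(1, 2, 3), 3, p)
  set.seed(42)
  ch <- gibbs_chain(c(1, 2, 3))
  for (i in 1:3) ch <- rbm_gibbs_sweep(ch, p)
  expect_identical(out_run, ch$x)
  expect_identical(ch$step_count, 3L)
})

test_that("with W = 0 one sweep forgets the start state and draws N(c, 1/lam)", {
  p <- rbm_params(matrix(0, 2, 2), c(0, 0), c(2, -1), c(4, 0.25))
  set.seed(17)
  X0 <- matrix(rnorm(2e4, sd = 10), 1e4, 2)  # extreme, irrelevant starts
  out <- rbm_gibbs_run(X0, 1, p)
  expect_true(all(abs(colMeans(out) - p$c) < 4 * sqrt(1 / p$lam) / sqrt(1e4)))
  expect_true(all(abs(apply(out, 2, var) * p$lam - 1) < 0.06))
})

test_that("long Gibbs chains reproduce the exact enumerated mixture moments", {
  set.seed(31)
  p <- random_rbm(2, 2, w_sd = 0.8)
  ex <- exact_visible_moments(p)
  n_chain <- 4000
  X <- matrix(rnorm(2 * n_chain), n_chain, 2)
  X <- rbm_gibbs_run(X, 60, p)
  se <- sqrt(diag(ex$cov) / n_chain)
  expect_true(all(abs(colMeans(X) - ex$mean) < 5 * se))
  expect_true(all(abs(diag(cov(X)) - diag(ex$cov)) / diag(ex$cov) < 0.15))
})

test_that("score equals Lam(c - x) + Lam W^T sigma and -grad of free energy", {
  p0 <- rbm_params(matrix(0, 2, 3), c(0, 0), c(1, 0, -1), c(1, 2, 4))
  x <- c(0.5, 0.5, 0.5)
  expect_equal(rbm_score(x, p0), p0$lam * (p0$c - x))
  expect_equal(rbm_score(p0$c, p0), rep(0, 3))

  set.seed(55)
  for (i in 1:10) {
    p <- random_rbm(4, 3)
    x <- rnorm(4)
    g <- rbm_score(x, p)
    gn <- -fd_grad_x(function(z) rbm_free_energy(z, p), x)
    expect_lt(rel_err(g, gn), 1e-5)
  }
})

test_that("line integral of the score equals the free-energy drop", {
  set.seed(66)
  p <- random_rbm(3, 2)
  a <- rnorm(3); b <- rnorm(3)
  ts <- seq(0, 1, length.out = 2001)
  pts <- outer(1 - ts, a) + outer(ts, b)
  proj <- drop(rbm_score(pts, p) %*% (b - a))
  integral <- sum((proj[-1] + proj[-length(proj)]) / 2) * (ts[2] - ts[1])
  expect_equal(integral,
               rbm_free_energy(a, p) - rbm_free_energy(b, p),
               tolerance = 1e-3)
})

test_that("exact log partition agrees with closed forms, quadrature and shifts", {
  # decoupled: product of Bernoulli and Gaussian normalisers
  p <- rbm_params(matrix(0, 3, 2), rep(0, 3), c(1, -1), c(2, 0.5))
  expect_equal(rbm_log_partition(p),
               3 * log(2) + 0.5 * sum(log(2 * pi / p$lam)))

  # D = 1, H = 1: wide-grid quadrature of exp(-F)
  p1 <- rbm_params(matrix(0.7, 1, 1), 0.3, 0.2, 1.5)
  gr <- seq(-25, 25, length.out = 40001)
  quad <- log(sum(exp(-rbm_free_energy(matrix(gr, ncol = 1), p1))) *
                (gr[2] - gr[1]))
  expect_equal(rbm_log_partition(p1), quad, tolerance = 1e-6)

  # shifting b rescales each hidden configuration consistently
  set.seed(8)
  p <- random_rbm(2, 3)
  p_shift <- p; p_shift$b <- p$b + 0.7
  hm <- crossrbm:::hidden_configs(3)
  direct <- rbm_log_partition(p_shift)
  A <- hm %*% p$W
  expo <- drop(hm %*% p$b) + drop(A %*% (p$lam * p$c)) +
    0.5 * drop(A^2 %*% p$lam) + 0.7 * rowSums(hm)
  enum <- 0.5 * sum(log(2 * pi / p$lam)) +
    max(expo) + log(sum(exp(expo - max(expo))))
  expect_equal(direct, enum, tolerance = 1e-10)

  expect_error(rbm_log_partition(random_rbm(2, 13)), "H <= 12")
})
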