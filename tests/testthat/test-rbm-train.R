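test_that("Hyvarinen score reduces to the Gaussian case when W = 0", {
  # D = 1, lam = 2, c = 0, x = 1: 0.5 * (2 * 1)^2 - 2 = 0
  p <- rbm_params(matrix(0, 1, 1), 0, 0, 2)
  expect_equal(rbm_hyvarinen_score(1, p), 0)
  # at x = c the squared score vanishes, leaving -sum(lam)
  p2 <- rbm_params(matrix(0, 2, 3), c(0, 0), c(1, 2, 3), c(0.5, 1, 2))
  expect_equal(rbm_hyvarinen_score(p2$c, p2), -sum(p2$lam))
})

test_that("Hyvarinen score equals 0.5||grad log p||^2 + laplacian by finite differences", {
  set.seed(202)
  for (i in 1:12) {
    p <- random_rbm(4, 3)
    x <- rnorm(4)
    fe <- function(z) rbm_free_energy(z, p)
    g <- -fd_grad_x(fe, x)
    lap <- -fd_laplacian_x(fe, x)
    expect_lt(rel_err(rbm_hyvarinen_score(x, p), 0.5 * sum(g^2) + lap), 1e-4)
  }
})

test_that("closed-form FD gradients match finite differences for every block", {
  # W = 0: dc = mean of Lam^2 (c - x), zero at the batch mean
  p0 <- rbm_params(matrix(0, 2, 3), c(0, 0), c(1, -1, 0), c(1, 2, 0.5))
  batch0 <- rbind(p0$c + c(1, 0, 0), p0$c - c(1, 0, 0))
  g0 <- rbm_fd_gradients(batch0, p0)
  expect_equal(g0$dc, rep(0, 3))
  batch1 <- matrix(p0$c + c(0.3, -0.2, 0.1), 1)
  expect_equal(rbm_fd_gradients(batch1, p0)$dc,
               p0$lam^2 * (p0$c - drop(batch1)))

  set.seed(303)
  for (i in 1:5) {
    p <- random_rbm(4, 3)
    batch <- matrix(rnorm(32), 8, 4)
    ga <- rbm_fd_gradients(batch, p)
    gn <- fd_grad_params(function(q) mean(rbm_hyvarinen_score(batch, q)), p)
    expect_lt(rel_err(ga$dW, gn$W), 1e-4)
    expect_lt(rel_err(ga$db, gn$b), 1e-4)
    expect_lt(rel_err(ga$dc, gn$c), 1e-4)
    expect_lt(rel_err(ga$dlam, gn$lam), 1e-4)
  }
  expect_error(rbm_fd_gradients(matrix(numeric(0), 0, 4), random_rbm(4, 2)),
               "non-empty")
})

test_that("a small step along the FD gradient decreases the batch-mean score", {
  set.seed(404)
  p <- random_rbm(5, 3)
  batch <- matrix(rnorm(60), 12, 5)
  g <- rbm_fd_gradients(batch, p)
  eta <- 1e-3
  p2 <- p
  p2$W <- p$W - eta * g$dW; p2$b <- p$b - eta * g$db
  p2$c <- p$c - eta * g$dc; p2$lam <- p$lam - eta * g$dlam
  expect_lt(mean(rbm_hyvarinen_score(batch, p2)),
            mean(rbm_hyvarinen_score(batch, p)))
})

test_that("analytic free-energy gradients match finite differences", {
  set.seed(505)
  for (i in 1:5) {
    p <- random_rbm(3, 2)
    batch <- matrix(rnorm(18), 6, 3)
    ga <- rbm_free_energy_grad(batch, p)
    gn <- fd_grad_params(function(q) mean(rbm_free_energy(batch, q)), p)
    expect_lt(rel_err(ga$dW, gn$W), 1e-5)
    expect_lt(rel_err(ga$db, gn$b), 1e-5)
    expect_lt(rel_err(ga$dc, gn$c), 1e-5)
    expect_lt(rel_err(ga$dlam, gn$lam), 1e-5)
  }
})

test_that("CD gradient is centred at zero when the data come from the model", {
  set.seed(606)
  p <- random_rbm(2, 2, w_sd = 0.6)
  n <- 6000
  batch <- rbm_gibbs_run(matrix(rnorm(2 * n), n, 2), 60, p)
  # per-sample CD-1 difference, component-wise, with its Monte-Carlo error
  g_data <- rbm_free_energy_grad(batch, p)
  fant <- rbm_gibbs_run(batch, 1, p)
  g_model <- rbm_free_energy_grad(fant, p)
  # conservative scale for the standard error from per-sample free-energy
  # gradients of each set
  s_hidden <- crossrbm:::sigmoid(crossrbm:::hidden_preact(batch, p))
  comp_sd <- max(apply(cbind(s_hidden, batch), 2, sd), 1)
  for (blk in c("dW", "db", "dc", "dlam")) {
    expect_lt(max(abs(g_data[[blk]] - g_model[[blk]])),
              6 * comp_sd / sqrt(n))
  }
})

test_that("CD model-expectation term matches exact quadrature on a small model", {
  set.seed(707)
  p <- random_rbm(2, 2, w_sd = 0.6)
  # exact E_p[grad_theta F] by 2-D grid quadrature of the normalised density
  gr <- seq(-9, 9, length.out = 241)
  gridX <- as.matrix(expand.grid(gr, gr))
  logp <- -rbm_free_energy(gridX, p) - rbm_log_partition(p)
  w <- exp(logp) * (gr[2] - gr[1])^2
  expect_equal(sum(w), 1, tolerance = 1e-6)  # quadrature sanity
  s <- crossrbm:::sigmoid(crossrbm:::hidden_preact(gridX, p))
  dxc <- sweep(gridX, 2, p$c, "-")
  exact <- list(
    dW = -(t(s * w) %*% sweep(gridX, 2, p$lam, "*")),
    db = -colSums(s * w),
    dc = -p$lam * colSums(dxc * w),
    dlam = 0.5 * colSums(dxc^2 * w) - colSums(gridX * (s %*% p$W) * w))

  # Monte-Carlo estimate from many independent long chains
  n <- 10000
  fant <- rbm_gibbs_run(matrix(rnorm(2 * n), n, 2), 60, p)
  mc <- rbm_free_energy_grad(fant, p)
  for (blk in c("dW", "db", "dc", "dlam")) {
    expect_lt(max(abs(mc[[blk]] - exact[[blk]])), 0.1)
  }
})

test_that("training with epochs = 0 returns the initialisation unchanged", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  fit <- gbrbm(x, hidden = 2, epochs = 0, seed = 9)
  expect_identical(fit$params, fit$init)
  expect_equal(nrow(fit$trace), 0L)
})

test_that("score matching with frozen W recovers Gaussian moments", {
  set.seed(2024)
  D <- 3
  mu <- c(0.5, -1, 2); v <- c(0.5, 1, 2)
  x <- sweep(sweep(matrix(rnorm(3000 * D), ncol = D), 2, sqrt(v), "*"),
             2, mu, "+")
  fit <- gbrbm(x, hidden = 4, method = "fd", epochs = 25, batch_size = 150,
               freeze = "W", init = list(W = matrix(0, 4, D)), seed = 3)
  expect_true(all(abs(coef(fit)$c - mu) < 0.05))
  expect_true(all(abs(coef(fit)$lam * v - 1) < 0.10))
  expect_true(all(coef(fit)$W == 0))
})

test_that("Gaussian recovery error shrinks as the sample grows", {
  set.seed(31415)
  mu <- c(1, -0.5); v <- c(2, 0.5)
  err <- vapply(c(1e2, 1e4), function(n) {
    x <- sweep(sweep(matrix(rnorm(n * 2), ncol = 2), 2, sqrt(v), "*"),
               2, mu, "+")
    fit <- gbrbm(x, hidden = 2, method = "fd", epochs = 10,
                 batch_size = min(100, n), freeze = "W",
                 init = list(W = matrix(0, 2, 2)), seed = 4)
    sqrt(sum((coef(fit)$c - mu)^2))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("FD training decreases the objective and never touches the Gibbs sampler", {
  set.seed(100)
  centers <- rbind(c(2, 2, -2, 0), c(-2, -2, 2, 0))
  x <- centers[rep(1:2, each = 150), ] + matrix(rnorm(300 * 4), 300, 4)
  drops <- vapply(1:10, function(s) {
    gibbs_call_count(reset = TRUE)
    fit <- gbrbm(x, hidden = 3, method = "fd", epochs = 15,
                 batch_size = 100, seed = s, trace_every = 1)
    expect_identical(gibbs_call_count(), 0L)
    init_obj <- mean(rbm_hyvarinen_score(x, fit$init))
    utils::tail(fit$trace$objective, 1) < init_obj
  }, TRUE)
  expect_true(all(drops))
})

test_that("CD training runs, logs monitoring columns and reduces reconstruction error", {
  set.seed(200)
  centers <- rbind(c(3, 3), c(-3, -3))
  x <- centers[rep(1:2, each = 100), ] + matrix(rnorm(400), 200, 2)
  gibbs_call_count(reset = TRUE)
  fit <- gbrbm(x, hidden = 3, method = "cd", epochs = 200,
               learning_rate = 0.02, batch_size = 100, k_cd = 1, seed = 5)
  expect_gt(gibbs_call_count(), 0L)
  expect_true(all(c("recon_mse", "fe_gap") %in% names(fit$trace)))
  # the trained model reconstructs far better than the initialisation
  fit0 <- gbrbm(x, hidden = 3, method = "cd", epochs = 0, seed = 5)
  expect_lt(mean(residuals(fit, x)^2), 0.5 * mean(residuals(fit0, x)^2))
})

test_that("CD and FD fits share data contracts and checkpoint schema", {
  set.seed(42)
  x <- matrix(rnorm(300), 100, 3)
  lay <- subject_layout(c("a", "b", "c"), 1)
  f1 <- gbrbm(x, hidden = 2, method = "fd", epochs = 3, batch_size = 50,
              layout = lay, seed = 1)
  f2 <- gbrbm(x, hidden = 2, method = "cd", epochs = 3, batch_size = 50,
              layout = lay, seed = 1)
  p1 <- file.path(tempdir(), "fd.json"); p2 <- file.path(tempdir(), "cd.json")
  write_gbrbm(f1, p1); write_gbrbm(f2, p2)
  j1 <- jsonlite::read_json(p1); j2 <- jsonlite::read_json(p2)
  expect_identical(names(j1), names(j2))
  expect_identical(names(j1$params), names(j2$params))
})

test_that("training validates inputs and seeds reproducibly", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(gbrbm(x, hidden = 2, epochs = 5, batch_size = 50),
               "batch_size")
  expect_error(gbrbm(cbind(x, NA), hidden = 2, epochs = 1, batch_size = 5),
               "finite")
  set.seed(1); xx <- matrix(rnorm(600), 200, 3)
  a <- gbrbm(xx, hidden = 3, epochs = 5, batch_size = 100, seed = 77)
  b <- gbrbm(xx, hidden = 3, epochs = 5, batch_size = 100, seed = 77)
  expect_identical(a$params, b$params)
})
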