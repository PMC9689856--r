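test_that("search boxes validate bounds and map the unit cube", {
  expect_error(search_box(1, 0), "lower < upper")
  expect_error(search_box(0, 1, log = TRUE))  # log scale needs lower > 0
  b <- search_box(c(1e-4, 0), c(1, 10), log = c(TRUE, FALSE))
  x <- wcepipe:::box_from_unit(b, c(0.5, 0.5))
  expect_equal(unname(x[1]), 1e-2, tolerance = 1e-12)  # log midpoint
  expect_equal(unname(x[2]), 5)
})

test_that("the GP interpolates noiseless data and reverts to the prior", {
  x <- matrix(seq(0, 1, length.out = 5), ncol = 1)
  y <- 2 * x[, 1] + 1
  m <- gp_fit(x, y)
  p <- gp_predict(m, x)
  expect_lt(max(abs(p$mu - y)), 1e-4)
  expect_lt(max(p$sd), 1e-3)

  far <- gp_predict(m, matrix(50, 1, 1))
  expect_lt(abs(far$sd - sqrt(m$sf2)) / sqrt(m$sf2), 0.05)

  expect_error(gp_fit(matrix(0, 1, 1), 1), "at least 2")
  expect_error(gp_fit(matrix(c(0, 1), 2, 1), c(1, NaN)), "non-finite")
  expect_warning(gp_fit(matrix(c(0, 0, 1), 3, 1), c(1, 1, 2)), "duplicate")
})

test_that("GP posterior matches a dense linear-algebra oracle", {
  set.seed(4)
  X <- matrix(runif(3), ncol = 1)
  y <- sin(3 * X[, 1])
  th <- list(ell = 0.4, sf = 1.0, sn = 0.01)
  m <- gp_fit(X, y, optimize_theta = FALSE, theta0 = th)
  xs <- matrix(seq(0, 1, 0.25), ncol = 1)
  p <- gp_predict(m, xs)

  K <- wcepipe:::matern52(X, X, th$ell, th$sf^2) + diag(th$sn^2 + 1e-8, 3)
  Ks <- wcepipe:::matern52(X, xs, th$ell, th$sf^2)
  mu_o <- mean(y) + drop(t(Ks) %*% solve(K, y - mean(y)))
  sd_o <- sqrt(pmax(th$sf^2 - diag(t(Ks) %*% solve(K, Ks)), 0))
  expect_lt(max(abs(p$mu - mu_o)), 1e-8)
  expect_lt(max(abs(p$sd - sd_o)), 1e-8)

  # constant-valued data: the posterior mean stays at that constant
  yc <- rep(0.7, 3)
  mc <- gp_fit(X, yc, optimize_theta = FALSE, theta0 = th)
  pc <- gp_predict(mc, matrix(mean(X), 1, 1))
  expect_lt(abs(pc$mu - 0.7), 1e-6)
})

test_that("expected improvement matches its closed form and quadrature", {
  set.seed(5)
  X <- matrix(c(0.1, 0.5, 0.9), ncol = 1)
  y <- c(0.8, 0.3, 0.6)
  m <- gp_fit(X, y, optimize_theta = FALSE,
              theta0 = list(ell = 0.3, sf = 1, sn = 0.05))
  xs <- matrix(0.35, 1, 1)
  p <- gp_predict(m, xs)
  for (g in c(-3, -1, 0, 1, 3)) {
    best <- p$mu + g * p$sd
    ei <- expected_improvement(m, xs, best)
    q <- integrate(function(t) pmax(best - t, 0) * dnorm(t, p$mu, p$sd),
                   p$mu - 12 * p$sd, p$mu + 12 * p$sd,
                   rel.tol = 1e-10)$value
    expect_lt(abs(ei - q), 1e-4)
    # gamma = 0 reduces to sd * dnorm(0)
    if (g == 0) expect_equal(ei, p$sd * dnorm(0), tolerance = 1e-10)
  }
  expect_true(all(expected_improvement(m, matrix(runif(20), ncol = 1),
                                       min(y)) >= 0))
  # at a noiseless observation EI is zero up to the 1e-8 jitter (sd ~ 1e-4)
  m0 <- gp_fit(X, y, optimize_theta = FALSE,
               theta0 = list(ell = 0.3, sf = 1, sn = 1e-6))
  expect_lt(expected_improvement(m0, X[2, , drop = FALSE], min(y)), 1e-4)
})

test_that("Bayesian optimization finds a 1D quadratic minimum", {
  obj <- function(x) (x[1] - 0.3)^2
  r <- bo_optimize(obj, search_box(0, 1), n_init = 4, n_iter = 10, seed = 5)
  expect_lt(abs(r$best_x[[1]] - 0.3), 0.05)

  r2 <- bo_optimize(obj, search_box(0, 1), n_init = 4, n_iter = 10, seed = 5)
  expect_identical(r$history, r2$history)

  expect_equal(nrow(r$history), 14)  # n_init + n_iter evaluations
  expect_true(all(diff(r$history$incumbent) <= 0))

  r0 <- bo_optimize(obj, search_box(0, 1), n_init = 4, n_iter = 0, seed = 5)
  expect_equal(nrow(r0$history), 4)
  expect_equal(r0$best_value, min(r0$history$value))

  flaky <- function(x) if (x[1] > 0.5) NaN else (x[1] - 0.3)^2
  w <- capture_warnings(
    rf <- bo_optimize(flaky, search_box(0, 1), n_init = 4, n_iter = 2,
                      seed = 6))
  expect_true(any(grepl("non-finite", w)))
  expect_true(all(is.finite(rf$history$value)))
})
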