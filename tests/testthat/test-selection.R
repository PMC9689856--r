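test_that("the convergence coefficient is exactly linear from 2 to 0", {
  expect_equal(coefficient_c(0, 200), 2)
  expect_equal(coefficient_c(200, 200), 0)
  expect_equal(coefficient_c(50, 200), 1.5)
  expect_error(coefficient_c(1, 0), "positive")
})

test_that("the median follows the sorted-middle definition", {
  expect_equal(compute_md(c(3, 1, 2)), 2)
  expect_equal(compute_md(c(1, 2, 3, 4)), 2.5)
  expect_error(compute_md(numeric(0)), "empty")
  set.seed(1)
  for (n in c(999, 1000)) {
    v <- runif(n)
    expect_equal(compute_md(v), median(v))
  }
})

test_that("position binarization thresholds at 0.5 and never empties", {
  expect_equal(binarize_position(rep(1, 5)), rep(1L, 5))
  m0 <- binarize_position(c(0.1, 0.4, 0.2))
  expect_equal(sum(m0), 1L)
  expect_equal(which(m0 == 1L), 2L)  # largest position forced on
  set.seed(2)
  p <- runif(50)
  expect_equal(binarize_position(p), as.integer(p >= 0.5))
})

test_that("mask fitness tracks the planted structure", {
  tb <- make_table(table_recipe(n = 200, d = 50, k = 5, effect = 2,
                                seed = 10))
  cfg <- selection_config(seed = 10)
  m_inf <- integer(50); m_inf[tb$informative] <- 1L
  f_inf <- selection_fitness(m_inf, tb$x, tb$y, cfg)
  expect_lt(f_inf, 0.1)

  m_noise <- 1L - m_inf
  f_noise <- selection_fitness(m_noise, tb$x, tb$y, cfg)
  expect_lt(abs(f_noise - 0.5), 0.15)

  expect_identical(selection_fitness(m_inf, tb$x, tb$y, cfg), f_inf)
  expect_error(selection_fitness(integer(50), tb$x, tb$y, cfg), "empty")
  expect_error(selection_fitness(m_inf, tb$x, rep(1, 200), cfg),
               "at least 2")
})

test_that("a whale round reproduces a hand-stepped scalar oracle", {
  cfg <- selection_config(pop = 2, iters = 4, seed = 1)
  fit <- function(mask) sum(mask) / length(mask)  # deterministic, no RNG
  set.seed(11)
  state <- swarm_init(2, 2, 4, fit, cfg)
  seed_state <- .Random.seed
  s2 <- woa_update(state, fit)

  # oracle: replay the identical draw sequence with scalar arithmetic
  .Random.seed <<- seed_state
  cc <- 2 - 2 * state$v / state$V
  newpos <- state$pos
  for (i in 1:2) {
    y <- state$pos[i, ]
    P <- runif(1)
    md <- compute_md(y)
    if (P >= md) {
      l <- runif(1, -1, 1)
      y2 <- abs(state$best_pos - y) * exp(l) * cos(2 * pi * l) +
        state$best_pos
    } else {
      dvec <- runif(2)
      W <- 2 * cc * runif(1) - cc
      target <- if (abs(W) < 1) state$best_pos
                else state$pos[sample.int(2, 1), ]
      y2 <- target - W * abs(2 * dvec * target - y)
    }
    newpos[i, ] <- pmin(pmax(y2, 0), 1)
  }
  expect_equal(s2$pos, newpos, tolerance = 1e-14)
  expect_equal(s2$v, 1L)
  expect_lte(s2$best_fit, state$best_fit)  # elitism
  expect_true(all(s2$pos >= 0 & s2$pos <= 1))
})

test_that("a converged swarm at the best point is a fixed point when c = 0", {
  cfg <- selection_config(pop = 3, iters = 10, seed = 3)
  fit <- function(mask) 0.5
  set.seed(12)
  state <- swarm_init(3, 4, 10, fit, cfg)
  state$pos <- matrix(rep(state$best_pos, each = 3), 3, 4)
  state$v <- 10L  # c(v = V) = 0
  s2 <- woa_update(state, fit)
  expect_equal(s2$pos, state$pos, tolerance = 1e-12)
})

test_that("a Harris-Hawks step reproduces the two-branch update", {
  set.seed(13)
  pos <- matrix(runif(6), 2, 3)
  best <- runif(3)
  seed_state <- .Random.seed
  out <- wcepipe:::hho_step(pos, best)

  .Random.seed <<- seed_state
  ym <- colMeans(pos)
  oracle <- pos
  for (i in 1:2) {
    y <- pos[i, ]
    Q <- runif(1)
    d1 <- runif(1); d2 <- runif(1); d3 <- runif(1); d4 <- runif(1)
    y2 <- if (Q >= mean(y)) {
      yr <- pos[sample.int(2, 1), ]
      yr - d1 * abs(yr - 2 * d2 * y)
    } else (best - ym) - d3 * d4
    oracle[i, ] <- pmin(pmax(y2, 0), 1)
  }
  expect_equal(out, oracle, tolerance = 1e-14)
})

test_that("Harris-Hawks refinement never degrades the whale mask", {
  tb <- make_table(table_recipe(n = 120, d = 20, k = 3, effect = 2,
                                seed = 14))
  cfg <- selection_config(pop = 6, iters = 5, hho_iters = 8, seed = 14)
  start <- integer(20); start[c(tb$informative, 1, 2)] <- 1L
  f0 <- selection_fitness(start, tb$x, tb$y, cfg)

  set.seed(15)
  r0 <- hho_refine(tb$x, tb$y, start, cfg, iters = 0)
  expect_identical(r0$mask, start)
  expect_equal(r0$fitness, f0)

  set.seed(15)
  r <- hho_refine(tb$x, tb$y, start, cfg)
  expect_lte(r$fitness, f0)
  expect_true(all(diff(r$history) <= 0))
  expect_true(all(r$mask[start == 0] == 0))  # submatrix scope
})

test_that("hybrid selection is deterministic with a monotone history", {
  tb <- make_table(table_recipe(n = 120, d = 20, k = 3, effect = 2,
                                seed = 16))
  cfg <- selection_config(pop = 6, iters = 8, hho_iters = 4, seed = 16)
  r1 <- hybrid_select(tb$x, tb$y, cfg)
  r2 <- hybrid_select(tb$x, tb$y, cfg)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best_fitness) <= 0))
  woa_last <- min(r1$history$best_fitness[r1$history$phase == "woa"])
  expect_true(all(r1$history$best_fitness[r1$history$phase == "hho"] <=
                    woa_last))
  expect_equal(ncol(r1$selected), sum(r1$mask))
  expect_gte(sum(r1$mask), 1)

  expect_error(hybrid_select(tb$x[1:5, ], tb$y[1:5], cfg), "N >= 10")
})
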