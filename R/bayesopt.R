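#' A bounded hyperparameter search box
#'
#' @param lower,upper numeric vectors of per-dimension bounds
#'   (`lower < upper`).
#' @param log logical vector: dimensions searched on a log scale (use for
#'   ranges spanning orders of magnitude, e.g. learning rates).
#' @param names optional dimension names.
#' @return an object of class `search_box`.
#' @export
search_box <- function(lower, upper, log = rep(FALSE, length(lower)),
                       names = NULL) {
  stopifnot(length(lower) == length(upper), length(log) == length(lower),
            all(lower < upper), all(!log | lower > 0))
  structure(list(lower = lower, upper = upper, log = log,
                 names = names %||% paste0("x", seq_along(lower))),
            class = "search_box")
}

# unit-cube coordinates <-> original scale
box_from_unit <- function(box, z) {
  z <- pmin(pmax(z, 0), 1)
  x <- numeric(length(z))
  for (i in seq_along(z)) {
    x[i] <- if (box$log[i])
      exp(log(box$lower[i]) + z[i] * (log(box$upper[i]) - log(box$lower[i])))
    else box$lower[i] + z[i] * (box$upper[i] - box$lower[i])
  }
  names(x) <- box$names
  x
}

# Matern 5/2 covariance with per-dimension length scales.
# X1, X2: rows are points (already on the unit cube).
matern52 <- function(X1, X2, ell, sf2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  D2 <- matrix(0, n1, n2)
  for (d in seq_len(ncol(X1)))
    D2 <- D2 + outer(X1[, d] / ell[d], X2[, d] / ell[d], "-")^2
  r <- sqrt(pmax(D2, 0))
  s5 <- sqrt(5) * r
  sf2 * (1 + s5 + 5 * D2 / 3) * exp(-s5)
}

gp_nll <- function(theta, X, yc, jitter) {
  k <- ncol(X)
  ell <- exp(theta[seq_len(k)])
  sf2 <- exp(2 * theta[k + 1])
  sn2 <- exp(2 * theta[k + 2])
  K <- matern52(X, X, ell, sf2) + diag(sn2 + jitter, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  a <- backsolve(L, forwardsolve(t(L), yc))
  0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * length(yc) * log(2 * pi)
}

#' Fit a Gaussian-process surrogate
#'
#' Zero-mean (after centering) GP with a Matern 5/2 kernel, per-dimension
#' length scales, signal and noise variances. Kernel meta-parameters are set
#' by maximizing the marginal likelihood from several starts; the Cholesky
#' factorization is cached for prediction.
#'
#' @param x numeric matrix of observed points (rows), on the unit cube or
#'   any bounded scale.
#' @param y numeric vector of observed objective values.
#' @param optimize_theta fit kernel meta-parameters (default) or keep
#'   `theta0`.
#' @param theta0 optional initial/fixed meta-parameters as a list with
#'   `ell`, `sf`, `sn`.
#' @param jitter diagonal jitter added for numerical positive-definiteness.
#' @return an object of class `gp_model`.
#' @export
gp_fit <- function(x, y, optimize_theta = TRUE, theta0 = NULL,
                   jitter = 1e-8) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite observation", call. = FALSE)
  if (anyDuplicated(x)) warning("duplicate points; relying on jitter/noise")
  k <- ncol(x)
  mu0 <- mean(y)
  yc <- y - mu0
  sy <- max(sd(y), 1e-6)
  th <- if (!is.null(theta0))
    c(log(theta0$ell), log(theta0$sf), log(theta0$sn))
  else c(rep(log(0.3), k), log(sy), log(1e-3 * sy))
  if (optimize_theta) {
    starts <- list(th,
                   c(rep(log(0.1), k), log(sy), log(1e-2 * sy)),
                   c(rep(log(1.0), k), log(sy), log(1e-4 * sy)))
    best <- NULL; bestv <- Inf
    for (s in starts) {
      o <- tryCatch(
        optim(s, gp_nll, X = x, yc = yc, jitter = jitter,
              method = "L-BFGS-B",
              lower = c(rep(log(0.01), k), log(1e-4 * sy), log(1e-6 * sy)),
              upper = c(rep(log(10), k), log(100 * sy), log(1 * sy))),
        error = function(e) NULL)
      if (!is.null(o) && o$value < bestv) { bestv <- o$value; best <- o$par }
    }
    if (!is.null(best)) th <- best
  }
  ell <- exp(th[seq_len(k)]); sf2 <- exp(2 * th[k + 1]); sn2 <- exp(2 * th[k + 2])
  K <- matern52(x, x, ell, sf2) + diag(sn2 + jitter, nrow(x))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(x = x, y = y, mu0 = mu0, ell = ell, sf2 = sf2, sn2 = sn2,
                 L = L, alpha = alpha, jitter = jitter),
            class = "gp_model")
}

#' GP posterior mean and standard deviation
#'
#' @param model a [gp_fit()] model.
#' @param xstar a single point (vector) or matrix of points (rows).
#' @return list with vectors `mu` and `sd` (`sd >= 0`).
#' @export
gp_predict <- function(model, xstar) {
  if (is.null(dim(xstar))) xstar <- matrix(xstar, nrow = 1)
  Ks <- matern52(model$x, xstar, model$ell, model$sf2)
  mu <- model$mu0 + drop(crossprod(Ks, model$alpha))
  v <- forwardsolve(t(model$L), Ks)
  var <- pmax(model$sf2 - colSums(v^2), 0)
  list(mu = mu, sd = sqrt(var))
}

#' Expected improvement acquisition (minimization)
#'
#' `EI = sd * (gamma * pnorm(gamma) + dnorm(gamma))` with
#' `gamma = (best - mu) / sd`; defined as 0 where `sd == 0`.
#'
#' @param model a [gp_fit()] model.
#' @param xstar point(s) to score.
#' @param best_value incumbent (smallest observed) objective value.
#' @return non-negative EI value(s).
#' @export
expected_improvement <- function(model, xstar, best_value) {
  p <- gp_predict(model, xstar)
  ei <- numeric(length(p$mu))
  ok <- p$sd > 1e-12
  g <- (best_value - p$mu[ok]) / p$sd[ok]
  ei[ok] <- p$sd[ok] * (g * pnorm(g) + dnorm(g))
  pmax(ei, 0)
}

#' Bayesian optimization of a black-box objective
#'
#' Latin-hypercube initial design, then GP fit + expected-improvement
#' maximization (random candidates plus Nelder-Mead refinement of the best
#' few) each round. Minimization convention. Fully deterministic under
#' `seed` (the objective is evaluated inside the seeded stream).
#'
#' @param objective function of one numeric vector (original scale)
#'   returning a scalar; non-finite returns are recorded with a penalty
#'   value and a warning.
#' @param box a [search_box()].
#' @param n_init initial design size (at least 2).
#' @param n_iter number of BO rounds after the initial design.
#' @param seed RNG seed.
#' @param refine_starts candidates refined locally each round.
#' @param n_cand random EI candidates per round.
#' @return list with `best_x` (original scale), `best_value`, and `history`
#'   (data.frame: iteration, unit-cube coordinates, value, incumbent).
#' @export
bo_optimize <- function(objective, box, n_init = 5, n_iter = 15, seed = 1,
                        refine_starts = 5, n_cand = 256) {
  stopifnot(inherits(box, "search_box"), n_init >= 2, n_iter >= 0)
  k <- length(box$lower)
  with_seed(seed, {
    Z <- lhs::randomLHS(n_init, k)
    vals <- numeric(n_init)
    evaluate <- function(z) {
      v <- tryCatch(objective(box_from_unit(box, z)), error = function(e) NaN)
      if (!is.finite(v)) {
        warning("objective returned non-finite value; penalized")
        v <- NA_real_
      }
      v
    }
    for (i in seq_len(n_init)) vals[i] <- evaluate(Z[i, ])
    penalty <- function(v) {
      fin <- v[is.finite(v)]
      if (!length(fin)) return(rep(1e6, length(v)))
      v[!is.finite(v)] <- max(fin) + diff(range(fin)) + 1
      v
    }
    for (it in seq_len(n_iter)) {
      yv <- penalty(vals)
      model <- gp_fit(Z, yv)
      best <- min(yv)
      cand <- matrix(runif(n_cand * k), n_cand, k)
      ei <- expected_improvement(model, cand, best)
      top <- order(ei, decreasing = TRUE)[seq_len(min(refine_starts, n_cand))]
      bz <- cand[top[1], ]; bei <- ei[top[1]]
      negei <- function(z) {
        if (any(z < 0) || any(z > 1)) return(0)
        -expected_improvement(model, z, best)
      }
      for (s in top) {
        o <- if (k == 1)
          optim(cand[s, ], negei, method = "Brent", lower = 0, upper = 1)
        else optim(cand[s, ], negei, method = "Nelder-Mead",
                   control = list(maxit = 100, reltol = 1e-6))
        if (-o$value > bei) { bei <- -o$value; bz <- pmin(pmax(o$par, 0), 1) }
      }
      Z <- rbind(Z, bz)
      vals <- c(vals, evaluate(bz))
    }
    yv <- penalty(vals)
    inc <- cummin(yv)
    hist <- data.frame(iteration = seq_along(yv), Z, value = yv,
                       incumbent = inc)
    names(hist)[1 + seq_len(k)] <- box$names
    ibest <- which.min(yv)
    list(best_x = box_from_unit(box, Z[ibest, ]), best_value = yv[ibest],
         history = hist)
  })
}
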