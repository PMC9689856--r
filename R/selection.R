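#' Configuration of the hybrid whale / Harris-Hawks feature selection
#'
#' A wrapper selector: continuous agent positions in `[0, 1]^D` are
#' thresholded to binary column masks whose fitness is the holdout error
#' rate of an ELM trained on the masked columns. A whale-optimization phase
#' (encircling / random-search / logarithmic-spiral updates, with the spiral
#' branch chosen when a uniform draw exceeds the *median* of the agent's
#' position values) runs for `iters` rounds; the best mask is then refined
#' by a Harris-Hawks exploration phase whose branch rule uses the *mean* of
#' the agent's position values.
#'
#' @param pop population size (at least 2).
#' @param iters whale-phase iterations `V` (default 200).
#' @param hho_iters Harris-Hawks refinement iterations (default 50).
#' @param transfer continuous-to-binary transfer function (`"sigmoid"`).
#' @param md_source whale branch statistic: `"position"` (median of the
#'   agent's position values, default) or `"fitness"` (median of the
#'   population fitness values).
#' @param hho_scope `"submatrix"` (refine within the whale-selected columns,
#'   default) or `"full"` (re-search all columns warm-started at the whale
#'   mask).
#' @param spiral_a logarithmic-spiral shape constant.
#' @param elm_hidden hidden units of the fitness ELM.
#' @param elm_ridge ridge of the fitness ELM.
#' @param val_fraction holdout fraction of each fitness split.
#' @param fitness_repeats number of seeded stratified holdout repetitions
#'   averaged into one fitness value; repetition smooths the 1/n-test
#'   granularity of a single split and markedly stabilizes the search.
#' @param seed RNG seed; the whole search is deterministic given the seed.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(pop = 10, iters = 200, hho_iters = 50,
                             transfer = "sigmoid",
                             md_source = c("position", "fitness"),
                             hho_scope = c("submatrix", "full"),
                             spiral_a = 1, elm_hidden = 100,
                             elm_ridge = 1e-6, val_fraction = 0.3,
                             fitness_repeats = 3, seed = 1) {
  md_source <- match.arg(md_source)
  hho_scope <- match.arg(hho_scope)
  stopifnot(pop >= 2, iters >= 1, hho_iters >= 0, elm_hidden >= 1,
            val_fraction > 0, val_fraction < 1, fitness_repeats >= 1)
  structure(list(pop = as.integer(pop), iters = as.integer(iters),
                 hho_iters = as.integer(hho_iters), transfer = transfer,
                 md_source = md_source, hho_scope = hho_scope,
                 spiral_a = spiral_a, elm_hidden = as.integer(elm_hidden),
                 elm_ridge = elm_ridge, val_fraction = val_fraction,
                 fitness_repeats = as.integer(fitness_repeats),
                 seed = seed),
            class = "selection_config")
}

#' Whale-optimization convergence coefficient
#'
#' Declines linearly from 2 at `v = 0` to 0 at `v = V`.
#'
#' @param v current iteration (`0 <= v <= V`).
#' @param V total iterations (positive).
#' @return `2 - 2 * v / V`.
#' @export
coefficient_c <- function(v, V) {
  if (V == 0) stop("V must be positive", call. = FALSE)
  stopifnot(v >= 0, v <= V)
  2 - 2 * v / V
}

#' Median of a numeric vector (sorted-middle definition)
#'
#' Middle order statistic for odd length; mean of the two middle order
#' statistics for even length.
#'
#' @param values non-empty numeric vector.
#' @return the median.
#' @export
compute_md <- function(values) {
  if (length(values) == 0) stop("empty vector", call. = FALSE)
  s <- sort(values)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

#' Threshold a continuous position into a feature mask
#'
#' An S-shaped transfer centered at 0.5 followed by a 0.5 cut (equivalently,
#' positions at or above 0.5 are selected). An all-empty mask is repaired by
#' forcing the dimension with the largest position on.
#'
#' @param position numeric vector in `[0, 1]^D`.
#' @param transfer transfer-function name (only `"sigmoid"`).
#' @return integer 0/1 vector with at least one 1.
#' @export
binarize_position <- function(position, transfer = "sigmoid") {
  stopifnot(transfer == "sigmoid")
  s <- 1 / (1 + exp(-10 * (position - 0.5)))
  mask <- as.integer(s >= 0.5)
  if (!any(mask == 1)) mask[which.max(position)] <- 1L
  mask
}

#' Holdout-error fitness of a feature mask
#'
#' Trains an ELM on the masked columns of `fitness_repeats` seeded
#' stratified train/validation splits and returns the mean validation error
#' rate plus a vanishing feature-count term (`1e-6 * k / D`) that breaks
#' ties between equal-error masks toward fewer features.
#'
#' @param mask 0/1 vector over the feature columns (at least one 1).
#' @param features `N x D` matrix.
#' @param labels class labels (at least 2 classes).
#' @param cfg a [selection_config()].
#' @return the fitness value (smaller is better).
#' @export
selection_fitness <- function(mask, features, labels, cfg = selection_config()) {
  if (!any(mask == 1)) stop("empty mask", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("need at least 2 classes", call. = FALSE)
  D <- ncol(features)
  idx <- which(mask == 1)
  errs <- vapply(seq_len(cfg$fitness_repeats) - 1L, function(k) {
    split <- stratified_split(labels, 1 - cfg$val_fraction,
                              seed = cfg$seed + 1000L * k)
    m <- elm_train(features[split$train, idx, drop = FALSE],
                   labels[split$train], hidden_units = cfg$elm_hidden,
                   ridge = cfg$elm_ridge, seed = cfg$seed + k)
    mean(elm_predict(m, features[split$test, idx, drop = FALSE]) !=
           labels[split$test])
  }, numeric(1))
  mean(errs) + 1e-6 * length(idx) / D
}

#' Seeded stratified train/test split
#' @param labels class labels.
#' @param train_fraction fraction per class assigned to training.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.5, seed = 1) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      ids <- which(labels == cl)
      n_tr <- max(1L, round(train_fraction * length(ids)))
      n_tr <- min(n_tr, length(ids) - 1L)
      train <- c(train, sample(ids, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Initialize a whale-optimization swarm
#'
#' @param pop population size.
#' @param d dimensionality (feature count).
#' @param V total whale iterations.
#' @param fitness_fn function mapping a 0/1 mask to a fitness value.
#' @param cfg a [selection_config()].
#' @return a `swarm_state`: positions, fitness values, global best, and the
#'   iteration counter. Positions are drawn from the caller's RNG stream.
#' @export
swarm_init <- function(pop, d, V, fitness_fn, cfg = selection_config()) {
  pos <- matrix(runif(pop * d), pop, d)
  fit <- apply(pos, 1, function(p)
    fitness_fn(binarize_position(p, cfg$transfer)))
  ib <- which.min(fit)
  structure(list(pos = pos, fit = fit, best_pos = pos[ib, ],
                 best_fit = fit[ib], v = 0L, V = as.integer(V), cfg = cfg),
            class = "swarm_state")
}

#' One whale-optimization round
#'
#' Per agent: draw `P ~ U[0,1]`; when `P` is at or above the branch median
#' the agent spirals around the global best
#' (`|Y* - Y| * exp(a l) * cos(2 pi l) + Y*`, `l ~ U[-1, 1]`); otherwise it
#' encircles the best (`|W| < 1`) or a random agent (`|W| >= 1`) with
#' `W = 2 c d - c`, `c` declining linearly from 2 to 0. Positions are
#' clipped to `[0, 1]`; the global best is retained (elitism). Random draws
#' come from the caller's RNG stream.
#'
#' @param state a `swarm_state`.
#' @param fitness_fn mask-fitness function.
#' @return the updated `swarm_state` (`v` incremented).
#' @export
woa_update <- function(state, fitness_fn) {
  cfg <- state$cfg
  pop <- nrow(state$pos); d <- ncol(state$pos)
  cc <- coefficient_c(state$v, state$V)
  newpos <- state$pos
  for (i in seq_len(pop)) {
    y <- state$pos[i, ]
    P <- runif(1)
    md <- if (cfg$md_source == "position") compute_md(y)
          else compute_md(state$fit)
    if (P >= md) {
      l <- runif(1, -1, 1)
      X <- abs(state$best_pos - y)
      y2 <- X * exp(cfg$spiral_a * l) * cos(2 * pi * l) + state$best_pos
    } else {
      dvec <- runif(d)
      W <- 2 * cc * runif(1) - cc
      U <- 2 * dvec
      target <- if (abs(W) < 1) state$best_pos
                else state$pos[sample.int(pop, 1), ]
      X <- abs(U * target - y)
      y2 <- target - W * X
    }
    newpos[i, ] <- pmin(pmax(y2, 0), 1)
  }
  fit <- apply(newpos, 1, function(p)
    fitness_fn(binarize_position(p, cfg$transfer)))
  state$pos <- newpos
  state$fit <- fit
  ib <- which.min(fit)
  if (fit[ib] < state$best_fit) {
    state$best_fit <- fit[ib]
    state$best_pos <- newpos[ib, ]
  }
  state$v <- state$v + 1L
  state
}

# one Harris-Hawks exploration round on a position matrix; returns new matrix
hho_step <- function(pos, best_pos) {
  pop <- nrow(pos); d <- ncol(pos)
  ym <- colMeans(pos)
  newpos <- pos
  for (i in seq_len(pop)) {
    y <- pos[i, ]
    Q <- runif(1)
    d1 <- runif(1); d2 <- runif(1); d3 <- runif(1); d4 <- runif(1)
    if (Q >= mean(y)) {
      yr <- pos[sample.int(pop, 1), ]
      y2 <- yr - d1 * abs(yr - 2 * d2 * y)
    } else {
      y2 <- (best_pos - ym) - d3 * (0 + d4 * (1 - 0))
    }
    newpos[i, ] <- pmin(pmax(y2, 0), 1)
  }
  newpos
}

#' Harris-Hawks refinement of a whale-selected mask
#'
#' Runs the two-branch Harris-Hawks exploration (perch near a random agent
#' when `Q` is at or above the mean of the agent's position values,
#' otherwise relative to the best agent and the population mean) for
#' `cfg$hho_iters` rounds. With `cfg$hho_scope = "submatrix"` the search is
#' restricted to the columns already selected by `start_mask`; with
#' `"full"` it re-searches all columns warm-started at `start_mask`. The
#' returned mask is never worse in fitness than `start_mask` (elitism).
#' Random draws come from the caller's RNG stream.
#'
#' @param features `N x D` matrix.
#' @param labels class labels.
#' @param start_mask 0/1 vector from the whale phase.
#' @param cfg a [selection_config()].
#' @param iters override of `cfg$hho_iters`.
#' @param fitness_fn optional mask-fitness function (e.g. a memoized
#'   wrapper); defaults to [selection_fitness()].
#' @return list with `mask` (full-length 0/1 vector), `fitness`, and
#'   `history` (best fitness per round, monotone non-increasing).
#' @export
hho_refine <- function(features, labels, start_mask,
                       cfg = selection_config(), iters = NULL,
                       fitness_fn = NULL) {
  iters <- iters %||% cfg$hho_iters
  D <- ncol(features)
  stopifnot(length(start_mask) == D)
  fit_full <- fitness_fn %||%
    function(mask) selection_fitness(mask, features, labels, cfg)
  best_fit <- fit_full(start_mask)
  best_mask <- as.integer(start_mask)
  if (iters == 0)
    return(list(mask = best_mask, fitness = best_fit, history = best_fit))
  sub <- cfg$hho_scope == "submatrix"
  cols <- if (sub) which(start_mask == 1) else seq_len(D)
  d <- length(cols)
  to_full <- function(submask) {
    m <- integer(D)
    m[cols[submask == 1]] <- 1L
    if (!any(m == 1)) m[cols[1]] <- 1L
    m
  }
  pos <- matrix(runif(cfg$pop * d), cfg$pop, d)
  pos[1, ] <- 0.9  # warm start: the incoming mask
  if (!sub) pos[1, ] <- ifelse(start_mask == 1, 0.9, 0.1)
  evals <- apply(pos, 1, function(p)
    fit_full(to_full(binarize_position(p, cfg$transfer))))
  ib <- which.min(evals)
  best_pos <- pos[ib, ]
  if (evals[ib] < best_fit) {
    best_fit <- evals[ib]
    best_mask <- to_full(binarize_position(pos[ib, ], cfg$transfer))
  }
  history <- best_fit
  for (it in seq_len(iters)) {
    pos <- hho_step(pos, best_pos)
    evals <- apply(pos, 1, function(p)
      fit_full(to_full(binarize_position(p, cfg$transfer))))
    ib <- which.min(evals)
    if (evals[ib] < best_fit) {
      best_fit <- evals[ib]
      best_pos <- pos[ib, ]
      best_mask <- to_full(binarize_position(pos[ib, ], cfg$transfer))
    }
    history <- c(history, best_fit)
  }
  list(mask = best_mask, fitness = best_fit, history = history)
}

#' Hybrid whale + Harris-Hawks feature selection
#'
#' Whale-optimization phase over all columns for `cfg$iters` rounds, then
#' Harris-Hawks refinement of the best mask. Fitness values are memoized per
#' mask, the best-so-far fitness history is monotone non-increasing, and the
#' whole run is a pure function of (`features`, `labels`, `cfg`).
#'
#' @param features `N x D` matrix (`N >= 10`, `D >= 2`).
#' @param labels class labels (at least 2 classes).
#' @param cfg a [selection_config()].
#' @return list with `mask` (0/1 vector), `selected` (column-subset
#'   matrix), `fitness`, and `history` (data.frame: phase, iteration,
#'   best_fitness).
#' @export
hybrid_select <- function(features, labels, cfg = selection_config()) {
  features <- as.matrix(features)
  if (nrow(features) < 10 || ncol(features) < 2)
    stop("need N >= 10 samples and D >= 2 features", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("need at least 2 classes", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  fit_fn <- function(mask) {
    key <- paste(mask, collapse = "")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- selection_fitness(mask, features, labels, cfg)
      cache[[key]] <- v
    }
    v
  }
  with_seed(cfg$seed, {
    state <- swarm_init(cfg$pop, ncol(features), cfg$iters, fit_fn, cfg)
    woa_hist <- state$best_fit
    for (it in seq_len(cfg$iters)) {
      state <- woa_update(state, fit_fn)
      woa_hist <- c(woa_hist, state$best_fit)
    }
    start_mask <- binarize_position(state$best_pos, cfg$transfer)
    if (fit_fn(start_mask) > state$best_fit) {
      # guard: best_fit always corresponds to the binarized best position
      state$best_fit <- fit_fn(start_mask)
    }
    hho <- hho_refine(features, labels, start_mask, cfg, fitness_fn = fit_fn)
    # elitism across phases
    if (hho$fitness > state$best_fit) {
      hho$mask <- start_mask
      hho$fitness <- state$best_fit
      hho$history <- pmin(hho$history, state$best_fit)
    }
    history <- rbind(
      data.frame(phase = "woa", iteration = seq_along(woa_hist) - 1L,
                 best_fitness = woa_hist),
      data.frame(phase = "hho", iteration = seq_along(hho$history) - 1L,
                 best_fitness = pmin(hho$history, min(woa_hist))))
    list(mask = hho$mask, selected = features[, hho$mask == 1, drop = FALSE],
         fitness = min(hho$fitness, state$best_fit), history = history)
  })
}
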