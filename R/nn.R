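# Minimal CNN engine on plain R arrays.
#
# Tensors are (H, W, C, N) arrays up to the global average pool, then (C, N)
# matrices. Convolutions are computed as kh*kw shift-and-multiply BLAS
# matmuls, which keeps everything vectorized without an im2col buffer.
# Backward passes exist for every trainable layer; depthwise convolutions
# (used only by the forward-only MobileNetV2 topology) are inference-only.

nn_conv <- function(k, cin, cout, stride = 1L, pad = 1L) {
  list(type = "conv", k = as.integer(k), cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad))
}
nn_dwconv <- function(k, c, stride = 1L, pad = 1L) {
  list(type = "dwconv", k = as.integer(k), cin = c, cout = c,
       stride = as.integer(stride), pad = as.integer(pad))
}
nn_bn <- function(c) list(type = "bn", c = c, eps = 1e-5, momentum = 0.1)
nn_relu <- function() list(type = "relu")
nn_relu6 <- function() list(type = "relu6")
nn_maxpool <- function() list(type = "maxpool")
nn_avgpool <- function() list(type = "avgpool")
nn_fc <- function(cin, cout) list(type = "fc", cin = cin, cout = cout)
nn_softmax <- function() list(type = "softmax")

# initialize parameters (He for conv/fc, identity for BN) under `seed`
net_init <- function(layers, seed = 1) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type == "conv") {
        sd <- sqrt(2 / (l$k * l$k * l$cin))
        l$W <- array(rnorm(l$k * l$k * l$cin * l$cout, 0, sd),
                     c(l$k, l$k, l$cin, l$cout))
        l$b <- numeric(l$cout)
      } else if (l$type == "dwconv") {
        sd <- sqrt(2 / (l$k * l$k))
        l$W <- array(rnorm(l$k * l$k * l$cin, 0, sd), c(l$k, l$k, l$cin))
        l$b <- numeric(l$cout)
      } else if (l$type == "bn") {
        l$gamma <- rep(1, l$c); l$beta <- numeric(l$c)
        l$rmean <- numeric(l$c); l$rvar <- rep(1, l$c)
      } else if (l$type == "fc") {
        sd <- sqrt(2 / l$cin)
        l$W <- matrix(rnorm(l$cin * l$cout, 0, sd), l$cin, l$cout)
        l$b <- numeric(l$cout)
      }
      layers[[i]] <- l
    }
  })
  structure(list(layers = layers), class = "wce_net")
}

pad_tensor <- function(X, p) {
  if (p == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  Xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- X
  Xp
}

conv_out_dim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

conv_forward <- function(l, X) {
  d <- dim(X)
  Xp <- pad_tensor(X, l$pad)
  Ho <- conv_out_dim(d[1], l$k, l$stride, l$pad)
  Wo <- conv_out_dim(d[2], l$k, l$stride, l$pad)
  N <- d[4]
  Ymat <- matrix(rep(l$b, each = Ho * Wo * N), Ho * Wo * N, l$cout)
  for (a in seq_len(l$k)) for (b in seq_len(l$k)) {
    rows <- a + l$stride * (seq_len(Ho) - 1L)
    cols <- b + l$stride * (seq_len(Wo) - 1L)
    Xs <- Xp[rows, cols, , , drop = FALSE]
    M <- matrix(aperm(Xs, c(1, 2, 4, 3)), ncol = l$cin)
    Ymat <- Ymat + M %*% matrix(l$W[a, b, , ], l$cin, l$cout)
  }
  Y <- aperm(array(Ymat, c(Ho, Wo, N, l$cout)), c(1, 2, 4, 3))
  list(out = Y, cache = list(Xp = Xp, dims = d, Ho = Ho, Wo = Wo))
}

conv_backward <- function(l, cache, dY) {
  Xp <- cache$Xp; Ho <- cache$Ho; Wo <- cache$Wo
  N <- cache$dims[4]
  dYmat <- matrix(aperm(dY, c(1, 2, 4, 3)), ncol = l$cout)
  dW <- array(0, dim(l$W))
  dXp <- array(0, dim(Xp))
  for (a in seq_len(l$k)) for (b in seq_len(l$k)) {
    rows <- a + l$stride * (seq_len(Ho) - 1L)
    cols <- b + l$stride * (seq_len(Wo) - 1L)
    Xs <- Xp[rows, cols, , , drop = FALSE]
    M <- matrix(aperm(Xs, c(1, 2, 4, 3)), ncol = l$cin)
    dW[a, b, , ] <- crossprod(M, dYmat)
    dM <- dYmat %*% t(matrix(l$W[a, b, , ], l$cin, l$cout))
    dXs <- aperm(array(dM, c(Ho, Wo, N, l$cin)), c(1, 2, 4, 3))
    dXp[rows, cols, , ] <- dXp[rows, cols, , , drop = FALSE] + dXs
  }
  p <- l$pad
  d <- cache$dims
  dX <- if (p > 0L) dXp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
        else dXp
  list(dX = dX, grads = list(W = dW, b = colSums(dYmat)))
}

dwconv_forward <- function(l, X) {
  d <- dim(X)
  Xp <- pad_tensor(X, l$pad)
  Ho <- conv_out_dim(d[1], l$k, l$stride, l$pad)
  Wo <- conv_out_dim(d[2], l$k, l$stride, l$pad)
  Y <- array(rep(l$b, each = Ho * Wo), c(Ho, Wo, l$cin, d[4]))
  for (a in seq_len(l$k)) for (b in seq_len(l$k)) {
    rows <- a + l$stride * (seq_len(Ho) - 1L)
    cols <- b + l$stride * (seq_len(Wo) - 1L)
    Xs <- Xp[rows, cols, , , drop = FALSE]
    Y <- Y + Xs * rep(l$W[a, b, ], each = Ho * Wo)
  }
  list(out = Y, cache = NULL)
}

bn_forward <- function(l, X, train) {
  d <- dim(X)
  R <- d[1] * d[2] * d[4]
  Xm <- matrix(aperm(X, c(1, 2, 4, 3)), ncol = l$c)
  if (train) {
    mu <- colMeans(Xm)
    va <- colMeans(Xm^2) - mu^2
    l$rmean <- (1 - l$momentum) * l$rmean + l$momentum * mu
    l$rvar <- (1 - l$momentum) * l$rvar + l$momentum * va * R / max(R - 1, 1)
  } else {
    mu <- l$rmean; va <- l$rvar
  }
  istd <- 1 / sqrt(va + l$eps)
  xhat <- (Xm - rep(mu, each = R)) * rep(istd, each = R)
  Ym <- xhat * rep(l$gamma, each = R) + rep(l$beta, each = R)
  Y <- aperm(array(Ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = Y, cache = list(xhat = xhat, istd = istd, dims = d, R = R),
       layer = l)
}

bn_backward <- function(l, cache, dY) {
  d <- cache$dims; R <- cache$R
  dYm <- matrix(aperm(dY, c(1, 2, 4, 3)), ncol = l$c)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxh <- dYm * rep(l$gamma, each = R)
  s1 <- colSums(dxh); s2 <- colSums(dxh * cache$xhat)
  dXm <- (dxh - rep(s1 / R, each = R) -
            cache$xhat * rep(s2 / R, each = R)) * rep(cache$istd, each = R)
  dX <- aperm(array(dXm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

maxpool_forward <- function(X) {
  d <- dim(X)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  x11 <- X[i1, j1, , , drop = FALSE]; x12 <- X[i1, j1 + 1L, , , drop = FALSE]
  x21 <- X[i1 + 1L, j1, , , drop = FALSE]
  x22 <- X[i1 + 1L, j1 + 1L, , , drop = FALSE]
  Y <- pmax(x11, x12, x21, x22)
  m11 <- x11 == Y
  m12 <- (x12 == Y) & !m11
  m21 <- (x21 == Y) & !m11 & !m12
  m22 <- !m11 & !m12 & !m21
  list(out = Y, cache = list(m = list(m11, m12, m21, m22), dims = d))
}

maxpool_backward <- function(cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  m <- cache$m
  dX[i1, j1, , ] <- dY * m[[1]]
  dX[i1, j1 + 1L, , ] <- dY * m[[2]]
  dX[i1 + 1L, j1, , ] <- dY * m[[3]]
  dX[i1 + 1L, j1 + 1L, , ] <- dY * m[[4]]
  dX
}

avgpool_forward <- function(X) {
  d <- dim(X)
  Y <- matrix(colMeans(matrix(X, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(out = Y, cache = d)
}

avgpool_backward <- function(cache, dY) {
  d <- cache
  array(rep(as.vector(dY), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

fc_forward <- function(l, X, train, dropout) {
  mask <- NULL
  if (train && dropout > 0) {
    mask <- matrix(rbinom(length(X), 1, 1 - dropout) / (1 - dropout),
                   nrow(X), ncol(X))
    X <- X * mask
  }
  list(out = crossprod(l$W, X) + l$b, cache = list(X = X, mask = mask))
}

fc_backward <- function(l, cache, dY) {
  dX <- l$W %*% dY
  if (!is.null(cache$mask)) dX <- dX * cache$mask
  list(dX = dX, grads = list(W = cache$X %*% t(dY), b = rowSums(dY)))
}

softmax_forward <- function(X) {
  Z <- exp(sweep(X, 2, apply(X, 2, max)))
  sweep(Z, 2, colSums(Z), "/")
}

#' @noRd
net_forward <- function(net, X, train = FALSE, upto = NULL,
                        dropout = 0, collect = FALSE) {
  layers <- net$layers
  n <- if (is.null(upto)) length(layers) else upto
  caches <- vector("list", n)
  acts <- if (collect) vector("list", n) else NULL
  for (i in seq_len(n)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(l, X),
      dwconv = dwconv_forward(l, X),
      bn = bn_forward(l, X, train),
      relu = list(out = pmax(X, 0), cache = X > 0),
      relu6 = list(out = pmin(pmax(X, 0), 6), cache = X > 0 & X < 6),
      maxpool = maxpool_forward(X),
      avgpool = avgpool_forward(X),
      fc = fc_forward(l, X, train, dropout),
      softmax = list(out = softmax_forward(X), cache = NULL),
      stop("unknown layer type: ", l$type))
    if (l$type == "bn" && train) net$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    X <- r$out
    if (collect) acts[[i]] <- X
  }
  list(out = X, caches = caches, net = net, acts = acts)
}

# Backward from a gradient w.r.t. the softmax logits (cross-entropy fused:
# the caller passes probs - onehot, and the softmax layer is skipped).
net_backward <- function(net, caches, dTop) {
  layers <- net$layers
  n <- length(layers)
  grads <- vector("list", n)
  dX <- dTop
  start <- if (layers[[n]]$type == "softmax") n - 1L else n
  for (i in seq(start, 1L)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_backward(l, caches[[i]], dX); dX <- r$dX; grads[[i]] <- r$grads
    } else if (l$type == "bn") {
      r <- bn_backward(l, caches[[i]], dX); dX <- r$dX; grads[[i]] <- r$grads
    } else if (l$type %in% c("relu", "relu6")) {
      dX <- dX * caches[[i]]
    } else if (l$type == "maxpool") {
      dX <- maxpool_backward(caches[[i]], dX)
    } else if (l$type == "avgpool") {
      dX <- avgpool_backward(caches[[i]], dX)
    } else if (l$type == "fc") {
      r <- fc_backward(l, caches[[i]], dX); dX <- r$dX; grads[[i]] <- r$grads
    } else if (l$type == "dwconv") {
      stop("depthwise convolution is inference-only")
    }
  }
  grads
}

# SGD with momentum and L2 weight decay (decay on W/gamma only)
net_sgd_step <- function(net, grads, state, lr, momentum, l2) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- net$layers[[i]]
    for (nm in names(g)) {
      gr <- g[[nm]]
      if (nm %in% c("W", "gamma")) gr <- gr + l2 * l[[nm]]
      key <- paste0(i, ".", nm)
      v <- state[[key]]
      if (is.null(v)) v <- gr * 0
      v <- momentum * v - lr * gr
      state[[key]] <- v
      l[[nm]] <- l[[nm]] + v
    }
    net$layers[[i]] <- l
  }
  list(net = net, state = state)
}

onehot <- function(y, C) {
  T <- matrix(0, C, length(y))
  T[cbind(y, seq_along(y))] <- 1
  T
}

#' @noRd
net_train <- function(net, X, y, epochs, lr, momentum = 0.9, l2 = 0,
                      batch = 32, dropout = 0, seed = 1, clip_grad = 5) {
  N <- dim(X)[4]
  state <- list()
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(N)
      tot <- 0
      for (b0 in seq(1L, N, by = batch)) {
        ids <- idx[b0:min(b0 + batch - 1L, N)]
        Xb <- X[, , , ids, drop = FALSE]
        fw <- net_forward(net, Xb, train = TRUE, dropout = dropout)
        net <- fw$net
        P <- fw$out
        Tb <- onehot(y[ids], nrow(P))
        loss <- -mean(log(pmax(P[Tb == 1], 1e-12)))
        tot <- tot + loss * length(ids)
        dTop <- (P - Tb) / length(ids)
        grads <- net_backward(net, fw$caches, dTop)
        # global gradient-norm clip keeps high-lr runs finite
        gn <- sqrt(sum(vapply(grads, function(g)
          if (is.null(g)) 0 else sum(vapply(g, function(z) sum(z^2),
                                            numeric(1))), numeric(1))))
        if (is.finite(gn) && gn > clip_grad) {
          sc <- clip_grad / gn
          grads <- lapply(grads, function(g)
            if (is.null(g)) NULL else lapply(g, function(z) z * sc))
        }
        st <- net_sgd_step(net, grads, state, lr, momentum, l2)
        net <- st$net; state <- st$state
      }
      losses[ep] <- tot / N
    }
  })
  net <- net_calibrate_bn(net, X)
  list(net = net, loss = losses)
}

# set BN running statistics from a full pass over X (eval-mode calibration)
net_calibrate_bn <- function(net, X) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "bn") {
      l$momentum <- 1
      net$layers[[i]] <- l
    }
  }
  fw <- net_forward(net, X, train = TRUE)
  net <- fw$net
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "bn") {
      l$momentum <- 0.1
      net$layers[[i]] <- l
    }
  }
  net
}

#' @noRd
net_predict_probs <- function(net, X, batch = 64) {
  N <- dim(X)[4]
  out <- NULL
  for (b0 in seq(1L, N, by = batch)) {
    ids <- b0:min(b0 + batch - 1L, N)
    P <- net_forward(net, X[, , , ids, drop = FALSE], train = FALSE)$out
    out <- if (is.null(out)) P else cbind(out, P)
  }
  out
}

net_predict_class <- function(net, X, batch = 64) {
  P <- net_predict_probs(net, X, batch)
  max.col(t(P), ties.method = "first")
}
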