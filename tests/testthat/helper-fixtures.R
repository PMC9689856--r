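# shared fixtures and brute-force oracles

# two-class blob images: a bright square whose corner position encodes the
# class; trivially separable
make_blob_set <- function(n = 20, size = 64, seed = 1) {
  set.seed(seed)
  imgs <- vector("list", n)
  labs <- integer(n)
  for (i in seq_len(n)) {
    im <- array(runif(size * size * 3) * 0.1, c(size, size, 3))
    cls <- 1L + (i %% 2L)
    if (cls == 1L) im[10:30, 10:30, ] <- im[10:30, 10:30, ] + 0.8
    else im[(size - 30):(size - 10), (size - 30):(size - 10), ] <-
        im[(size - 30):(size - 10), (size - 30):(size - 10), ] + 0.8
    imgs[[i]] <- clamp01(im)
    labs[i] <- cls
  }
  list(images = imgs, labels = labs)
}

# scalar-loop median-of-9 with replicated borders
oracle_median3 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  p <- x[c(1, seq_len(n), n), c(1, seq_len(m), m)]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- median(p[i:(i + 2), j:(j + 2)])
  out
}

# a smooth colorful scene in the dark-channel prior's regime: every pixel
# has one near-zero channel
dcp_scene <- function(size = 48, seed = 1) {
  set.seed(seed)
  g <- 6
  low <- array(runif(g * g * 3), c(g, g, 3))
  sc <- array(0, c(size, size, 3))
  for (ch in 1:3) sc[, , ch] <- resize_gray(low[, , ch], size, size)
  mn <- pmin(sc[, , 1], sc[, , 2], sc[, , 3])
  for (ch in 1:3) sc[, , ch] <- sc[, , ch] - mn
  clamp01(sc)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
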