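test_that("channel split is an exact round trip", {
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 1
  ch <- split_channels(red)
  expect_equal(ch$c1, matrix(1, 4, 4))
  expect_equal(ch$c2, matrix(0, 4, 4))
  expect_equal(ch$c3, matrix(0, 4, 4))

  set.seed(1)
  img <- array(runif(2 * 2 * 3), c(2, 2, 3))
  ch <- split_channels(img)
  expect_identical(ch$c1, img[, , 1])
  expect_identical(ch$c3, img[, , 3])
  back <- array(0, c(2, 2, 3))
  back[, , 1] <- ch$c1; back[, , 2] <- ch$c2; back[, , 3] <- ch$c3
  expect_identical(back, img)

  expect_error(split_channels(matrix(0, 3, 3)), "H x W x 3")
})

test_that("denoising preserves shape and identity/median semantics", {
  set.seed(2)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  d <- denoise_channels(split_channels(img), denoiser_handle("identity"))
  expect_equal(d$f4, img)

  const <- matrix(0.4, 8, 8)
  expect_equal(denoiser_handle("median")$fn(const), const)

  salt <- matrix(0.1, 9, 9); salt[5, 5] <- 1
  f <- denoiser_handle("median")$fn(salt)
  expect_equal(f, oracle_median3(salt))
  expect_equal(f[5, 5], 0.1)

  bad <- list(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 5, 5))
  expect_error(denoise_channels(bad), "mismatch")
})

test_that("exact 3x3 median matches a brute-force oracle", {
  set.seed(3)
  x <- matrix(runif(20 * 20), 20, 20)
  expect_equal(median_filter3(x), oracle_median3(x), tolerance = 1e-14)
})

test_that("non-local means is shape-preserving and smooths noise", {
  set.seed(8)
  x <- matrix(0.5, 16, 16) + matrix(rnorm(256, 0, 0.1), 16, 16)
  y <- denoiser_handle("nlm", h = 0.2)$fn(x)
  expect_identical(dim(y), dim(x))
  expect_lt(sd(y), sd(x))
})

test_that("top/bottom-hat: constants vanish, impulses pass, duality holds", {
  const <- array(0.7, c(16, 16, 3))
  h <- top_bottom_hat(const, 3)
  expect_equal(max(abs(h$top)), 0)
  expect_equal(max(abs(h$bot)), 0)

  z <- array(0, c(7, 7, 3)); z[4, 4, ] <- 1
  h <- top_bottom_hat(z, 2)
  expect_equal(h$top[4, 4, 1], 1)
  expect_equal(sum(h$top), 3)  # one impulse per channel

  set.seed(4)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  h1 <- top_bottom_hat(1 - x, 2)
  h2 <- top_bottom_hat(x, 2)
  expect_equal(h1$top, h2$bot, tolerance = 1e-12)
  expect_true(min(h2$top) >= 0 && min(h2$bot) >= 0)

  expect_error(top_bottom_hat(x, 0), "degenerate")
  expect_error(top_bottom_hat(x, 10), "degenerate")
})

test_that("hat fusion matches the elementwise oracle in both modes", {
  const <- array(0.3, c(4, 4, 3))
  zero <- array(0, c(4, 4, 3))
  expect_equal(fuse_hat(zero, zero, const), zero)  # -c clamps to 0

  half <- array(0.5, c(2, 2, 3))
  expect_equal(fuse_hat(half, half, array(0.3, c(2, 2, 3))),
               array(0.7, c(2, 2, 3)))

  set.seed(5)
  top <- array(runif(4 * 4 * 3), c(4, 4, 3))
  bot <- array(runif(4 * 4 * 3), c(4, 4, 3))
  src <- array(runif(4 * 4 * 3), c(4, 4, 3))
  o_rep <- array(pmin(pmax(as.vector(top) + as.vector(bot) -
                             as.vector(src), 0), 1), dim(top))
  o_add <- array(pmin(pmax(as.vector(src) + as.vector(top) -
                             as.vector(bot), 0), 1), dim(top))
  expect_equal(fuse_hat(top, bot, src), o_rep, tolerance = 1e-14)
  expect_equal(fuse_hat(top, bot, src, mode = "additive"), o_add,
               tolerance = 1e-14)
  expect_error(fuse_hat(top, bot, array(0, c(2, 2, 3))), "mismatch")
})

test_that("dark-channel dehazing recovers a veiled scene and is stable", {
  scene <- dcp_scene(48, seed = 6)
  veiled <- clamp01(0.5 * scene + 0.5)
  out <- dehaze(veiled, enhancement_config())
  expect_lt(sqrt(mean((out - scene)^2)), sqrt(mean((veiled - scene)^2)))

  # haze-free limit: dark channel already ~0 everywhere
  out2 <- dehaze(scene, enhancement_config())
  expect_lt(max(abs(out2 - scene)), 0.05)

  white <- array(1, c(24, 24, 3))
  outw <- dehaze(white, enhancement_config())
  expect_all_finite(outw)
  expect_true(min(outw) >= 0 && max(outw) <= 1)
})

test_that("final fusion follows the multiplicative composition", {
  set.seed(7)
  hz <- array(runif(4 * 4 * 3), c(4, 4, 3))
  fused <- array(runif(4 * 4 * 3), c(4, 4, 3))
  zero <- array(0, c(4, 4, 3))
  expect_equal(fuse_final(hz, fused, zero), clamp01(hz))

  ones <- array(1, c(3, 3, 3))
  expect_equal(fuse_final(ones, ones, ones), ones)  # pre-clamp 2 -> 1

  top <- array(runif(4 * 4 * 3), c(4, 4, 3))
  oracle <- array(0, dim(hz))
  for (i in seq_along(hz))
    oracle[i] <- min(max(hz[i] * (fused[i] * top[i]) + hz[i], 0), 1)
  expect_equal(fuse_final(hz, fused, top), oracle, tolerance = 1e-14)
  expect_error(fuse_final(hz, fused, array(0, c(2, 2, 3))), "mismatch")
})

test_that("the full enhancement chain is pure, bounded and zero-preserving", {
  fr <- make_frames(frame_recipe(n_frames = 1, size = 48, seed = 9))
  img <- fr$images[[1]]
  cfg <- enhancement_config()
  e1 <- enhance(img, cfg)
  e2 <- enhance(img, cfg)
  expect_identical(e1, e2)
  expect_identical(dim(e1), dim(img))
  expect_true(min(e1) >= 0 && max(e1) <= 1)
  expect_all_finite(e1)

  black <- array(0, c(48, 48, 3))
  expect_equal(enhance(black, cfg), black)
})

test_that("enhancement does not degrade lesion/background contrast overall", {
  mich <- function(img, mask) {
    a <- mean(channel_mean(img)[mask == 1])
    b <- mean(channel_mean(img)[mask == 0])
    abs(a - b) / (a + b + 1e-9)
  }
  ratios <- vapply(1:10, function(s) {
    fr <- make_frames(frame_recipe(n_frames = 1, size = 64, seed = s))
    mich(enhance(fr$images[[1]]), fr$masks[[1]]) /
      max(mich(fr$images[[1]], fr$masks[[1]]), 1e-9)
  }, numeric(1))
  expect_gte(mean(ratios), 1)       # contrast improves on average
  expect_gte(sum(ratios >= 1), 6)   # and for the majority of frames
})
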