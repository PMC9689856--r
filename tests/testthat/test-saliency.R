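test_that("the saliency architecture has the fixed 14-layer inventory", {
  spec <- saliency_cnn_spec(c(256, 256, 3), 8)
  expect_length(spec$layers, 14)
  inv <- layer_inventory(spec)
  expect_equal(unname(inv[c("conv", "maxpool", "bn", "relu", "avgpool",
                            "fc", "softmax")]),
               c(3L, 2L, 3L, 3L, 1L, 1L, 1L))
  expect_equal(sum(inv), 14)
  expect_error(saliency_cnn_spec(c(256, 256, 3), 1), "at least 2")
  expect_error(saliency_cnn_spec(c(100, 100, 3), 2), "divisible")
})

test_that("training separates a trivial blob set and is reproducible", {
  bl <- make_blob_set(20, 64, seed = 1)
  cfg <- saliency_train_config(epochs = 5, seed = 3)
  m1 <- train_saliency_cnn(bl$images, bl$labels, cfg)
  expect_gt(m1$train_accuracy, 0.9)
  expect_length(m1$loss, 5)

  m2 <- train_saliency_cnn(bl$images, bl$labels, cfg)
  expect_identical(m1$net, m2$net)

  expect_error(train_saliency_cnn(bl$images, rep(1L, 20), cfg),
               "at least 2 classes")
  expect_error(train_saliency_cnn(bl$images, bl$labels[-1], cfg),
               "counts differ")
})

test_that("saliency maps are normalized, structure-sensitive and mergeable", {
  bl <- make_blob_set(12, 64, seed = 2)
  model <- train_saliency_cnn(bl$images, bl$labels,
                              saliency_train_config(epochs = 3, seed = 4))
  const <- array(0.5, c(64, 64, 3))
  expect_equal(compute_saliency_map(model, const), matrix(0, 64, 64))

  img <- bl$images[[1]]
  m <- compute_saliency_map(model, img)
  expect_identical(dim(m), c(64L, 64L))
  expect_true(min(m) >= 0 && max(m) <= 1)

  expect_warning(compute_saliency_map(model, img, top_k = 999), "clipped")

  # with top_k = all filters the merge is the plain mean of all normalized
  # polarity-invariant response maps (independent recomputation)
  nf <- dim(model$net$layers[[5]]$W)[4]
  full <- compute_saliency_map(model, img, top_k = nf)
  fw <- wcepipe:::net_forward(model$net, array(img, c(dim(img), 1)),
                              train = FALSE, upto = 7L, collect = TRUE)
  A <- fw$acts[[7]]
  A <- A[2:(dim(A)[1] - 1), 2:(dim(A)[2] - 1), , , drop = FALSE]
  acc <- 0
  for (i in seq_len(nf)) {
    a <- A[, , i, 1]
    acc <- acc + minmax01(abs(a - mean(a)))
  }
  oracle <- minmax01(resize_gray(acc / nf, 64, 64))
  expect_equal(full, oracle, tolerance = 1e-12)

  # weights mosaic mode is input-sized and normalized
  wm <- compute_saliency_map(model, img, source = "weights")
  expect_identical(dim(wm), c(64L, 64L))
})

test_that("trained saliency is higher inside lesions than outside", {
  fr <- make_frames(frame_recipe(n_frames = 30, size = 64, seed = 21))
  enh <- lapply(fr$images, enhance)
  model <- train_saliency_cnn(enh[1:20], fr$labels[1:20],
                              saliency_train_config(epochs = 8, seed = 5))
  hits <- 0
  for (j in 21:30) {
    m <- refine_map(compute_saliency_map(model, enh[[j]]), enh[[j]])
    gt <- fr$masks[[j]]
    hits <- hits + (mean(m[gt == 1]) > mean(m[gt == 0]))
  }
  expect_gte(hits, 8)
})

test_that("map refinement adds the enhanced channel mean and renormalizes", {
  set.seed(6)
  omap <- matrix(runif(16), 4, 4)
  zero <- array(0, c(4, 4, 3))
  expect_equal(refine_map(omap, zero), minmax01(omap))

  enh <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(refine_map(matrix(0, 4, 4), enh), minmax01(channel_mean(enh)))

  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    oracle[i, j] <- omap[i, j] + mean(enh[i, j, ])
  expect_equal(refine_map(omap, enh), minmax01(oracle), tolerance = 1e-12)

  expect_error(refine_map(omap, array(0, c(5, 5, 3))), "differ")
})

test_that("mean-thresholding is exact and ties go to foreground", {
  m <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)  # mean 0.5
  expect_equal(binarize(m), matrix(c(0, 1, 0, 1), 2, 2))

  const <- matrix(0.3, 5, 5)
  expect_equal(binarize(const), matrix(1, 5, 5))  # x >= mean everywhere

  set.seed(7)
  r <- matrix(runif(256), 16, 16)
  b <- binarize(r)
  expect_true(all(b %in% c(0, 1)))
  expect_equal(b, (r >= mean(r)) + 0)
  expect_equal(mean(b), mean(r >= mean(r)))
})

test_that("morphological refinement closes, fills, and only adds pixels", {
  disk <- matrix(0, 21, 21)
  disk[(row(disk) - 11)^2 + (col(disk) - 11)^2 <= 64] <- 1
  holed <- disk
  holed[10:12, 10:12] <- 0
  expect_equal(morph_refine(holed, 2), disk)

  gap <- matrix(0, 15, 15)
  gap[5:11, 3:6] <- 1; gap[5:11, 8:11] <- 1  # 1-px gap at column 7
  merged <- morph_refine(gap, 2)
  expect_true(all(merged[5:11, 7] == 1))

  empty <- matrix(0, 8, 8)
  expect_equal(morph_refine(empty, 2), empty)

  set.seed(8)
  rnd <- (matrix(runif(400), 20, 20) > 0.7) + 0
  out <- morph_refine(rnd, 2)
  expect_true(all(out[rnd == 1] == 1))  # never removes foreground
  expect_error(morph_refine(matrix(0.5, 3, 3), 2), "binary")
})

test_that("localization boxes track components and sort by area", {
  img0 <- array(0.5, c(32, 32, 3))
  expect_identical(localize(matrix(0, 32, 32), img0), list())

  mask <- matrix(0, 96, 96); mask[21:60, 31:70] <- 1
  img <- array(0.3, c(96, 96, 3))
  for (ch in 1:3) img[21:60, 31:70, ch] <- 0.8
  rg <- localize(mask, img, min_area = 64)
  expect_length(rg, 1)
  b <- rg[[1]]$box
  expect_true(b[1] <= 20 && b[2] <= 30 && b[3] >= 60 && b[4] >= 70)
  expect_lt(abs(rg[[1]]$area - 1600) / 1600, 0.2)
  expect_identical(dim(rg[[1]]$crop)[3], 3L)

  mask2 <- matrix(0, 96, 96)
  mask2[11:30, 11:30] <- 1; mask2[51:90, 51:90] <- 1
  img2 <- array(0.3, c(96, 96, 3))
  img2[11:30, 11:30, ] <- 0.8; img2[51:90, 51:90, ] <- 0.8
  rg2 <- localize(mask2, img2, min_area = 64)
  expect_length(rg2, 2)
  expect_gte(rg2[[1]]$area, rg2[[2]]$area)
})

test_that("mask IoU behaves at the boundaries", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  expect_equal(mask_iou(a, b), 1)
  a[1:2, 1:2] <- 1
  expect_equal(mask_iou(a, a), 1)
  b[1:2, 1] <- 1
  expect_equal(mask_iou(a, b), 0.5)
})
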