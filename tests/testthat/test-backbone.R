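test_that("backbone specs pin the embedding width per architecture", {
  s <- backbone_spec("mobilenet_v2", n_classes = 8)
  expect_equal(s$embed_dim, 1280L)
  expect_error(backbone_spec("mobilenet_v2", embed_dim = 512), "1280")

  t <- backbone_spec("tiny_cnn", n_classes = 3, embed_dim = 48)
  expect_equal(t$embed_dim, 48L)
  expect_error(backbone_spec("resnet99"), "unknown architecture")

  m <- build_backbone(t, seed = 1)
  expect_equal(m$net$layers[[13]]$cout, 3L)  # head sized to class count
})

test_that("feature extraction has the spec width and is order-faithful", {
  fr <- make_frames(frame_recipe(n_frames = 6, size = 64, seed = 11))
  m <- build_backbone(backbone_spec("tiny_cnn", 2, embed_dim = 32), seed = 2)
  f <- extract_features(m, fr$images)
  expect_identical(dim(f), c(6L, 32L))
  expect_all_finite(f)

  f0 <- extract_features(m, list())
  expect_identical(dim(f0), c(0L, 32L))

  fdup <- extract_features(m, fr$images[c(1, 1)])
  expect_equal(fdup[1, ], fdup[2, ])

  perm <- c(3, 1, 2, 6, 4, 5)
  fp <- extract_features(m, fr$images[perm])
  expect_equal(fp, f[perm, ], tolerance = 1e-12)
})

test_that("the MobileNetV2 topology emits 1280-wide embeddings", {
  fr <- make_frames(frame_recipe(n_frames = 2, size = 64, seed = 12))
  mb <- build_backbone(backbone_spec("mobilenet_v2", 2, input_size = 96),
                       seed = 3)
  f <- extract_features(mb, fr$images)
  expect_identical(dim(f), c(2L, 1280L))
  expect_all_finite(f)
  f2 <- extract_features(mb, fr$images)
  expect_equal(f, f2)
})

test_that("fine-tuning fits separable crops and is seed-reproducible", {
  fr <- make_frames(frame_recipe(n_frames = 20, size = 64, seed = 13))
  spec <- backbone_spec("tiny_cnn", 2)
  hp <- hyper_params(lr = 0.05, momentum = 0.7, l2 = 1e-6)
  m <- build_backbone(spec, seed = 4)
  m1 <- finetune(m, fr$images, fr$labels, hp, epochs = 8, seed = 5)
  expect_gt(mean(backbone_predict(m1, fr$images) == fr$labels), 0.9)
  expect_all_finite(unlist(m1$loss))

  m2 <- finetune(m, fr$images, fr$labels, hp, epochs = 8, seed = 5)
  expect_identical(m1$net, m2$net)

  # at the smallest admissible learning rate the loss trend is downhill
  mlo <- finetune(m, fr$images, fr$labels,
                  hyper_params(lr = 1e-4, momentum = 0.7, l2 = 1e-8),
                  epochs = 10, seed = 6)
  sm <- stats::filter(mlo$loss, rep(1 / 3, 3), sides = 1)
  expect_lt(sm[length(sm)], sm[3])

  expect_error(finetune(m, list(), integer(0), hp), "empty")
  expect_error(hyper_params(lr = 2), "lr")
  expect_error(hyper_params(momentum = 0.5), "momentum")
  expect_error(hyper_params(l2 = 1), "l2")
})

test_that("Bayesian tuning returns an in-box, reproducible incumbent", {
  fr <- make_frames(frame_recipe(n_frames = 24, size = 64, seed = 31))
  sp <- stratified_split(fr$labels, 0.5, seed = 2)
  tr <- tune_hyperparams(fr$images[sp$train], fr$labels[sp$train],
                         fr$images[sp$test], fr$labels[sp$test],
                         spec = backbone_spec("tiny_cnn", 2),
                         n_init = 5, n_iter = 5, proxy_epochs = 3, seed = 7)
  expect_true(tr$hp$lr >= 1e-4 && tr$hp$lr <= 1)
  expect_true(tr$hp$momentum >= 0.6 && tr$hp$momentum <= 0.8)
  expect_true(tr$hp$l2 >= 1e-10 && tr$hp$l2 <= 1e-2)
  expect_lte(tr$best_error, median(tr$history$value[1:5]))

  tr2 <- tune_hyperparams(fr$images[sp$train], fr$labels[sp$train],
                          fr$images[sp$test], fr$labels[sp$test],
                          spec = backbone_spec("tiny_cnn", 2),
                          n_init = 5, n_iter = 5, proxy_epochs = 3, seed = 7)
  expect_identical(tr$hp, tr2$hp)
})
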