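#' Backbone specification
#'
#' Two architectures are available: `"mobilenet_v2"`, the full MobileNetV2
#' topology (inverted residual bottlenecks, ReLU6, 1280-wide average-pool
#' embedding) run forward-only with a trainable classification head, and
#' `"tiny_cnn"`, a small fully trainable CNN used at fixture scale. The
#' original classifier is replaced by dropout + a linear layer sized to the
#' dataset's class count.
#'
#' @param architecture `"tiny_cnn"` or `"mobilenet_v2"`.
#' @param n_classes output classes (head width).
#' @param embed_dim embedding width; fixed at 1280 for `mobilenet_v2`,
#'   configurable (default 64) for `tiny_cnn`.
#' @param input_size square input side; 224 for `mobilenet_v2`, 64 for
#'   `tiny_cnn` by default.
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(architecture = c("tiny_cnn", "mobilenet_v2"),
                          n_classes = 2, embed_dim = NULL,
                          input_size = NULL) {
  architecture <- tryCatch(match.arg(architecture),
                           error = function(e)
                             stop("unknown architecture", call. = FALSE))
  stopifnot(n_classes >= 2)
  if (architecture == "mobilenet_v2") {
    if (!is.null(embed_dim) && embed_dim != 1280)
      stop("mobilenet_v2 embedding width is fixed at 1280", call. = FALSE)
    embed_dim <- 1280L
    input_size <- input_size %||% 224L
  } else {
    embed_dim <- as.integer(embed_dim %||% 64L)
    input_size <- input_size %||% 64L
  }
  if (input_size %% 32 != 0)
    stop("input_size must be divisible by 32", call. = FALSE)
  structure(list(architecture = architecture,
                 n_classes = as.integer(n_classes),
                 embed_dim = embed_dim, input_size = as.integer(input_size)),
            class = "backbone_spec")
}

# MobileNetV2 inverted-residual stack: (expansion, channels, repeats, stride)
mobilenet_v2_cfg <- list(
  c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
  c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))

# build segments: each segment is a net over (H,W,C,N) tensors plus a
# residual flag (skip connection around the whole segment)
mobilenet_segments <- function(seed) {
  segs <- list()
  add <- function(layers, residual = FALSE) {
    segs[[length(segs) + 1]] <<- list(
      net = net_init(layers, seed = seed + length(segs)), residual = residual)
  }
  add(list(nn_conv(3, 3, 32, stride = 2, pad = 1), nn_bn(32), nn_relu6()))
  cin <- 32
  for (blk in mobilenet_v2_cfg) {
    t <- blk[1]; c <- blk[2]; n <- blk[3]; s <- blk[4]
    for (i in seq_len(n)) {
      stride <- if (i == 1) s else 1
      hid <- cin * t
      layers <- list()
      if (t != 1)
        layers <- c(layers, list(nn_conv(1, cin, hid, 1, 0), nn_bn(hid),
                                 nn_relu6()))
      layers <- c(layers, list(nn_dwconv(3, hid, stride, 1), nn_bn(hid),
                               nn_relu6(),
                               nn_conv(1, hid, c, 1, 0), nn_bn(c)))
      add(layers, residual = (stride == 1 && cin == c))
      cin <- c
    }
  }
  add(list(nn_conv(1, cin, 1280, 1, 0), nn_bn(1280), nn_relu6()))
  segs
}

mobilenet_forward <- function(segments, X) {
  for (seg in segments) {
    Y <- net_forward(seg$net, X, train = FALSE)$out
    X <- if (seg$residual) X + Y else Y
  }
  d <- dim(X)
  matrix(colMeans(matrix(X, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

tiny_cnn_layers <- function(embed_dim, n_classes) {
  list(nn_conv(3, 3, 16, stride = 2, pad = 1), nn_bn(16), nn_relu(),
       nn_maxpool(),
       nn_conv(3, 16, 32, stride = 2, pad = 1), nn_bn(32), nn_relu(),
       nn_maxpool(),
       nn_conv(3, 32, embed_dim, stride = 2, pad = 1), nn_bn(embed_dim),
       nn_relu(),
       nn_avgpool(), nn_fc(embed_dim, n_classes), nn_softmax())
}

#' Build a backbone model
#'
#' @param spec a [backbone_spec()].
#' @param seed RNG seed for weight initialization (weights are random;
#'   no pretrained download is required).
#' @return an object of class `backbone_model` whose global-average-pool
#'   output has the spec's embedding width and whose head matches the class
#'   count.
#' @export
build_backbone <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$architecture == "mobilenet_v2") {
    segs <- mobilenet_segments(seed)
    head <- net_init(list(nn_fc(1280, spec$n_classes), nn_softmax()),
                     seed = seed + 1000)
    structure(list(spec = spec, segments = segs, head = head,
                   loss = numeric(0)),
              class = "backbone_model")
  } else {
    net <- net_init(tiny_cnn_layers(spec$embed_dim, spec$n_classes),
                    seed = seed)
    structure(list(spec = spec, net = net, loss = numeric(0)),
              class = "backbone_model")
  }
}

#' Fine-tuning hyperparameters
#'
#' The searched box: learning rate in `[1e-4, 1]`, momentum in
#' `[0.6, 0.8]`, L2 regularization in `[1e-10, 1e-2]`.
#'
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param l2 L2 regularization (weight decay).
#' @return an object of class `hyper_params`.
#' @export
hyper_params <- function(lr = 0.01, momentum = 0.7, l2 = 1e-6) {
  if (lr < 1e-4 || lr > 1) stop("lr outside [1e-4, 1]", call. = FALSE)
  if (momentum < 0.6 || momentum > 0.8)
    stop("momentum outside [0.6, 0.8]", call. = FALSE)
  if (l2 < 1e-10 || l2 > 1e-2) stop("l2 outside [1e-10, 1e-2]", call. = FALSE)
  structure(list(lr = lr, momentum = momentum, l2 = l2),
            class = "hyper_params")
}

#' The default hyperparameter search box
#' @return a [search_box()] over learning rate (log scale), momentum, and
#'   L2 regularization (log scale).
#' @export
hyper_box <- function() {
  search_box(lower = c(1e-4, 0.6, 1e-10), upper = c(1, 0.8, 1e-2),
             log = c(TRUE, FALSE, TRUE), names = c("lr", "momentum", "l2"))
}

# resize a list of crops to the spec input size and stack
crops_to_tensor <- function(crops, size) {
  imgs <- lapply(crops, function(cr) {
    if (!identical(dim(cr)[1:2], c(size, size))) resize_rgb(cr, size, size)
    else cr
  })
  images_to_tensor(imgs)
}

#' Fine-tune a backbone on localized region crops
#'
#' Crops are resized to the spec's input size. For `tiny_cnn` the whole
#' network is trained with SGD (momentum and L2 from `hp`); for
#' `mobilenet_v2` the convolutional base is frozen and the replaced head is
#' trained on the 1280-dim average-pool features (linear probing).
#'
#' @param model a [build_backbone()] model.
#' @param crops list of RGB arrays (region crops or whole frames).
#' @param labels integer labels `1..n_classes` aligned with `crops`.
#' @param hp a [hyper_params()].
#' @param epochs training epochs (default 20).
#' @param seed RNG seed; identical seeds give identical weights.
#' @return the trained `backbone_model` with a recorded loss history.
#' @export
finetune <- function(model, crops, labels, hp = hyper_params(), epochs = 20,
                     seed = 1) {
  stopifnot(inherits(model, "backbone_model"), inherits(hp, "hyper_params"))
  if (length(crops) == 0) stop("empty crop list", call. = FALSE)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("need at least 2 classes", call. = FALSE)
  if (length(crops) != length(labels))
    stop("crop and label counts differ", call. = FALSE)
  size <- model$spec$input_size
  if (model$spec$architecture == "mobilenet_v2") {
    feats <- t(extract_features(model, crops))  # D x N
    tr <- net_train(model$head, feats, labels, epochs = epochs, lr = hp$lr,
                    momentum = hp$momentum, l2 = hp$l2,
                    batch = 32, seed = seed)
    model$head <- tr$net
  } else {
    X <- crops_to_tensor(crops, size)
    tr <- net_train(model$net, X, labels, epochs = epochs, lr = hp$lr,
                    momentum = hp$momentum, l2 = hp$l2, batch = 32,
                    seed = seed)
    model$net <- tr$net
  }
  model$loss <- tr$loss
  model
}

#' Extract average-pool embedding features
#'
#' @param model a `backbone_model` (trained or freshly initialized).
#' @param crops list of RGB arrays; resized to the model input size.
#' @return `N x D` matrix (`D` = embedding width, 1280 for mobilenet_v2)
#'   with rows in input order and columns named `f1..fD`. An empty input
#'   yields a `0 x D` matrix.
#' @export
extract_features <- function(model, crops) {
  stopifnot(inherits(model, "backbone_model"))
  D <- model$spec$embed_dim
  if (length(crops) == 0)
    return(matrix(numeric(0), 0, D,
                  dimnames = list(NULL, paste0("f", seq_len(D)))))
  size <- model$spec$input_size
  out <- matrix(0, length(crops), D)
  bs <- if (model$spec$architecture == "mobilenet_v2") 4L else 32L
  for (b0 in seq(1L, length(crops), by = bs)) {
    ids <- b0:min(b0 + bs - 1L, length(crops))
    X <- crops_to_tensor(crops[ids], size)
    F <- if (model$spec$architecture == "mobilenet_v2")
      mobilenet_forward(model$segments, X)
    else
      net_forward(model$net, X, train = FALSE, upto = 12L)$out  # avgpool
    out[ids, ] <- t(F)
  }
  colnames(out) <- paste0("f", seq_len(D))
  out
}

#' Predict classes with a backbone's head
#' @param model a trained `backbone_model`.
#' @param crops list of RGB arrays.
#' @return integer class labels.
#' @export
backbone_predict <- function(model, crops) {
  if (model$spec$architecture == "mobilenet_v2") {
    feats <- t(extract_features(model, crops))
    P <- net_forward(model$head, feats, train = FALSE)$out
    max.col(t(P), ties.method = "first")
  } else {
    X <- crops_to_tensor(crops, model$spec$input_size)
    net_predict_class(model$net, X)
  }
}

#' Tune fine-tuning hyperparameters with Bayesian optimization
#'
#' The objective is the validation error rate after a short proxy fine-tune
#' (`proxy_epochs`); the returned incumbent is the best point found.
#'
#' @param train_crops,train_labels training split.
#' @param val_crops,val_labels validation split.
#' @param spec a [backbone_spec()].
#' @param box a [search_box()]; defaults to [hyper_box()].
#' @param n_init,n_iter BO budget.
#' @param proxy_epochs epochs of the inner proxy fine-tune.
#' @param seed RNG seed.
#' @return list with `hp` (a [hyper_params()]), `best_error`, and the BO
#'   `history`.
#' @export
tune_hyperparams <- function(train_crops, train_labels, val_crops,
                             val_labels, spec = backbone_spec(),
                             box = hyper_box(), n_init = 5, n_iter = 5,
                             proxy_epochs = 3, seed = 1) {
  stopifnot(length(train_crops) > 0, length(val_crops) > 0)
  objective <- function(x) {
    hp <- hyper_params(lr = x[["lr"]], momentum = x[["momentum"]],
                       l2 = x[["l2"]])
    model <- build_backbone(spec, seed = seed)
    model <- finetune(model, train_crops, train_labels, hp,
                      epochs = proxy_epochs, seed = seed)
    mean(backbone_predict(model, val_crops) != val_labels)
  }
  r <- bo_optimize(objective, box, n_init = n_init, n_iter = n_iter,
                   seed = seed)
  list(hp = hyper_params(lr = r$best_x[["lr"]],
                         momentum = r$best_x[["momentum"]],
                         l2 = r$best_x[["l2"]]),
       best_error = r$best_value, history = r$history)
}
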