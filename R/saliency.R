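#' Specification of the 14-layer saliency CNN
#'
#' The fixed architecture used to derive lesion saliency maps: three 3x3
#' stride-2 convolution blocks (each conv + batch-norm + ReLU), 2x2 stride-2
#' max-pools after the first two blocks, a global average pool, one fully
#' connected layer and a softmax — exactly 14 layers.
#'
#' @param input_shape integer vector `c(H, W, C)`; `H` and `W` must survive
#'   the stride chain (divisible by 32).
#' @param n_classes number of output classes (at least 2).
#' @param filters filter counts of the three convolutions.
#' @return an object of class `saliency_cnn_spec` with elements `layers`
#'   (ordered layer type names), `input_shape`, `n_classes`, `filters`.
#' @export
saliency_cnn_spec <- function(input_shape = c(256, 256, 3), n_classes = 2,
                              filters = c(16, 32, 64)) {
  if (n_classes < 2) stop("`n_classes` must be at least 2", call. = FALSE)
  stopifnot(length(input_shape) == 3, length(filters) == 3)
  if (any(input_shape[1:2] %% 32 != 0))
    stop("input H and W must be divisible by 32 to survive the stride chain",
         call. = FALSE)
  layers <- c("conv", "bn", "relu", "maxpool",
              "conv", "bn", "relu", "maxpool",
              "conv", "bn", "relu",
              "avgpool", "fc", "softmax")
  structure(list(layers = layers, input_shape = input_shape,
                 n_classes = as.integer(n_classes), filters = filters),
            class = "saliency_cnn_spec")
}

#' Layer-type inventory of a saliency CNN spec
#' @param spec a [saliency_cnn_spec()].
#' @return named integer vector of counts per layer type.
#' @export
layer_inventory <- function(spec) {
  stopifnot(inherits(spec, "saliency_cnn_spec"))
  tab <- table(factor(spec$layers,
                      levels = c("conv", "maxpool", "bn", "relu", "avgpool",
                                 "fc", "softmax")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# instantiate the network object for a spec
saliency_net_layers <- function(spec) {
  f <- spec$filters
  cin <- spec$input_shape[3]
  list(nn_conv(3, cin, f[1], stride = 2, pad = 1), nn_bn(f[1]), nn_relu(),
       nn_maxpool(),
       nn_conv(3, f[1], f[2], stride = 2, pad = 1), nn_bn(f[2]), nn_relu(),
       nn_maxpool(),
       nn_conv(3, f[2], f[3], stride = 2, pad = 1), nn_bn(f[3]), nn_relu(),
       nn_avgpool(), nn_fc(f[3], spec$n_classes), nn_softmax())
}

#' Training configuration for the saliency CNN
#'
#' Defaults are the printed training settings of the architecture: SGD with
#' learning rate 0.05, 100 epochs, mini-batch 32, momentum 0.6 and dropout
#' 0.5 before the fully connected layer. All are overridable (tests use far
#' fewer epochs).
#'
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch mini-batch size.
#' @param momentum SGD momentum.
#' @param dropout dropout rate on the FC input during training.
#' @param seed RNG seed for init, shuffling and dropout.
#' @return an object of class `saliency_train_config`.
#' @export
saliency_train_config <- function(lr = 0.05, epochs = 100, batch = 32,
                                  momentum = 0.6, dropout = 0.5, seed = 1) {
  stopifnot(lr > 0, epochs >= 1, batch >= 1,
            momentum >= 0, momentum < 1, dropout >= 0, dropout < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch), momentum = momentum,
                 dropout = dropout, seed = seed),
            class = "saliency_train_config")
}

#' Build and train the saliency CNN
#'
#' @param images list of `H x W x 3` arrays (all the same shape).
#' @param labels integer class labels `1..K` aligned with `images`.
#' @param cfg a [saliency_train_config()].
#' @param spec optional [saliency_cnn_spec()]; by default derived from the
#'   image shape and label set.
#' @return an object of class `saliency_model`: the trained network, its
#'   spec, the per-epoch training-loss history and the final training
#'   accuracy.
#' @export
train_saliency_cnn <- function(images, labels, cfg = saliency_train_config(),
                               spec = NULL) {
  if (length(images) != length(labels))
    stop("image and label counts differ", call. = FALSE)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("need at least 2 classes to train", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("need at least 2 samples per class", call. = FALSE)
  d <- dim(images[[1]])
  if (is.null(spec)) spec <- saliency_cnn_spec(d, max(labels))
  net <- net_init(saliency_net_layers(spec), seed = cfg$seed)
  X <- images_to_tensor(images)
  tr <- net_train(net, X, labels, epochs = cfg$epochs, lr = cfg$lr,
                  momentum = cfg$momentum, batch = cfg$batch,
                  dropout = cfg$dropout, seed = cfg$seed)
  acc <- mean(net_predict_class(tr$net, X) == labels)
  structure(list(net = tr$net, spec = spec, loss = tr$loss,
                 train_accuracy = acc),
            class = "saliency_model")
}

# index of the second convolution's ReLU output in the 14-layer net
second_conv_relu_index <- function() 7L

#' Deep saliency map of an image
#'
#' Runs the image through the trained saliency CNN and reads the response
#' maps of the second convolution block. Each per-filter activation is made
#' polarity-invariant by taking its absolute deviation from its spatial mean
#' (a lesion can be a low-activation hole in one filter and a bright blob in
#' another; distinctness is what matters) and min-max normalized. Maps are
#' ranked by spatial variance ("clear pattern" proxy), the `top_k` maps are
#' averaged, upsampled to the image size and min-max normalized to `[0, 1]`.
#' With `source = "weights"` a literal kernel-weight mosaic is returned
#' instead (inspection only — it is input-independent).
#'
#' @param model a `saliency_model` from [train_saliency_cnn()].
#' @param image `H x W x 3` array matching the model's input shape.
#' @param top_k number of response maps to merge; values above the filter
#'   count are clipped with a warning. Default: half the filters.
#' @param source `"activations"` (default) or `"weights"`.
#' @return `H x W` saliency matrix in `[0, 1]`.
#' @export
compute_saliency_map <- function(model, image, top_k = NULL,
                                 source = c("activations", "weights")) {
  stopifnot(inherits(model, "saliency_model"))
  source <- match.arg(source)
  check_rgb_image(image)
  d <- dim(image)
  if (source == "weights") {
    W <- model$net$layers[[5]]$W  # (3,3,cin,cout) kernels of conv 2
    k <- dim(W)[4]
    side <- ceiling(sqrt(k))
    mos <- matrix(0, side * 3, side * 3)
    for (i in seq_len(k)) {
      r <- (i - 1) %/% side; c <- (i - 1) %% side
      mos[r * 3 + 1:3, c * 3 + 1:3] <- minmax01(apply(W[, , , i], c(1, 2), mean))
    }
    return(minmax01(resize_gray(mos, d[1], d[2])))
  }
  X <- array(image, c(d, 1L))
  fw <- net_forward(model$net, X, train = FALSE,
                    upto = second_conv_relu_index(), collect = TRUE)
  A <- fw$acts[[second_conv_relu_index()]]  # (h, w, F, 1)
  # drop the outermost activation ring: those receptive fields touch the
  # zero padding and light up on dark frames regardless of content
  if (dim(A)[1] > 4 && dim(A)[2] > 4)
    A <- A[2:(dim(A)[1] - 1), 2:(dim(A)[2] - 1), , , drop = FALSE]
  nf <- dim(A)[3]
  if (is.null(top_k)) top_k <- max(1L, nf %/% 2L)
  if (top_k > nf) {
    warning("top_k exceeds filter count; clipped to ", nf)
    top_k <- nf
  }
  maps <- lapply(seq_len(nf), function(i) {
    a <- A[, , i, 1]
    minmax01(abs(a - mean(a)))
  })
  vars <- vapply(maps, function(m) var(as.vector(m)), numeric(1))
  keep <- order(vars, decreasing = TRUE)[seq_len(top_k)]
  avg <- Reduce(`+`, maps[keep]) / top_k
  minmax01(resize_gray(avg, d[1], d[2]))
}

#' Refine a saliency map with the enhanced image
#'
#' Adds the channel-mean of the enhanced image to the raw saliency map and
#' renormalizes to `[0, 1]`.
#'
#' @param omap `H x W` saliency matrix.
#' @param enhanced `H x W x 3` enhanced image.
#' @return refined `H x W` saliency matrix in `[0, 1]`.
#' @export
refine_map <- function(omap, enhanced) {
  check_gray_map(omap)
  if (!identical(dim(omap), dim(enhanced)[1:2]))
    stop("saliency map and enhanced image shapes differ", call. = FALSE)
  minmax01(omap + channel_mean(enhanced))
}

#' Threshold a saliency map at its mean
#'
#' Pixels at or above the map's arithmetic mean become foreground (ties go
#' to foreground).
#'
#' @param map `H x W` saliency matrix.
#' @return `H x W` matrix with values in `{0, 1}`.
#' @export
binarize <- function(map) {
  check_gray_map(map)
  (map >= mean(map)) + 0
}

#' Morphologically refine a binary mask
#'
#' Closing with a disk, then hole filling. Both operations only ever add
#' foreground pixels.
#'
#' @param mask `H x W` 0/1 matrix.
#' @param radius closing disk radius in pixels.
#' @return refined 0/1 matrix.
#' @export
morph_refine <- function(mask, radius = 2) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  if (!any(mask == 1)) return(mask)
  m <- t(mask)
  m <- EBImage::closing(m, disc_brush(radius))
  m <- EBImage::fillHull(m)
  t(as.matrix(m)) + 0
}

# lightweight two-phase active contour (Chan-Vese energy, no length term
# beyond a 3x3 majority smoothing), run on a gray window
chan_vese_refine <- function(gray, init, iters = 50) {
  m <- init > 0
  for (it in seq_len(iters)) {
    if (!any(m) || all(m)) break
    c1 <- mean(gray[m]); c2 <- mean(gray[!m])
    m2 <- (gray - c1)^2 < (gray - c2)^2
    m2 <- boxsum3(m2 + 0) >= 5  # majority vote regularizer
    if (identical(m2, m)) { m <- m2; break }
    m <- m2
  }
  m + 0
}

#' Localize lesion regions from a refined binary mask
#'
#' Connected components of at least `min_area` pixels are refined with a
#' Chan-Vese-style active contour initialized from the component (falling
#' back to the raw component if the contour collapses), then converted to
#' bounding boxes and image crops. Regions are sorted by area, largest first.
#'
#' @param mask `H x W` 0/1 matrix.
#' @param image `H x W x 3` image the crops are taken from.
#' @param min_area minimum component area in pixels.
#' @param contour_iters active-contour iterations.
#' @param feature `H x W` matrix the contour evolves on; defaults to the
#'   image's channel mean. Passing the saliency map makes the contour track
#'   the salient region rather than the bright one.
#' @param close_radius closing disk radius applied (with hole filling) to
#'   each contour-refined region: open annular contours around a lesion of
#'   contrasting interior become filled blobs. 0 disables.
#' @return list of regions, each a list with `box` (0-based half-open
#'   `c(r0, c0, r1, c1)`), `area` (pixels), `mask` (component 0/1 matrix on
#'   the full frame) and `crop` (RGB array). May be empty.
#' @export
localize <- function(mask, image, min_area = 64, contour_iters = 50,
                     feature = NULL, close_radius = 3) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  check_rgb_image(image)
  H <- nrow(mask); W <- ncol(mask)
  lab <- t(as.matrix(EBImage::bwlabel(t(mask))))
  n <- max(lab)
  if (n == 0) return(list())
  gray <- feature %||% channel_mean(image)
  stopifnot(identical(dim(gray), dim(mask)))
  out <- list()
  for (i in seq_len(n)) {
    comp <- (lab == i) + 0
    area0 <- sum(comp)
    if (area0 < min_area) next
    rr <- range(which(rowSums(comp) > 0))
    cc <- range(which(colSums(comp) > 0))
    # expand the window by 25% of the box size for the contour to move in
    er <- ceiling(0.25 * (rr[2] - rr[1] + 1)); ec <- ceiling(0.25 * (cc[2] - cc[1] + 1))
    r0 <- max(1, rr[1] - er); r1 <- min(H, rr[2] + er)
    c0 <- max(1, cc[1] - ec); c1 <- min(W, cc[2] + ec)
    ref <- chan_vese_refine(gray[r0:r1, c0:c1, drop = FALSE],
                            comp[r0:r1, c0:c1, drop = FALSE], contour_iters)
    full <- matrix(0, H, W)
    full[r0:r1, c0:c1] <- ref
    if (close_radius > 0 && any(full == 1))
      full <- morph_refine(full, close_radius)
    # keep the refined blob only where it stays attached to the seed
    labr <- t(as.matrix(EBImage::bwlabel(t(full))))
    hit <- unique(labr[comp == 1 & labr > 0])
    full <- (labr %in% hit) + 0
    dim(full) <- c(H, W)
    if (sum(full) < min_area) full <- comp  # contour collapsed; fall back
    rr2 <- range(which(rowSums(full) > 0))
    cc2 <- range(which(colSums(full) > 0))
    crop <- image[rr2[1]:rr2[2], cc2[1]:cc2[2], , drop = FALSE]
    out[[length(out) + 1]] <- list(
      box = c(rr2[1] - 1L, cc2[1] - 1L, rr2[2], cc2[2]),
      area = sum(full), mask = full, crop = crop)
  }
  out[order(vapply(out, function(r) r$area, numeric(1)), decreasing = TRUE)]
}

#' Segment one frame end to end
#'
#' Saliency map (computed on the enhanced frame, the distribution the CNN is
#' trained on), refinement, mean-thresholding, morphological cleanup and
#' active-contour localization in one call. The union of the localized
#' region masks is the final segmentation.
#'
#' @param model a `saliency_model`.
#' @param image original `H x W x 3` frame (source of the crops and of the
#'   contour intensities).
#' @param enhanced enhanced version of the frame; computed on the fly when
#'   absent.
#' @param top_k response maps to merge (see [compute_saliency_map()]).
#' @param min_area minimum region area in pixels.
#' @param morph_radius closing disk radius.
#' @return list with `saliency` (refined map), `mask` (mean-threshold binary
#'   mask after morphology), `regions` (from [localize()]) and
#'   `region_mask` (union of the localized region masks — the final
#'   segmentation).
#' @export
segment_frame <- function(model, image, enhanced = NULL, top_k = NULL,
                          min_area = 64, morph_radius = 2) {
  if (is.null(enhanced)) enhanced <- enhance(image)
  omap <- compute_saliency_map(model, enhanced, top_k)
  ref <- refine_map(omap, enhanced)
  bin <- binarize(ref)
  bin <- morph_refine(bin, morph_radius)
  regions <- localize(bin, image, min_area, feature = ref)
  region_mask <- if (length(regions))
    (Reduce(`+`, lapply(regions, function(r) r$mask)) > 0) + 0
  else matrix(0, nrow(bin), ncol(bin))
  list(saliency = ref, mask = bin, regions = regions,
       region_mask = region_mask)
}

#' Intersection-over-union of two binary masks
#' @param a,b 0/1 matrices of identical shape.
#' @return IoU in `[0, 1]`; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  i <- sum(a == 1 & b == 1)
  u <- sum(a == 1 | b == 1)
  if (u == 0) return(1)
  i / u
}
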