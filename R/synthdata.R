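#' Recipe for synthetic endoscopy-like frames
#'
#' Describes a seeded generator of WCE-style RGB frames: a mucosa-pink
#' textured background, elliptical lesions with a controlled intensity shift
#' (the segmentation targets), bright specular "bubble" discs (what the
#' denoising stage is aimed at), and an additive white haze veil (what the
#' dehazer inverts). Each stressor maps onto one stage of the enhancement
#' chain so the chain can be exercised without real endoscopy data.
#'
#' @param n_frames number of frames to generate.
#' @param size frame side length in pixels (frames are square).
#' @param base_color background RGB triple, mucosa-like by default.
#' @param texture_scale spatial scale of the value-noise texture, in pixels.
#' @param texture_amp amplitude of the texture, in intensity units.
#' @param n_lesions lesions per frame (0 gives healthy frames).
#' @param lesion_size semi-axis range as a fraction of `size`.
#' @param lesion_contrast absolute per-pixel intensity shift of a lesion
#'   relative to the surrounding mucosa (channel-mean units).
#' @param n_bubbles specular highlight discs per frame.
#' @param bubble_radius disc radius range as a fraction of `size`.
#' @param bubble_brightness blend weight toward white inside a bubble.
#' @param haze_weight additive veil weight `w`: frame = (1-w)*scene + w.
#' @param vignette strength of the radial illumination falloff typical of
#'   endoscopic optics (0 disables; 1 makes the corners fully dark).
#' @param n_classes number of lesion classes (lesion appearance types).
#' @param seed RNG seed; the recipe is a pure function of its fields.
#' @return an object of class `frame_recipe`.
#' @seealso [make_frames()]
#' @export
frame_recipe <- function(n_frames = 10, size = 64,
                         base_color = c(0.72, 0.45, 0.40),
                         texture_scale = 8, texture_amp = 0.05,
                         n_lesions = 1, lesion_size = c(0.14, 0.24),
                         lesion_contrast = 0.3,
                         n_bubbles = 3, bubble_radius = c(0.02, 0.05),
                         bubble_brightness = 0.8,
                         haze_weight = 0.2, vignette = 0.6,
                         n_classes = 2, seed = 1) {
  stopifnot(n_frames >= 1, size >= 16, n_lesions >= 0, n_bubbles >= 0,
            n_classes >= 1, haze_weight >= 0, haze_weight < 1,
            vignette >= 0, vignette <= 1,
            lesion_contrast >= 0, lesion_contrast <= 0.5)
  if (max(lesion_size) >= 0.5)
    stop("lesion larger than frame: max `lesion_size` fraction must be < 0.5",
         call. = FALSE)
  structure(list(n_frames = n_frames, size = size, base_color = base_color,
                 texture_scale = texture_scale, texture_amp = texture_amp,
                 n_lesions = n_lesions, lesion_size = lesion_size,
                 lesion_contrast = lesion_contrast, n_bubbles = n_bubbles,
                 bubble_radius = bubble_radius,
                 bubble_brightness = bubble_brightness,
                 haze_weight = haze_weight, vignette = vignette,
                 n_classes = n_classes, seed = seed),
            class = "frame_recipe")
}

# smooth value-noise texture: low-res gaussian grid upsampled bilinearly
value_noise <- function(size, scale, amp) {
  g <- max(2L, ceiling(size / scale))
  low <- matrix(rnorm(g * g), g, g)
  amp * resize_gray(low, size, size)
}

# soft-edged ellipse field: 1 inside, feathering to 0 just outside.
# Returns list(hard = logical matrix, soft = numeric matrix).
ellipse_field <- function(size, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(size), size, size) - cy
  xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- (xx * cos(theta) + yy * sin(theta)) / a
  v <- (-xx * sin(theta) + yy * cos(theta)) / b
  e <- u^2 + v^2
  list(hard = e <= 1, soft = clamp01((1.1 - e) / 0.25))
}

#' Generate synthetic endoscopy-like frames with ground truth
#'
#' Frames are seeded and fully reproducible. The returned masks are the exact
#' (hard-edged) lesion ellipses used by the generator, and the labels encode
#' the lesion class (`0` when `n_lesions == 0`). A self-check asserts that the
#' realized inside/outside intensity contrast of every lesion is consistent
#' with the recipe.
#'
#' @param recipe a [frame_recipe()].
#' @return list with `images` (list of `H x W x 3` arrays), `masks` (list of
#'   0/1 matrices), `labels` (integer vector).
#' @export
make_frames <- function(recipe) {
  stopifnot(inherits(recipe, "frame_recipe"))
  r <- recipe
  with_seed(r$seed, {
    images <- vector("list", r$n_frames)
    masks <- vector("list", r$n_frames)
    labels <- integer(r$n_frames)
    for (f in seq_len(r$n_frames)) {
      cls <- if (r$n_lesions == 0) 0L else 1L + (f - 1L) %% r$n_classes
      fr <- render_frame(r, cls)
      images[[f]] <- fr$img
      masks[[f]] <- fr$mask
      labels[f] <- cls
      if (r$n_lesions > 0 && r$lesion_contrast >= 0.2 && any(fr$mask == 1)) {
        din <- mean(channel_mean(fr$raw)[fr$mask == 1])
        dout <- mean(channel_mean(fr$raw)[fr$mask == 0])
        stopifnot(abs(din - dout) >= r$lesion_contrast / 2)
      }
    }
    list(images = images, masks = masks, labels = labels)
  })
}

# render a single frame; `raw` is the pre-haze scene (used for the self-check)
render_frame <- function(r, cls) {
  s <- r$size
  img <- array(0, c(s, s, 3))
  jitter <- rnorm(3, 0, 0.02)
  tex <- value_noise(s, r$texture_scale, r$texture_amp)
  for (ch in 1:3)
    img[, , ch] <- clamp01(r$base_color[ch] + jitter[ch] + tex * c(1, 0.7, 0.6)[ch])

  mask <- matrix(0, s, s)
  if (r$n_lesions > 0) {
    # class-dependent appearance: odd classes are dark ulcer-like patches,
    # even classes pale polyp-like protrusions; the mean channel shift has
    # magnitude `lesion_contrast` in both cases.
    dir <- if (cls %% 2L == 1L) -1 else 1
    chroma <- if (cls %% 2L == 1L) c(0.7, 1.2, 1.1) else c(1.15, 1.0, 0.85)
    chroma <- chroma / mean(chroma)
    for (l in seq_len(r$n_lesions)) {
      a <- runif(1, r$lesion_size[1], r$lesion_size[2]) * s
      b <- runif(1, r$lesion_size[1], r$lesion_size[2]) * s
      m <- max(a, b) + 2
      cy <- runif(1, m + 1, s - m)
      cx <- runif(1, m + 1, s - m)
      ef <- ellipse_field(s, cy, cx, a, b, runif(1, 0, pi))
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] + dir * r$lesion_contrast * chroma[ch] * ef$soft
      mask[ef$hard] <- 1
    }
    img <- clamp01(img)
  }

  if (r$n_bubbles > 0) {
    for (bb in seq_len(r$n_bubbles)) {
      rad <- runif(1, r$bubble_radius[1], r$bubble_radius[2]) * s
      rad <- max(rad, 1.2)
      cy <- runif(1, rad + 1, s - rad)
      cx <- runif(1, rad + 1, s - rad)
      ef <- ellipse_field(s, cy, cx, rad, rad, 0)
      w <- r$bubble_brightness * ef$soft
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - w) + w
    }
  }
  raw <- img  # pre-lighting scene: the generator contrast self-check target
  if (r$vignette > 0) {
    # radial illumination falloff of the endoscope optics; the optical
    # center wanders a little between frames
    cy <- s / 2 + runif(1, -0.1, 0.1) * s
    cx <- s / 2 + runif(1, -0.1, 0.1) * s
    yy <- matrix(seq_len(s), s, s) - cy
    xx <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
    rr2 <- (yy^2 + xx^2) / (s / 2)^2
    vg <- 1 - r$vignette * pmin(rr2, 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * vg
  }
  if (r$haze_weight > 0)
    img <- (1 - r$haze_weight) * img + r$haze_weight
  list(img = clamp01(img), mask = mask, raw = raw)
}

#' Recipe for feature tables with planted informative dimensions
#'
#' @param n number of samples.
#' @param d total feature dimensions.
#' @param k number of informative dimensions (the rest are standard normal
#'   noise).
#' @param effect class-mean separation of adjacent classes in noise-sd units.
#' @param n_classes number of classes (balanced).
#' @param seed RNG seed.
#' @return an object of class `table_recipe`.
#' @export
table_recipe <- function(n = 200, d = 50, k = 5, effect = 2,
                         n_classes = 2, seed = 1) {
  if (k > d) stop("`k` informative dimensions cannot exceed `d`", call. = FALSE)
  stopifnot(n >= 2 * n_classes, n_classes >= 2, effect >= 0)
  structure(list(n = n, d = d, k = k, effect = effect,
                 n_classes = n_classes, seed = seed),
            class = "table_recipe")
}

#' Generate a feature table with planted informative columns
#'
#' Informative columns carry class-dependent means separated by `effect`
#' noise standard deviations between adjacent classes; all other columns are
#' pure standard normal noise. The informative column indices are returned as
#' ground truth for selection experiments.
#'
#' @param recipe a [table_recipe()].
#' @return list with `x` (`n x d` matrix, columns `f1..fd`), `y` (integer
#'   class labels `1..n_classes`), `informative` (integer column indices).
#' @export
make_table <- function(recipe) {
  stopifnot(inherits(recipe, "table_recipe"))
  r <- recipe
  with_seed(r$seed, {
    y <- rep(seq_len(r$n_classes), length.out = r$n)
    x <- matrix(rnorm(r$n * r$d), r$n, r$d)
    informative <- sort(sample.int(r$d, r$k))
    centers <- r$effect * (seq_len(r$n_classes) - (r$n_classes + 1) / 2)
    for (j in informative) x[, j] <- x[, j] + centers[y]
    colnames(x) <- paste0("f", seq_len(r$d))
    stopifnot(length(informative) == r$k, !anyNA(x))
    list(x = x, y = y, informative = informative)
  })
}
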