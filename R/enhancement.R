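#' Configuration for the hybrid contrast-enhancement chain
#'
#' The chain runs: channel split, per-channel denoising (bubble/highlight
#' suppression), white top-hat and black bottom-hat filtering, additive hat
#' fusion, dark-channel-prior dehazing, and a multiplicative final fusion.
#' All free parameters live here.
#'
#' @param selem_radius disk radius (pixels) of the morphological structuring
#'   element; must be at least 1. Default 5 at 256x256 scale, the typical
#'   vessel/bubble scale.
#' @param denoiser denoiser choice: `"identity"`, `"median"` (exact 3x3
#'   median) or `"nlm"` (non-local means). Default `"median"`.
#' @param dehaze_patch dark-channel min-filter patch side (odd, pixels).
#' @param dehaze_omega haze retention weight `omega` in the transmission
#'   estimate `t = 1 - omega * dark(I/A)`.
#' @param dehaze_t0 transmission floor, keeps the recovery bounded.
#' @param hat_mode how the hat transforms are fused with the image:
#'   `"additive"` (default; the classic morphological contrast enhancement
#'   `image + tophat - bothat`) or `"replace"` (`tophat + bothat - image`,
#'   which is non-zero only where hat responses exceed the pixel intensity
#'   and therefore blanks typical bright scenes; kept for comparison).
#' @param subtract_source which image the `"replace"` fusion subtracts:
#'   `"original"` or `"denoised"`.
#' @return an object of class `enhancement_config`.
#' @export
enhancement_config <- function(selem_radius = 5, denoiser = "median",
                               dehaze_patch = 15, dehaze_omega = 0.95,
                               dehaze_t0 = 0.1,
                               hat_mode = c("additive", "replace"),
                               subtract_source = c("original", "denoised")) {
  subtract_source <- match.arg(subtract_source)
  hat_mode <- match.arg(hat_mode)
  denoiser <- match.arg(denoiser, c("identity", "median", "nlm"))
  stopifnot(selem_radius >= 1, dehaze_patch >= 1, dehaze_patch %% 2 == 1,
            dehaze_omega > 0, dehaze_omega <= 1,
            dehaze_t0 > 0, dehaze_t0 < 1)
  structure(list(selem_radius = as.integer(selem_radius), denoiser = denoiser,
                 dehaze_patch = as.integer(dehaze_patch),
                 dehaze_omega = dehaze_omega, dehaze_t0 = dehaze_t0,
                 hat_mode = hat_mode, subtract_source = subtract_source),
            class = "enhancement_config")
}

#' Split an RGB image into its three channel planes
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @return list of three `H x W` matrices (`c1`, `c2`, `c3`); stacking them
#'   back reproduces `img` exactly.
#' @export
split_channels <- function(img) {
  check_rgb_image(img)
  list(c1 = img[, , 1], c2 = img[, , 2], c3 = img[, , 3])
}

#' A per-channel denoising operator
#'
#' @param name `"identity"`, `"median"` or `"nlm"`.
#' @param ... operator parameters: `h` and `search` for `"nlm"`.
#' @return an object of class `denoiser_handle`: a function of one gray map
#'   returning a gray map of identical shape.
#' @export
denoiser_handle <- function(name = c("median", "identity", "nlm"), ...) {
  name <- match.arg(name)
  pars <- list(...)
  fn <- switch(name,
    identity = function(x) x,
    median = median_filter3,
    nlm = function(x) nlm_filter(x, h = pars$h %||% 0.1,
                                 search = pars$search %||% 2L))
  structure(list(name = name, fn = fn, params = pars),
            class = "denoiser_handle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replicate-pad a matrix by `k` pixels on every side
pad_replicate <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(rep(1L, k), seq_len(n), rep(n, k))
  ci <- c(rep(1L, k), seq_len(m), rep(m, k))
  x[ri, ci, drop = FALSE]
}

#' Exact 3x3 median filter
#'
#' Median of each pixel's 3x3 neighborhood (replicated borders), computed with
#' a 9-element pmin/pmax sorting network, so it is exact (no histogram
#' quantization).
#'
#' @param x numeric matrix.
#' @return filtered matrix of identical shape.
#' @export
median_filter3 <- function(x) {
  check_gray_map(x)
  p <- pad_replicate(x, 1L)
  n <- nrow(x); m <- ncol(x)
  v <- vector("list", 9L)
  k <- 0L
  for (a in 0:2) for (b in 0:2) {
    k <- k + 1L
    v[[k]] <- p[a + seq_len(n), b + seq_len(m), drop = FALSE]
  }
  # median-of-9 selection network (19 pairwise min/max ops)
  swp <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  swp(2,3); swp(5,6); swp(8,9); swp(1,2); swp(4,5); swp(7,8)
  swp(2,3); swp(5,6); swp(8,9); swp(1,4); swp(6,9); swp(5,8)
  swp(4,7); swp(2,5); swp(3,6); swp(5,8); swp(5,3); swp(7,5); swp(5,3)
  matrix(v[[5]], n, m)
}

# 3x3 box sum with replicated borders
boxsum3 <- function(z) {
  p <- pad_replicate(z, 1L)
  n <- nrow(z); m <- ncol(z)
  s <- matrix(0, n, m)
  for (a in 0:2) for (b in 0:2)
    s <- s + p[a + seq_len(n), b + seq_len(m)]
  s
}

# patch-based non-local means, 3x3 patches, (2*search+1)^2 window
nlm_filter <- function(x, h = 0.1, search = 2L) {
  check_gray_map(x)
  n <- nrow(x); m <- ncol(x)
  k <- as.integer(search)
  p <- pad_replicate(x, k)
  wsum <- matrix(0, n, m); acc <- matrix(0, n, m)
  for (dy in -k:k) for (dx in -k:k) {
    sh <- p[k + dy + seq_len(n), k + dx + seq_len(m)]
    d2 <- boxsum3((x - sh)^2) / 9
    w <- exp(-d2 / h^2)
    wsum <- wsum + w
    acc <- acc + w * sh
  }
  acc / wsum
}

#' Denoise the three channel planes and recombine
#'
#' @param channels list of three same-shape gray maps (from
#'   [split_channels()]).
#' @param denoiser a [denoiser_handle()].
#' @return list with `f1`, `f2`, `f3` (denoised planes) and `f4`
#'   (`H x W x 3` recombined image, clamped to `[0, 1]`).
#' @export
denoise_channels <- function(channels, denoiser = denoiser_handle("median")) {
  stopifnot(inherits(denoiser, "denoiser_handle"), length(channels) == 3L)
  d <- dim(channels[[1]])
  if (!all(vapply(channels, function(c) identical(dim(c), d), logical(1))))
    stop("channel planes have mismatched shapes", call. = FALSE)
  f <- lapply(channels, denoiser$fn)
  for (i in 1:3) {
    if (!identical(dim(f[[i]]), d))
      stop("denoiser changed the plane shape", call. = FALSE)
  }
  f4 <- array(0, c(d, 3L))
  for (i in 1:3) f4[, , i] <- f[[i]]
  list(f1 = f[[1]], f2 = f[[2]], f3 = f[[3]], f4 = clamp01(f4))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' White top-hat and black bottom-hat of an RGB image
#'
#' Per channel: top-hat = image minus its morphological opening (small bright
#' structures); bottom-hat = closing minus image (small dark structures).
#' Both are non-negative by construction.
#'
#' @param img `H x W x 3` array.
#' @param radius disk structuring-element radius in pixels; must satisfy
#'   `1 <= radius < min(H, W) / 2`.
#' @return list with `top` and `bot`, both `H x W x 3` arrays.
#' @export
top_bottom_hat <- function(img, radius = 5) {
  check_rgb_image(img)
  d <- dim(img)
  if (radius < 1 || radius >= min(d[1:2]) / 2)
    stop("structuring element degenerate: need 1 <= radius < min(H, W)/2",
         call. = FALSE)
  br <- disc_brush(radius)
  top <- img; bot <- img
  for (ch in 1:3) {
    top[, , ch] <- t(as.matrix(EBImage::whiteTopHat(t(img[, , ch]), br)))
    bot[, , ch] <- t(as.matrix(EBImage::blackTopHat(t(img[, , ch]), br)))
  }
  list(top = pmax(top, 0), bot = pmax(bot, 0))
}

#' Fuse the hat transforms with the source image
#'
#' Two fusions, both clamped to `[0, 1]`: `"replace"` is the elementwise
#' `top + bot - source` (non-zero only where hat responses exceed the pixel
#' intensity); `"additive"` is the classic morphological contrast
#' enhancement `source + top - bot` (bright fine structure amplified, dark
#' fine structure suppressed).
#'
#' @param top,bot `H x W x 3` hat transforms.
#' @param original `H x W x 3` source image.
#' @param mode `"replace"` (default) or `"additive"`.
#' @return fused `H x W x 3` array in `[0, 1]`.
#' @export
fuse_hat <- function(top, bot, original, mode = c("replace", "additive")) {
  mode <- match.arg(mode)
  if (!identical(dim(top), dim(bot)) || !identical(dim(top), dim(original)))
    stop("shape mismatch among hat images and source", call. = FALSE)
  if (mode == "replace") clamp01(top + bot - original)
  else clamp01(original + top - bot)
}

# channel-minimum followed by a square min-filter (the "dark channel")
dark_channel <- function(img, patch) {
  dk <- pmin(img[, , 1], img[, , 2], img[, , 3])
  br <- matrix(1, patch, patch)
  t(as.matrix(EBImage::erode(t(dk), br)))
}

#' Dark-channel-prior dehazing
#'
#' Estimates atmospheric light `A` from the brightest 0.1% of dark-channel
#' pixels, transmission `t = max(1 - omega * dark(I / A), t0)`, and recovers
#' the scene `J = (I - A) / t + A`, clamped to `[0, 1]`.
#'
#' @param img `H x W x 3` hazy image.
#' @param cfg an [enhancement_config()] providing `dehaze_patch`,
#'   `dehaze_omega`, `dehaze_t0`.
#' @return dehazed `H x W x 3` array in `[0, 1]`.
#' @export
dehaze <- function(img, cfg = enhancement_config()) {
  check_rgb_image(img)
  patch <- min(cfg$dehaze_patch, 2L * (min(dim(img)[1:2]) %/% 2L) - 1L)
  dk <- dark_channel(img, patch)
  n_top <- max(1L, round(0.001 * length(dk)))
  idx <- order(dk, decreasing = TRUE)[seq_len(n_top)]
  A <- pmax(c(mean(img[, , 1][idx]), mean(img[, , 2][idx]),
              mean(img[, , 3][idx])), 1e-3)
  norm <- img
  for (ch in 1:3) norm[, , ch] <- img[, , ch] / A[ch]
  tmap <- pmax(1 - cfg$dehaze_omega * dark_channel(clamp01(norm), patch),
               cfg$dehaze_t0)
  out <- img
  for (ch in 1:3) out[, , ch] <- (img[, , ch] - A[ch]) / tmap + A[ch]
  clamp01(out)
}

#' Final multiplicative fusion of the enhancement chain
#'
#' `nw = fused * top`, `ml = hz * nw` (all elementwise), output
#' `clamp(ml + hz)`.
#'
#' @param hz dehazed image.
#' @param fused hat-fused image.
#' @param top white top-hat image.
#' @return enhanced `H x W x 3` array in `[0, 1]`.
#' @export
fuse_final <- function(hz, fused, top) {
  if (!identical(dim(hz), dim(fused)) || !identical(dim(hz), dim(top)))
    stop("shape mismatch among fusion inputs", call. = FALSE)
  nw <- fused * top
  ml <- hz * nw
  clamp01(ml + hz)
}

#' Hybrid sequential-fusion contrast enhancement
#'
#' Deterministic composition of the whole chain: channel split, per-channel
#' denoise, top/bottom-hat, additive hat fusion, dark-channel dehazing of the
#' fused image, multiplicative final fusion. Output shape equals input shape
#' and all values stay in `[0, 1]`.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param cfg an [enhancement_config()].
#' @return enhanced `H x W x 3` array.
#' @export
enhance <- function(img, cfg = enhancement_config()) {
  check_rgb_image(img)
  ch <- split_channels(img)
  den <- denoise_channels(ch, denoiser_handle(cfg$denoiser))
  hats <- top_bottom_hat(den$f4, cfg$selem_radius)
  src <- if (cfg$subtract_source == "original") img else den$f4
  fused <- fuse_hat(hats$top, hats$bot, src, mode = cfg$hat_mode)
  hz <- dehaze(fused, cfg)
  fuse_final(hz, fused, hats$top)
}
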