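#' @import stats
#' @import utils
NULL

#' Internal: run an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Clamp values into the unit interval
#'
#' @param x numeric vector, matrix or array.
#' @return `x` with every element clipped to `[0, 1]`.
#' @export
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Validate an RGB image array
#'
#' An RGB image is an `H x W x 3` numeric array with finite values in
#' `[0, 1]`.
#'
#' @param img object to check.
#' @param arg name used in error messages.
#' @return `img`, invisibly, if valid; otherwise an error is thrown.
#' @export
check_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (!is.numeric(img) || any(!is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(sprintf("`%s` has values outside [0, 1]", arg), call. = FALSE)
  invisible(img)
}

#' Validate a single-plane gray map
#' @param x object to check.
#' @param arg name used in error messages.
#' @return `x`, invisibly.
#' @export
check_gray_map <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric matrix", arg), call. = FALSE)
  invisible(x)
}

#' Read an image file as a unit-range RGB array
#'
#' 8-bit PNG/JPEG values are rescaled to `[0, 1]`; grayscale files are
#' replicated across three channels.
#'
#' @param path file path.
#' @param size optional target side length; when given the image is resized to
#'   `size x size` (bilinear).
#' @return an `H x W x 3` array in `[0, 1]`.
#' @export
read_rgb_image <- function(path, size = NULL) {
  im <- EBImage::readImage(path)
  a <- as.array(im)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  # EBImage stores x (columns) as the first margin; transpose to row-major H x W
  a <- aperm(a, c(2L, 1L, 3L))
  if (!is.null(size) && !all(dim(a)[1:2] == size)) {
    a <- resize_rgb(a, size, size)
  }
  clamp01(a)
}

#' Write a unit-range RGB array (or gray matrix) to an image file
#'
#' @param img `H x W x 3` array or `H x W` matrix in `[0, 1]`.
#' @param path output path; format from the extension (png, jpeg, tiff).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  a <- clamp01(img)
  if (is.matrix(a)) {
    im <- EBImage::Image(t(a), colormode = "Grayscale")
  } else {
    im <- EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
  }
  EBImage::writeImage(im, path)
  invisible(path)
}

#' Resize an RGB array with bilinear interpolation
#' @param img `H x W x 3` array.
#' @param h,w target height and width in pixels.
#' @return resized `h x w x 3` array in `[0, 1]`.
#' @export
resize_rgb <- function(img, h, w) {
  im <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  out <- as.array(EBImage::resize(im, w = w, h = h))
  clamp01(aperm(out, c(2L, 1L, 3L)))
}

#' Resize a gray matrix with bilinear interpolation
#' @param x `H x W` matrix.
#' @param h,w target height and width in pixels.
#' @return resized matrix.
#' @export
resize_gray <- function(x, h, w) {
  out <- as.array(EBImage::resize(EBImage::Image(t(x)), w = w, h = h))
  t(matrix(out, nrow = w, ncol = h))
}

#' Min-max normalize to the unit interval
#'
#' A constant input maps to all zeros (there is no structure to scale).
#'
#' @param x numeric matrix or array.
#' @return normalized object with range `[0, 1]` (or all zeros).
#' @export
minmax01 <- function(x) {
  r <- range(x)
  if (!all(is.finite(r))) stop("non-finite values in `x`", call. = FALSE)
  if (r[2] - r[1] < .Machine$double.eps) {
    x[] <- 0
    return(x)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Channel-wise mean of an RGB image
#' @param img `H x W x 3` array.
#' @return `H x W` matrix of per-pixel channel means.
#' @export
channel_mean <- function(img) {
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# stack images (list of H x W x 3) into an (H, W, C, N) tensor
images_to_tensor <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}
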