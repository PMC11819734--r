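# Low-level raster helpers shared by the fixture generator, the retrieval
# filters and the augmentation pipelines.  Images are numeric matrices in
# [0, 1], row 1 = top of the image; RGB images are H x W x 3 arrays.

#' Convert an image to a single grayscale channel
#'
#' RGB inputs are collapsed with the standard luma weights
#' (0.299, 0.587, 0.114); single-channel inputs pass through.
#'
#' @param image Numeric matrix or H x W x 3 array in \[0, 1\].
#' @return Numeric matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L) {
    d3 <- dim(image)[3L]
    if (d3 == 1L) return(image[, , 1L])
    if (d3 >= 3L) {
      return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
    }
  }
  stop("`image` must be a matrix or an H x W x {1,3,4} array", call. = FALSE)
}

# Reflective (mirror) padding by `p` pixels on every side.
reflect_pad <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  if (h <= p || w <= p) stop("image too small to pad reflectively", call. = FALSE)
  ri <- c((p + 1):2, 1:h, (h - 1):(h - p))
  ci <- c((p + 1):2, 1:w, (w - 1):(w - p))
  x[ri, ci, drop = FALSE]
}

# Direct 2-D correlation of `x` with a small kernel `k`, reflective borders,
# output same size as input.  Used for Sobel and Gaussian blur; kernels are
# tiny so the shift-and-add loop is cheap and fully vectorised per offset.
conv2_reflect <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  p <- max((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  xp <- reflect_pad(x, p)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  oy <- p - (kh - 1L) %/% 2L
  ox <- p - (kw - 1L) %/% 2L
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] * xp[oy + a + 0:(h - 1L), ox + b + 0:(w - 1L)]
    }
  }
  out
}

#' Bilinear resize of a grayscale image
#'
#' @param x Numeric matrix.
#' @param out_h,out_w Output dimensions in pixels.
#' @return `out_h` x `out_w` matrix.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  h <- nrow(x); w <- ncol(x)
  stopifnot(h >= 1, w >= 1, out_h >= 1, out_w >= 1)
  if (h == out_h && w == out_w) return(x)
  # align-corners = FALSE convention: sample at pixel centres
  sy <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  sx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(sy - y0, 0), 1)
  wx <- pmin(pmax(sx - x0, 0), 1)
  a <- x[y0, x0, drop = FALSE]; b <- x[y0, x1, drop = FALSE]
  c_ <- x[y1, x0, drop = FALSE]; d <- x[y1, x1, drop = FALSE]
  top <- a * outer(1 - wy, 1 - wx) + b * outer(1 - wy, wx) +
    c_ * outer(wy, 1 - wx) + d * outer(wy, wx)
  top
}

# 1-D Gaussian kernel of odd length `size`.
gaussian_kernel_1d <- function(size, sigma) {
  stopifnot(size %% 2L == 1L, sigma > 0)
  r <- (size - 1L) / 2L
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with a separable kernel and reflective borders
#'
#' @param x Numeric matrix.
#' @param size Odd kernel side in pixels.
#' @param sigma Standard deviation in pixels.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(x, size = 5L, sigma = 1) {
  k <- gaussian_kernel_1d(as.integer(size), sigma)
  conv2_reflect(conv2_reflect(x, matrix(k, ncol = 1)), matrix(k, nrow = 1))
}

#' Read / write 8-bit grayscale PNG images
#'
#' Thin wrappers around the png package that enforce the package's image
#' convention (numeric matrix in \[0, 1\]).
#'
#' @param path File path.
#' @return `read_image_png()` returns a grayscale matrix.
#' @export
read_image_png <- function(path) {
  to_grayscale(png::readPNG(path))
}

#' @rdname read_image_png
#' @param image Numeric matrix in \[0, 1\].
#' @export
write_image_png <- function(image, path) {
  stopifnot(is.matrix(image))
  # quantise to 8 bit so regeneration is byte-identical
  img <- round(pmin(pmax(image, 0), 1) * 255) / 255
  png::writePNG(img, target = path)
  invisible(path)
}
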