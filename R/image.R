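#' Grayscale image container
#'
#' A `gray_image` is a 2-D matrix of nonnegative integer intensities
#' together with the number of representable gray levels (e.g. 256 for
#' 8-bit data).  All texture descriptors in the package operate on this
#' container.  Coordinates are row-major with the origin at the top-left.
#'
#' @param pixels integer matrix of intensities, at least 2x2.
#' @param n_levels number of representable gray levels; values must lie in
#'   `[0, n_levels - 1]`.  Defaults to the smallest power of two covering
#'   the observed maximum (minimum 2).
#' @return an object of class `gray_image` with elements `pixels`
#'   (integer matrix) and `n_levels`.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2), n_levels = 4)
#' quantize(img, 2)
#' @export
gray_image <- function(pixels, n_levels = NULL) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2x2")
  if (anyNA(pixels) || any(pixels < 0))
    stop("pixel values must be nonnegative and non-missing")
  if (any(pixels != round(pixels)))
    stop("pixel values must be integers")
  storage.mode(pixels) <- "integer"
  if (is.null(n_levels)) {
    n_levels <- max(2L, 2L^ceiling(log2(max(pixels) + 1L)))
  }
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be at least 2")
  if (max(pixels) >= n_levels)
    stop("pixel values exceed n_levels - 1")
  structure(list(pixels = pixels, n_levels = n_levels),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, %d gray levels, range [%d, %d]>\n",
              nrow(x$pixels), ncol(x$pixels), x$n_levels,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

as_gray_image <- function(x, n_levels = NULL) {
  if (inherits(x, "gray_image")) x else gray_image(x, n_levels)
}

#' Reduce the number of gray levels of an image
#'
#' Maps intensity `v` to `floor(v * n_levels / old_levels)`, a monotone
#' rescaling onto `[0, n_levels - 1]`.  Co-occurrence and run-length
#' matrices at full 12- or 16-bit depth are impractically sparse, so
#' descriptors are computed on quantized images (32 levels by default
#' elsewhere in the package).
#'
#' @param image a [gray_image] (or bare integer matrix).
#' @param n_levels target number of gray levels, at least 2.
#' @return a [gray_image] with `n_levels` levels.
#' @export
quantize <- function(image, n_levels) {
  image <- as_gray_image(image)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) stop("'n_levels' must be >= 2")
  px <- floor(image$pixels * (n_levels / image$n_levels))
  px[px > n_levels - 1L] <- n_levels - 1L
  storage.mode(px) <- "integer"
  gray_image(px, n_levels)
}
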