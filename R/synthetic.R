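#' Reference class sizes of the eight-category archive
#'
#' The class distribution the pipeline's study conditions emulate: eight
#' diagnostic categories with counts 67, 220, 24, 13, 8, 21, 50 and 8
#' (411 images in total) — a strongly imbalanced multiclass problem with
#' the second class in the majority.
#'
#' @return named integer vector of length 8.
#' @export
birads_class_counts <- function() {
  stats::setNames(c(67L, 220L, 24L, 13L, 8L, 21L, 50L, 8L),
                  as.character(1:8))
}

#' Texture class specifications for the synthetic image generator
#'
#' Each class is a stationary Gaussian random field parameterized by its
#' spatial correlation length (smoothness), intensity spread (contrast)
#' and mean level — exactly the second-order structure the co-occurrence
#' and run-length descriptors measure, so classes are separable by the
#' pipeline without resembling real mammograms.
#'
#' @param counts images per class (default [birads_class_counts()]).
#' @param correlation_length Gaussian smoothing sigma per class, pixels.
#' @param contrast intensity standard deviation per class (gray levels).
#' @param base_level mean intensity per class (gray levels).
#' @return data.frame with one row per class.
#' @export
texture_class_specs <- function(counts = birads_class_counts(),
                                correlation_length =
                                  seq(1, 8, length.out = length(counts)),
                                contrast = rep(45, length(counts)),
                                base_level = rep(128, length(counts))) {
  data.frame(label = seq_along(counts), n_images = as.integer(counts),
             correlation_length = correlation_length,
             contrast = contrast, base_level = base_level)
}

# stationary Gaussian random field: white noise smoothed by circular
# convolution with a Gaussian kernel (via FFT), then restandardized
gaussian_field <- function(side, sigma) {
  z <- matrix(stats::rnorm(side * side), side, side)
  if (sigma > 0) {
    d <- pmin(0:(side - 1L), side - 0:(side - 1L))
    k1 <- exp(-d^2 / (2 * sigma^2))
    ker <- outer(k1, k1)
    ker <- ker / sum(ker)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(ker), inverse = TRUE)) /
      length(z)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate a labeled synthetic texture image dataset
#'
#' Draws, per class, seeded Gaussian random fields smoothed at the
#' class's correlation length, scaled by its contrast around its base
#' level, clamped and quantized to 8 bits.  Deterministic for a given
#' seed.  When `dir` is given, images are written as PNG files and a
#' `manifest.csv` with paths, labels and generator parameters.
#'
#' @param specs a [texture_class_specs()] data.frame.
#' @param size image side in pixels (at least 32; default 64).
#' @param seed RNG seed.
#' @param dir optional output directory for PNGs and the manifest.
#' @return object of class `texture_dataset`: list with `images` (list
#'   of [gray_image]), `manifest` (data.frame: `image`, `label`, `path`,
#'   generator parameters) and `seed`.
#' @export
make_texture_dataset <- function(specs = texture_class_specs(), size = 64L,
                                 seed = 1L, dir = NULL) {
  size <- as.integer(size)
  if (size < 32L) stop("'size' must be at least 32")
  if (any(specs$n_images < 1L)) stop("each class needs at least one image")
  set.seed(seed)
  images <- list(); rows <- list(); idx <- 0L
  for (ci in seq_len(nrow(specs))) {
    s <- specs[ci, ]
    for (r in seq_len(s$n_images)) {
      idx <- idx + 1L
      f <- gaussian_field(size, s$correlation_length)
      px <- round(s$base_level + s$contrast * f)
      px <- pmin(pmax(px, 0), 255)
      img <- gray_image(matrix(as.integer(px), size, size),
                        n_levels = 256L)
      path <- if (is.null(dir)) NA_character_ else
        file.path(dir, sprintf("class%d_img%03d.png", s$label, r))
      images[[idx]] <- img
      rows[[idx]] <- data.frame(
        image = idx, label = s$label, path = path,
        correlation_length = s$correlation_length,
        contrast = s$contrast, base_level = s$base_level)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(images)) write_png(images[[i]], manifest$path[i])
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(images = images, manifest = manifest, seed = seed),
            class = "texture_dataset")
}

#' @export
print.texture_dataset <- function(x, ...) {
  cat(sprintf("<texture_dataset: %d images, %d classes, seed %d>\n",
              nrow(x$manifest), length(unique(x$manifest$label)), x$seed))
  print(table(label = x$manifest$label))
  invisible(x)
}

#' Generate a labeled synthetic tabular dataset
#'
#' A desk-scale surrogate for an extracted feature table: class means for
#' the `n_informative` features are seeded Gaussian draws standardized so
#' that every informative coordinate has spread exactly `class_sep`
#' across the class means, samples are unit-variance Gaussians around
#' their class mean, and `n_noise` additional features are
#' label-independent standard normals.  `class_sep = 0` carries no
#' signal; with the default 10 informative features, `class_sep = 1`
#' gives moderately overlapping classes and `class_sep = 4` nearly
#' separable ones.
#'
#' @param n_per_class samples per class (default [birads_class_counts()]).
#' @param n_informative number of class-shifted features (default 10).
#' @param n_noise number of label-independent features (default 78, so
#'   the table has 88 columns like the image feature table).
#' @param class_sep distance of each class mean from the origin.
#' @param seed RNG seed.
#' @return list with `X` (matrix, informative columns first, named
#'   `inf1..`/`noise1..`), `y` (integer labels) and the generator
#'   parameters.
#' @export
make_tabular_dataset <- function(n_per_class = birads_class_counts(),
                                 n_informative = 10L, n_noise = 78L,
                                 class_sep = 2, seed = 1L) {
  if (any(n_per_class < 1L)) stop("each class needs at least one sample")
  k <- length(n_per_class)
  set.seed(seed)
  means <- matrix(stats::rnorm(k * n_informative), k, n_informative)
  if (k > 1L) {
    # standardize each coordinate's spread across class means so every
    # informative feature individually separates classes at class_sep
    sds <- apply(means, 2L, stats::sd)
    means <- sweep(sweep(means, 2L, colMeans(means)), 2L,
                   ifelse(sds > 0, sds, 1), "/")
  }
  means <- means * class_sep
  n <- sum(n_per_class)
  y <- rep(seq_len(k), n_per_class)
  Xi <- means[y, , drop = FALSE] +
    matrix(stats::rnorm(n * n_informative), n, n_informative)
  Xn <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  X <- cbind(Xi, Xn)
  colnames(X) <- c(sprintf("inf%d", seq_len(n_informative)),
                   if (n_noise > 0L) sprintf("noise%d", seq_len(n_noise)))
  list(X = X, y = y, n_informative = n_informative, n_noise = n_noise,
       class_sep = class_sep, seed = seed)
}
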