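#' Default feature-extraction configuration
#'
#' @param glcm_levels gray levels for co-occurrence and run-length
#'   matrices (default 32; full-depth matrices are impractically sparse).
#' @param distance co-occurrence displacement distance (default 1).
#' @param lbp_P,lbp_R local binary pattern parameters (8 neighbors,
#'   radius 1).
#' @param sfta_nt number of Otsu thresholds for SFTA (default 5, giving
#'   `2*5 - 1 = 9` binary images and 27 features).
#' @param sfta_levels gray levels at which SFTA analyzes the image
#'   (default 256; deeper inputs are quantized down first).
#' @return list of class `feature_config`.
#' @export
feature_config <- function(glcm_levels = 32L, distance = 1L, lbp_P = 8L,
                           lbp_R = 1L, sfta_nt = 5L, sfta_levels = 256L) {
  structure(list(glcm_levels = as.integer(glcm_levels),
                 distance = as.integer(distance),
                 lbp_P = as.integer(lbp_P), lbp_R = as.integer(lbp_R),
                 sfta_nt = as.integer(sfta_nt),
                 sfta_levels = as.integer(sfta_levels)),
            class = "feature_config")
}

#' Extract the combined texture feature vector of an image
#'
#' Concatenates the five descriptor families into one named vector:
#' 22 co-occurrence statistics (averaged over the four directions at the
#' configured distance), 22 co-occurrence statistics of the LBP code
#' image (LBGLCM), 7 run-length statistics (averaged over the four
#' directions), the 10-bin rotation-invariant uniform LBP histogram, and
#' `3 * (2 * nt - 1)` SFTA features — 88 in total under the default
#' configuration.  Deterministic: identical image and configuration give
#' a bit-identical vector.
#'
#' @param image a [gray_image] (any bit depth; quantization is internal).
#' @param config a [feature_config()].
#' @return named numeric vector (length 88 under defaults), names
#'   qualified by descriptor (`glcm.contrast`, `lbglcm.energy`,
#'   `glrlm.sre`, `lbp.u3`, `sfta.tb2.mean`, ...).
#' @examples
#' set.seed(1)
#' img <- gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64), 256)
#' length(extract_features(img))  # 88
#' @export
extract_features <- function(image, config = feature_config()) {
  image <- as_gray_image(image)
  qg <- quantize(image, config$glcm_levels)
  offs <- glcm_offsets(config$distance)

  glcm_f <- rowMeans(vapply(offs, function(o) glcm_features(glcm(qg, o)),
                            numeric(22L)))
  lbglcm_f <- lbglcm_features(image, P = config$lbp_P, R = config$lbp_R,
                              glcm_levels = config$glcm_levels,
                              distance = config$distance)
  glrlm_f <- rowMeans(vapply(c(0, 45, 90, 135),
                             function(d) glrlm_features(glrlm(qg, d)),
                             numeric(7L)))
  lbp_f <- lbp_histogram(lbp_image(image, P = config$lbp_P,
                                   R = config$lbp_R))
  simg <- if (image$n_levels > config$sfta_levels)
    quantize(image, config$sfta_levels) else image
  sfta_f <- sfta(simg, nt = config$sfta_nt)

  out <- c(glcm_f, lbglcm_f, glrlm_f, lbp_f, sfta_f)
  names(out) <- c(paste0("glcm.", names(glcm_f)),
                  paste0("lbglcm.", names(lbglcm_f)),
                  paste0("glrlm.", names(glrlm_f)),
                  paste0("lbp.", names(lbp_f)),
                  paste0("sfta.", names(sfta_f)))
  out
}

#' Extract features for a set of images into a feature table
#'
#' @param images list of [gray_image] objects (or a `texture_dataset`
#'   from [make_texture_dataset()]).
#' @param labels optional integer class labels, one per image.
#' @param config a [feature_config()].
#' @param paths optional source paths recorded in the table.
#' @return data.frame: one row per image, feature columns plus `label`
#'   (if given) and `path` (if given).
#' @export
feature_table <- function(images, labels = NULL, config = feature_config(),
                          paths = NULL) {
  if (inherits(images, "texture_dataset")) {
    labels <- if (is.null(labels)) images$manifest$label else labels
    images <- images$images
  }
  rows <- lapply(images, extract_features, config = config)
  tab <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(tab))
    tab$label <- as.integer(labels)
  }
  if (!is.null(paths)) tab$path <- paths
  tab
}

#' Write / read a feature table as CSV
#'
#' Fixed dialect: comma separated, UTF-8, `.` decimal, mandatory header
#' row.  Numeric values survive a round trip to full double precision.
#'
#' @param tab data.frame as produced by [feature_table()].
#' @param path file path.
#' @return `read_feature_table` returns the data.frame; the writer
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
}
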