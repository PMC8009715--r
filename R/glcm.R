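#' Gray-level co-occurrence matrix
#'
#' Counts pairs of pixel values at a fixed displacement.  Entry
#' `counts[i, j]` is the number of pixel pairs `(p, p + offset)` whose
#' values are `i - 1` and `j - 1` (levels are 0-based, matrix indices
#' 1-based).  In symmetric mode the transposed counts are added, so the
#' matrix equals its transpose; in normalized mode entries are divided by
#' their total and sum to one.
#'
#' The four standard directions at distance `d` correspond to offsets
#' `c(0, d)` (0 degrees), `c(-d, d)` (45), `c(-d, 0)` (90) and
#' `c(-d, -d)` (135); see [glcm_offsets()].
#'
#' @param image a [gray_image]; co-occurrence is computed over its
#'   `n_levels` levels, so quantize first (see [quantize()]).
#' @param offset integer `c(row_shift, col_shift)`, nonzero, smaller than
#'   the image in magnitude.
#' @param symmetric add the reversed pairs (default `TRUE`).
#' @param normalized divide by the total count (default `TRUE`).
#' @return an object of class `glcm`: list with `counts`
#'   (`n_levels` x `n_levels`), `offset`, `symmetric`, `normalized`.
#' @seealso [glcm_features()]
#' @export
glcm <- function(image, offset = c(0L, 1L), symmetric = TRUE,
                 normalized = TRUE) {
  image <- as_gray_image(image)
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop("'offset' must be a nonzero (row, col) shift")
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (abs(offset[1L]) >= nr || abs(offset[2L]) >= nc)
    stop("'offset' exceeds image dimensions")
  g <- image$n_levels
  rows <- seq_len(nr - abs(offset[1L])) + max(0L, -offset[1L])
  cols <- seq_len(nc - abs(offset[2L])) + max(0L, -offset[2L])
  v1 <- px[rows, cols, drop = FALSE]
  v2 <- px[rows + offset[1L], cols + offset[2L], drop = FALSE]
  counts <- matrix(tabulate(as.vector(v1) * g + as.vector(v2) + 1L,
                            nbins = g * g),
                   nrow = g, ncol = g, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  counts <- counts * 1.0
  if (normalized) {
    tot <- sum(counts)
    if (tot > 0) counts <- counts / tot
  }
  structure(list(counts = counts, offset = offset, symmetric = symmetric,
                 normalized = normalized),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm %dx%d, offset (%d,%d)%s%s>\n",
              nrow(x$counts), ncol(x$counts), x$offset[1L], x$offset[2L],
              if (x$symmetric) ", symmetric" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Standard co-occurrence offsets for the four directions
#'
#' @param distance pixel distance (default 1).
#' @return list of four `(row, col)` offsets at 0, 45, 90 and 135 degrees.
#' @export
glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(deg0 = c(0L, d), deg45 = c(-d, d), deg90 = c(-d, 0L),
       deg135 = c(-d, -d))
}

glcm_feature_names <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
  "max_probability", "variance", "sum_average", "sum_variance",
  "sum_entropy", "difference_variance", "difference_entropy", "imc1",
  "imc2", "inverse_difference", "inverse_difference_normalized",
  "inverse_difference_moment_normalized", "max_correlation_coefficient")

log2z <- function(p) ifelse(p > 0, log2(p), 0)
logz <- function(p) ifelse(p > 0, log(p), 0)

#' Haralick/Soh/Clausi co-occurrence statistics
#'
#' Computes the canonical set of 22 second-order texture statistics from a
#' normalized co-occurrence matrix: autocorrelation, contrast, correlation,
#' cluster prominence, cluster shade, dissimilarity, energy, entropy,
#' homogeneity (inverse difference moment), maximum probability, variance
#' (sum of squares), sum average, sum variance, sum entropy, difference
#' variance, difference entropy, the two information measures of
#' correlation, inverse difference, inverse difference normalized, inverse
#' difference moment normalized, and the maximal correlation coefficient.
#'
#' Gray levels are indexed 1..G in the moment formulas.  Entropies are in
#' bits (log base 2, with 0*log(0) = 0); the information measures of
#' correlation use natural logarithms internally, as is conventional.
#' Degenerate denominators (zero marginal variance, empty marginals)
#' yield 0 rather than NaN.
#'
#' @param m a normalized [glcm] (or bare normalized matrix).
#' @return named numeric vector of length 22.
#' @export
glcm_features <- function(m) {
  p <- if (inherits(m, "glcm")) {
    if (!m$normalized) stop("co-occurrence matrix must be normalized")
    m$counts
  } else {
    m
  }
  if (abs(sum(p) - 1) > 1e-8)
    stop("co-occurrence matrix must be normalized (entries summing to 1)")
  g <- nrow(p)
  i <- matrix(seq_len(g), g, g)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(g) * px); muy <- sum(seq_len(g) * py)
  sx <- sqrt(sum((seq_len(g) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(g) - muy)^2 * py))

  # p_{x+y}(k), k = 2..2G and p_{x-y}(k), k = 0..G-1
  pxy_sum <- as.vector(tapply(as.vector(p), as.vector(i + j), sum))
  ks <- sort(unique(as.vector(i + j)))
  pxy_dif <- as.vector(tapply(as.vector(p), as.vector(abs(i - j)), sum))
  kd <- sort(unique(as.vector(abs(i - j))))

  contrast <- sum((i - j)^2 * p)
  dissimilarity <- sum(abs(i - j) * p)
  autoc <- sum(i * j * p)
  correlation <- if (sx > 0 && sy > 0) (autoc - mux * muy) / (sx * sy) else 0
  energy <- sum(p^2)
  entropy <- -sum(p * log2z(p))
  homog <- sum(p / (1 + (i - j)^2))
  invdiff <- sum(p / (1 + abs(i - j)))
  idn <- sum(p / (1 + abs(i - j) / g))
  idmn <- sum(p / (1 + ((i - j) / g)^2))
  maxpr <- max(p)
  variance <- sum((i - mux)^2 * p)
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  sum_ent <- -sum(pxy_sum * log2z(pxy_sum))
  dif_avg <- sum(kd * pxy_dif)
  dif_var <- sum((kd - dif_avg)^2 * pxy_dif)
  dif_ent <- -sum(pxy_dif * log2z(pxy_dif))
  cshade <- sum((i + j - mux - muy)^3 * p)
  cprom <- sum((i + j - mux - muy)^4 * p)

  # information measures of correlation (natural log)
  hxy <- -sum(p * logz(p))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * logz(pxpy))
  hxy2 <- -sum(pxpy * logz(pxpy))
  hx <- -sum(px * logz(px)); hy <- -sum(py * logz(py))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  # maximal correlation coefficient: sqrt of the second-largest eigenvalue
  # of Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over non-empty levels
  keep <- px > 0 & py > 0
  mcc <- 0
  if (sum(keep) >= 2L) {
    ps <- p[keep, keep, drop = FALSE]
    q <- sweep(ps, 1L, px[keep], "/") %*% t(sweep(ps, 2L, py[keep], "/"))
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[2L]))
  }

  out <- c(autoc, contrast, correlation, cprom, cshade, dissimilarity,
           energy, entropy, homog, maxpr, variance, sum_avg, sum_var,
           sum_ent, dif_var, dif_ent, imc1, imc2, invdiff, idn, idmn, mcc)
  names(out) <- glcm_feature_names
  out
}
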