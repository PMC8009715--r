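#' Multilevel Otsu thresholds
#'
#' Finds `nt` thresholds maximizing the between-class variance of the
#' gray-level histogram, i.e. the exact maximizer of
#' `sum_c w_c mu_c^2` over all partitions of `0..n_levels-1` into
#' `nt + 1` contiguous classes.  A threshold `t` places levels `<= t` in
#' the lower class and `> t` in the upper one.  Solved by dynamic
#' programming over the histogram, which is exact for every `nt` and
#' reduces to the classical exhaustive search for `nt = 1`.  Ties are
#' broken toward the lexicographically smallest threshold vector.
#'
#' @param image a [gray_image].
#' @param nt number of thresholds, at least 1.
#' @return strictly increasing integer vector of `nt` threshold levels.
#' @export
otsu_multilevel <- function(image, nt = 1L) {
  image <- as_gray_image(image)
  nt <- as.integer(nt)
  if (nt < 1L) stop("'nt' must be at least 1")
  h <- tabulate(as.vector(image$pixels) + 1L, nbins = image$n_levels)
  present <- which(h > 0L)
  if (length(present) <= nt)
    stop("image has too few distinct gray levels for the requested 'nt'")
  # restrict to the occupied level range; empty bins inside are harmless
  h <- h / sum(h)
  L <- image$n_levels
  cw <- cumsum(h)                        # cumulative weight
  cm <- cumsum(h * (seq_len(L) - 1L))    # cumulative first moment
  # segment score for levels a..b (1-based bins): w * mu^2
  seg <- function(a, b) {
    w <- cw[b] - if (a > 1L) cw[a - 1L] else 0
    if (w <= 0) return(0)
    m <- cm[b] - if (a > 1L) cm[a - 1L] else 0
    m * m / w
  }
  # dp[k, b]: best score of splitting bins 1..b into k segments
  k_seg <- nt + 1L
  dp <- matrix(-Inf, k_seg, L)
  choice <- matrix(0L, k_seg, L)
  for (b in seq_len(L)) dp[1L, b] <- seg(1L, b)
  for (k in 2L:k_seg) {
    for (b in k:L) {
      best <- -Inf; arg <- 0L
      for (s in (k - 1L):(b - 1L)) {      # s: last bin of previous segment
        v <- dp[k - 1L, s] + seg(s + 1L, b)
        if (v > best + 1e-15) { best <- v; arg <- s }
      }
      dp[k, b] <- best
      choice[k, b] <- arg
    }
  }
  th <- integer(nt)
  b <- L
  for (k in k_seg:2L) {
    s <- choice[k, b]
    th[k - 1L] <- s - 1L                  # threshold = last level of segment
    b <- s
  }
  th
}

#' Box-counting fractal dimension of a binary set
#'
#' Covers the set with grids of dyadic box sizes `1, 2, 4, ...` up to half
#' the smaller image dimension (grid anchored at the top-left corner) and
#' returns the least-squares slope of `log(occupied boxes)` against
#' `log(1 / box size)`.  Returns 0 for an empty set and for degenerate
#' fits (a single box size, or a constant count as for a single pixel).
#'
#' @param border logical (or 0/1) matrix marking the set.
#' @return estimated fractal dimension (nonnegative real).
#' @export
box_counting_dimension <- function(border) {
  b <- border != 0
  if (!any(b)) return(0)
  nr <- nrow(b); nc <- ncol(b)
  smax <- min(nr, nc) %/% 2L
  sizes <- 1L
  while (2L * sizes[length(sizes)] <= smax)
    sizes <- c(sizes, 2L * sizes[length(sizes)])
  if (length(sizes) < 2L) return(0)
  idx <- which(b, arr.ind = TRUE) - 1L    # 0-based coordinates
  counts <- vapply(sizes, function(s) {
    cells <- idx %/% s
    nrow(unique(cells, MARGIN = 1L))
  }, numeric(1L))
  x <- log(1 / sizes)
  y <- log(counts)
  if (stats::sd(y) == 0) return(0)
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Segmentation-based fractal texture analysis (SFTA)
#'
#' Decomposes the image into `2 * nt - 1` binary images from its `nt`
#' multilevel-Otsu thresholds `t_1 < ... < t_nt`: the `nt - 1` band images
#' `t_i < pixel <= t_{i+1}` for contiguous threshold pairs (the TA set)
#' and the `nt` upper images `pixel > t_i` (the TB set).  Each binary
#' image contributes three features: (a) the box-counting fractal
#' dimension of its region border (foreground pixels with at least one
#' background 4-neighbor inside the image), (b) the mean original gray
#' level over the foreground, and
#' (c) the foreground pixel count.  A binary image with empty foreground
#' contributes `(0, 0, 0)`.
#'
#' If the image has too few distinct gray levels for `nt` Otsu thresholds
#' (e.g. a constant image), the sorted distinct levels are used as
#' thresholds, padded with the maximum level; the degenerate bands are
#' then empty and contribute zeros, keeping the feature vector finite and
#' of fixed length.
#'
#' @param image a [gray_image].
#' @param nt number of thresholds, at least 2.
#' @return named numeric vector of length `3 * (2 * nt - 1)`, ordered TA
#'   bands ascending then TB ascending, features fractal dimension, mean,
#'   size within each.
#' @export
sfta <- function(image, nt = 5L) {
  image <- as_gray_image(image)
  nt <- as.integer(nt)
  if (nt < 2L) stop("'nt' must be at least 2")
  th <- tryCatch(otsu_multilevel(image, nt), error = function(e) {
    lv <- sort(unique(as.vector(image$pixels)))
    c(lv, rep(max(lv), nt))[seq_len(nt)]
  })
  px <- image$pixels
  masks <- c(
    lapply(seq_len(nt - 1L),
           function(i) px > th[i] & px <= th[i + 1L]),
    lapply(seq_len(nt), function(i) px > th[i]))
  feats <- vapply(masks, function(m) {
    if (!any(m)) return(c(0, 0, 0))
    c(box_counting_dimension(sfta_borders(m)),
      mean(px[m]),
      sum(m))
  }, numeric(3L))
  labs <- c(paste0("ta", seq_len(nt - 1L)), paste0("tb", seq_len(nt)))
  out <- as.vector(feats)
  names(out) <- paste(rep(labs, each = 3L),
                      c("fractal_dim", "mean", "size"), sep = ".")
  out
}

# border pixels: foreground with >= 1 background 4-neighbor among the
# neighbors that exist (out-of-image neighbors are not background, so a
# half-plane's border is the straight separating line, not the frame)
sfta_borders <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(TRUE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nbg <- !pad[1:nr, 2:(nc + 1L)] | !pad[3:(nr + 2L), 2:(nc + 1L)] |
         !pad[2:(nr + 1L), 1:nc] | !pad[2:(nr + 1L), 3:(nc + 2L)]
  core & nbg
}
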