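#' Local binary pattern code image
#'
#' Each interior pixel receives the 8-bit code
#' `sum_p s(g_p - g_c) 2^p`, where `g_c` is the center value, `g_p` the
#' value of the p-th neighbor at radius `R`, and `s(x) = 1` iff `x >= 0`
#' (ties count as 1).  Neighbors are ordered counterclockwise starting
#' east: E, NE, N, NW, W, SW, S, SE (weights 2^0 .. 2^7).  Border pixels
#' have no full neighborhood and are excluded; the returned code image has
#' `2R` fewer rows and columns than the input.
#'
#' @param image a [gray_image].
#' @param P number of neighbors; only 8 is supported.
#' @param R radius in pixels (integer offsets; default 1).
#' @return a [gray_image] of LBP codes in `[0, 255]` (`n_levels = 256`).
#' @export
lbp_image <- function(image, P = 8L, R = 1L) {
  image <- as_gray_image(image)
  if (P != 8L) stop("only P = 8 neighbors is supported")
  R <- as.integer(R)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 2L * R + 2L || nc < 2L * R + 2L)
    stop("image too small for the requested LBP radius")
  rows <- (R + 1L):(nr - R)
  cols <- (R + 1L):(nc - R)
  ctr <- px[rows, cols, drop = FALSE]
  # counterclockwise from east; row offsets are negative northwards
  offs <- list(c(0L, R), c(-R, R), c(-R, 0L), c(-R, -R),
               c(0L, -R), c(R, -R), c(R, 0L), c(R, R))
  code <- matrix(0L, nrow(ctr), ncol(ctr))
  for (p in seq_along(offs)) {
    o <- offs[[p]]
    nb <- px[rows + o[1L], cols + o[2L], drop = FALSE]
    code <- code + (nb >= ctr) * 2L^(p - 1L)
  }
  gray_image(code, n_levels = 256L)
}

# number of 0/1 transitions in the circular 8-bit pattern
lbp_transitions <- function(code) {
  bits <- (matrix(code, length(code), 8L) %/%
             rep(2L^(0:7), each = length(code))) %% 2L
  rowSums(bits != bits[, c(2:8, 1L), drop = FALSE])
}

#' Rotation-invariant uniform LBP histogram
#'
#' Maps each 8-bit LBP code to one of 10 bins: uniform patterns (at most
#' two 0/1 transitions around the circle) are binned by their number of
#' set bits (0..8, nine bins); all non-uniform patterns share the tenth
#' bin.  The histogram is normalized to sum to one.
#'
#' @param codes a [gray_image] of LBP codes (see [lbp_image()]) or an
#'   integer matrix/vector of codes in `[0, 255]`.
#' @return named numeric vector of length 10 summing to 1
#'   (`u0`..`u8`, `nonuniform`).
#' @export
lbp_histogram <- function(codes) {
  v <- if (inherits(codes, "gray_image")) as.vector(codes$pixels)
       else as.vector(codes)
  if (length(v) == 0L) stop("empty code input")
  if (any(v < 0L | v > 255L)) stop("LBP codes must lie in [0, 255]")
  map <- lbp_riu_table()
  h <- tabulate(map[v + 1L] + 1L, nbins = 10L)
  h <- h / sum(h)
  names(h) <- c(paste0("u", 0:8), "nonuniform")
  h
}

# bin index (0..9) for each code 0..255
lbp_riu_table <- function() {
  code <- 0:255
  tr <- lbp_transitions(code)
  nbits <- rowSums((matrix(code, 256L, 8L) %/%
                      rep(2L^(0:7), each = 256L)) %% 2L)
  ifelse(tr <= 2L, nbits, 9L)
}

#' Co-occurrence features of the LBP code image
#'
#' The LBGLCM descriptor: the image is LBP-coded, the code image is
#' re-quantized to `glcm_levels` gray levels (codes span 0..255, which
#' would otherwise give a 256x256 co-occurrence matrix), and the 22
#' co-occurrence statistics are computed, averaged over the four standard
#' directions.  Pure composition of [lbp_image()], [quantize()], [glcm()]
#' and [glcm_features()].
#'
#' @param image a [gray_image].
#' @param P,R LBP parameters (see [lbp_image()]).
#' @param glcm_levels gray levels for the code co-occurrence (default 32).
#' @param distance co-occurrence displacement distance (default 1).
#' @return named numeric vector of length 22.
#' @export
lbglcm_features <- function(image, P = 8L, R = 1L, glcm_levels = 32L,
                            distance = 1L) {
  codes <- quantize(lbp_image(image, P = P, R = R), glcm_levels)
  feats <- vapply(glcm_offsets(distance),
                  function(o) glcm_features(glcm(codes, o)),
                  numeric(22L))
  rowMeans(feats)
}
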