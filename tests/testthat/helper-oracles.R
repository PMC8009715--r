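# Brute-force oracles, written independently of the package internals.

# seeded random test image
random_image <- function(side = 8L, levels = 4L, seed = 1L) {
  set.seed(seed)
  gray_image(matrix(sample(0:(levels - 1L), side * side, replace = TRUE),
                    side, side), n_levels = levels)
}

# exhaustive pair enumeration for co-occurrence counts
glcm_oracle <- function(img, offset, symmetric = TRUE) {
  px <- img$pixels
  g <- img$n_levels
  counts <- matrix(0, g, g)
  for (r in seq_len(nrow(px))) {
    for (c in seq_len(ncol(px))) {
      r2 <- r + offset[1L]; c2 <- c + offset[2L]
      if (r2 >= 1 && r2 <= nrow(px) && c2 >= 1 && c2 <= ncol(px)) {
        i <- px[r, c] + 1L; j <- px[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts
}

# exhaustive run enumeration along a direction
glrlm_oracle <- function(img, direction) {
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  step <- switch(as.character(direction),
                 "0" = c(0L, 1L), "45" = c(-1L, 1L),
                 "90" = c(1L, 0L), "135" = c(1L, 1L))
  counts <- matrix(0, img$n_levels, max(nr, nc))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    # run start: the predecessor along the line is absent or differs
    pr <- r - step[1L]; pc <- c - step[2L]
    if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc &&
        px[pr, pc] == px[r, c]) next
    len <- 0L; rr <- r; cc <- c
    while (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
           px[rr, cc] == px[r, c]) {
      len <- len + 1L
      rr <- rr + step[1L]; cc <- cc + step[2L]
    }
    counts[px[r, c] + 1L, len] <- counts[px[r, c] + 1L, len] + 1
  }
  counts[, seq_len(max(which(colSums(counts) > 0))), drop = FALSE]
}

# direct enumeration of the 8 neighbor comparisons at one pixel
lbp_code_oracle <- function(px, r, c) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  code <- 0L
  for (p in seq_along(offs)) {
    nb <- px[r + offs[[p]][1L], c + offs[[p]][2L]]
    if (nb >= px[r, c]) code <- code + 2L^(p - 1L)
  }
  code
}

# uniformity of an 8-bit pattern by direct bit walking
lbp_uniform_oracle <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != c(bits[-1], bits[1])) <= 2L
}

# exhaustive single-threshold Otsu: maximize between-class variance
otsu1_oracle <- function(img) {
  v <- as.vector(img$pixels)
  n <- length(v)
  best <- -Inf; arg <- NA_integer_
  for (t in 0:(img$n_levels - 2L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    bc <- length(lo) / n * mean(lo)^2 + length(hi) / n * mean(hi)^2
    if (bc > best + 1e-12) { best <- bc; arg <- t }
  }
  arg
}

# brute-force K nearest neighbor labels from a full distance table
knn_oracle <- function(X, i, K) {
  d <- sqrt(colSums((t(X) - X[i, ])^2))
  d[i] <- Inf
  order(d)[seq_len(K)]
}

# central-difference Jacobian of the network residuals
fd_jacobian <- function(net, spec, X, Y, h = 1e-6) {
  th <- mammotex:::mlp_flatten(net)
  e0 <- mammotex:::mlp_residuals(net, X, Y)
  J <- matrix(0, length(e0), length(th))
  for (i in seq_along(th)) {
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    J[, i] <- (mammotex:::mlp_residuals(mammotex:::mlp_unflatten(tp, spec),
                                        X, Y) -
               mammotex:::mlp_residuals(mammotex:::mlp_unflatten(tm, spec),
                                        X, Y)) / (2 * h)
  }
  J
}
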