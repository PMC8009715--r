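#' Class imbalance ratio
#'
#' The ratio `m_s / m_l` of a minority-class count to the majority-class
#' count; oversampling drives this toward 1.
#'
#' @param m_s minority class size (at least 1).
#' @param m_l majority class size (`m_l >= m_s`).
#' @return value in `(0, 1]`.
#' @examples
#' imbalance_ratio(67, 220)   # 0.3045...
#' @export
imbalance_ratio <- function(m_s, m_l) {
  if (m_l < 1) stop("majority count must be positive")
  if (m_s < 1 || m_s > m_l) stop("need 1 <= m_s <= m_l")
  m_s / m_l
}

#' Number of synthetic samples to generate for one class
#'
#' `G = round((m_l - m_s) * beta)`; `beta = 1` balances the class fully.
#'
#' @param m_l majority class size.
#' @param m_s minority class size.
#' @param beta balance level in `(0, 1]`.
#' @return nonnegative integer.
#' @export
n_to_generate <- function(m_l, m_s, beta = 1) {
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]")
  as.integer(round((m_l - m_s) * beta))
}

# index matrix of the K nearest rows of `ref` for each row of `query`
# (self excluded when `self_idx` maps query rows to ref rows);
# ties broken by lower index
knn_index <- function(query, ref, K, self_idx = NULL) {
  d2 <- outer(rowSums(query^2), rep(1, nrow(ref))) -
    2 * query %*% t(ref) +
    outer(rep(1, nrow(query)), rowSums(ref^2))
  if (!is.null(self_idx))
    d2[cbind(seq_len(nrow(query)), self_idx)] <- Inf
  nb <- apply(d2, 1L, function(d) order(d)[seq_len(K)])
  t(matrix(nb, nrow = K))
}

#' ADASYN difficulty weights for a minority class
#'
#' For each minority sample, the fraction `r_i` of its `K` Euclidean
#' nearest neighbors (searched over the whole dataset, self excluded)
#' that carry a different label, normalized to sum to one.  Samples in
#' mixed-class neighborhoods — the hard-to-learn ones — get larger
#' weights and hence more synthetic offspring.  If every `r_i` is zero
#' the weights fall back to uniform.
#'
#' @param X numeric feature matrix.
#' @param y label vector.
#' @param minority_label the class being oversampled.
#' @param K neighbor count (`K <= nrow(X) - 1`).
#' @return normalized weight vector over the minority samples (in row
#'   order of the minority class within `X`).
#' @export
density_ratios <- function(X, y, minority_label, K = 5L) {
  X <- as.matrix(X)
  if (K >= nrow(X)) stop("'K' must be smaller than the number of samples")
  min_idx <- which(y == minority_label)
  if (length(min_idx) == 0L) stop("minority class has no samples")
  nb <- knn_index(X[min_idx, , drop = FALSE], X, K, self_idx = min_idx)
  r <- vapply(seq_along(min_idx),
              function(i) mean(y[nb[i, ]] != minority_label),
              numeric(1L))
  if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
}

#' Largest-remainder integer allocation
#'
#' Rounds `r * G` to integers summing exactly to `G`: floors are taken,
#' then the remaining units go to the largest fractional remainders, ties
#' broken by lower index.
#'
#' @param r nonnegative weights summing to 1.
#' @param G total count to allocate.
#' @return integer vector with `sum == G`.
#' @export
allocate_counts <- function(r, G) {
  G <- as.integer(G)
  if (G < 0L) stop("'G' must be nonnegative")
  if (abs(sum(r) - 1) > 1e-8) stop("weights must sum to 1")
  raw <- r * G
  g <- floor(raw)
  left <- G - sum(g)
  if (left > 0L) {
    frac <- raw - g
    extra <- order(-frac, seq_along(r))[seq_len(left)]
    g[extra] <- g[extra] + 1L
  }
  as.integer(g)
}

#' Generate synthetic minority samples by neighbor interpolation
#'
#' Each synthetic sample is `s = x_i + lambda * (x_z - x_i)` with
#' `lambda ~ Uniform(0, 1)` and `x_z` drawn uniformly from the seed's
#' `K` nearest same-class neighbors, so every synthetic point is a convex
#' combination of two same-class originals.  A class with a single
#' sample yields duplicates of that sample (zero displacement), with a
#' warning.
#'
#' @param X numeric feature matrix (original feature space).
#' @param y label vector.
#' @param minority_label class to synthesize.
#' @param g integer vector: synthetic count per minority sample (row
#'   order of the class within `X`).
#' @param K same-class neighbor count.
#' @param Xs optional standardized copy of `X` used for the neighbor
#'   search (defaults to `X`).
#' @return numeric matrix of `sum(g)` synthetic rows.
#' @export
synthesize <- function(X, y, minority_label, g, K = 5L, Xs = NULL) {
  X <- as.matrix(X)
  if (is.null(Xs)) Xs <- X
  min_idx <- which(y == minority_label)
  stopifnot(length(g) == length(min_idx))
  total <- sum(g)
  out <- matrix(0, total, ncol(X))
  if (total == 0L) return(out)
  if (length(min_idx) == 1L) {
    warning("class ", minority_label,
            " has a single sample; synthetics are duplicates")
    out[] <- rep(X[min_idx, ], each = total)
    return(out)
  }
  Kc <- min(K, length(min_idx) - 1L)
  pos <- match(min_idx, min_idx)
  nb <- knn_index(Xs[min_idx, , drop = FALSE],
                  Xs[min_idx, , drop = FALSE], Kc, self_idx = pos)
  row <- 1L
  for (i in seq_along(min_idx)) {
    if (g[i] == 0L) next
    zi <- min_idx[nb[i, sample.int(Kc, g[i], replace = TRUE)]]
    lam <- stats::runif(g[i])
    xi <- X[min_idx[i], ]
    out[row:(row + g[i] - 1L), ] <-
      matrix(xi, g[i], ncol(X), byrow = TRUE) +
      lam * (X[zi, , drop = FALSE] -
               matrix(xi, g[i], ncol(X), byrow = TRUE))
    row <- row + g[i]
  }
  out
}

#' Adaptive synthetic oversampling of all minority classes
#'
#' Multiclass ADASYN: every class whose imbalance ratio against the
#' largest class falls below `d_threshold` receives
#' `G = round((m_l - m_s) * beta)` synthetic samples, allocated across
#' its members by K-nearest-neighbor difficulty weights
#' ([density_ratios()]) with largest-remainder rounding
#' ([allocate_counts()]) and generated by same-class interpolation
#' ([synthesize()]).  Neighbor searches use Euclidean distance on
#' features standardized to zero mean and unit variance (computed from
#' the input table); synthesis happens in the original feature space.
#' Original rows are returned unchanged, followed by the synthetic rows.
#'
#' @param X numeric feature matrix (or data.frame of numeric columns).
#' @param y integer class labels.
#' @param beta balance level in `(0, 1]` (default 1: full balancing).
#' @param K neighbor count (default 5).
#' @param d_threshold generate for classes with imbalance ratio below
#'   this (default 1: all non-majority classes).
#' @param seed RNG seed making the output deterministic.
#' @return list with `X` (matrix), `y` (labels) and `synthetic` (logical
#'   flag per row).
#' @examples
#' d <- make_tabular_dataset(n_per_class = c(20, 6, 4), n_informative = 2,
#'                           n_noise = 1, class_sep = 3, seed = 1)
#' b <- adasyn(d$X, d$y, seed = 1)
#' table(b$y)
#' @export
adasyn <- function(X, y, beta = 1, K = 5L, d_threshold = 1, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("'X' and 'y' sizes differ")
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least two classes")
  m_l <- max(counts)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  set.seed(seed)
  new_X <- list(); new_y <- list()
  for (cls in names(counts)) {
    m_s <- as.integer(counts[[cls]])
    if (m_s == m_l) next
    if (imbalance_ratio(m_s, m_l) >= d_threshold) next
    G <- n_to_generate(m_l, m_s, beta)
    if (G == 0L) next
    lab <- if (is.numeric(y)) as.numeric(cls) else cls
    r <- density_ratios(Xs, y, lab, K = min(K, nrow(X) - 1L))
    g <- allocate_counts(r, G)
    s <- synthesize(X, y, lab, g, K = K, Xs = Xs)
    new_X[[cls]] <- s
    new_y[[cls]] <- rep(lab, nrow(s))
  }
  Xout <- rbind(X, do.call(rbind, new_X))
  yout <- c(y, unlist(new_y, use.names = FALSE))
  list(X = Xout, y = yout,
       synthetic = c(rep(FALSE, nrow(X)),
                     rep(TRUE, nrow(Xout) - nrow(X))))
}
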