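#' Normalized attribute difference
#'
#' `|x1 - x2| / range` for a numeric attribute, where `range` is the
#' max-min spread of that attribute over the dataset; 0 by convention
#' when the range is 0 (constant feature).  This is the elementary
#' quantity both the ReliefF weight updates and its neighbor distances
#' are built from.
#'
#' @param x1,x2 attribute values (vectorized).
#' @param range attribute range (scalar or vector).
#' @return values in `[0, 1]`.
#' @export
relief_diff <- function(x1, x2, range) {
  ifelse(range > 0, abs(x1 - x2) / range, 0)
}

#' ReliefF feature weights
#'
#' Estimates the relevance `W[A]` of every feature by contrasting each
#' instance `T` with its `k` nearest hits (same class) and, for every
#' other class `C`, its `k` nearest misses, using the range-normalized
#' attribute difference [relief_diff()] and Manhattan distance over those
#' differences for the neighbor search.  The update over `m` instances is
#'
#' `W[A] <- W[A] - sum_hits diff / (m k)
#'             + sum_C P(C)/(1 - P(class(T))) sum_missesC diff / (m k)`
#'
#' with empirical class priors `P`.  Weights lie in `[-1, 1]`: positive
#' for features that separate classes locally, near zero for irrelevant
#' ones.  By default all instances are visited in index order, which
#' makes the result deterministic without a seed; `m` smaller than `n`
#' gives the classical seeded random subsample.
#'
#' @param X numeric feature matrix or data.frame.
#' @param y class labels.
#' @param k neighbors per class (default 3); truncated (with a message)
#'   for classes with fewer than `k + 1` members.
#' @param m number of instances to visit: `"all"` (default) or an
#'   integer.
#' @param seed RNG seed, used only when `m < n`.
#' @return object of class `relieff`: list with `weights` (named,
#'   length p), `ranking` (feature indices by decreasing weight, ties to
#'   the lower index), `k`, `m`.
#' @export
relieff_weights <- function(X, y, k = 3L, m = "all", seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("'X' and 'y' sizes differ")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes")
  rng <- apply(X, 2L, function(col) diff(range(col)))
  Xn <- sweep(X, 2L, ifelse(rng > 0, rng, 1), "/")
  Xn[, rng == 0] <- 0
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  names(priors) <- as.character(classes)
  if (any(table(y) < k + 1L))
    message("some classes have fewer than k + 1 members; ",
            "k is truncated for them")
  idx <- if (identical(m, "all") || m >= n) {
    seq_len(n)
  } else {
    set.seed(seed)
    sample.int(n, m)
  }
  m_used <- length(idx)
  W <- numeric(p)
  by_class <- split(seq_len(n), y)
  for (t in idx) {
    dt <- colSums(abs(t(Xn) - Xn[t, ]))   # Manhattan over diffs
    cls <- as.character(y[t])
    for (cname in names(by_class)) {
      members <- setdiff(by_class[[cname]], t)
      if (length(members) == 0L) next
      kk <- min(k, length(members))
      near <- members[order(dt[members], members)[seq_len(kk)]]
      contrib <- colSums(abs(Xn[near, , drop = FALSE] -
                               matrix(Xn[t, ], kk, p, byrow = TRUE))) /
        (m_used * kk)
      if (cname == cls) {
        W <- W - contrib
      } else {
        wgt <- priors[[cname]] / (1 - priors[[cls]])
        W <- W + wgt * contrib
      }
    }
  }
  names(W) <- colnames(X)
  structure(list(weights = W,
                 ranking = order(-W, seq_along(W)),
                 k = k, m = m_used),
            class = "relieff")
}

#' @export
print.relieff <- function(x, ...) {
  cat(sprintf("<relieff weights: %d features, k = %d, m = %d>\n",
              length(x$weights), x$k, x$m))
  top <- utils::head(x$ranking, 10L)
  lab <- if (is.null(names(x$weights))) top else names(x$weights)[top]
  cat("top features:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' Keep the highest-weighted features
#'
#' @param weights a [relieff_weights()] result (or bare numeric vector).
#' @param n_select how many features to keep.
#' @return integer vector: the first `n_select` entries of the ranking
#'   (descending weight, ties broken toward the lower index).
#' @export
select_top <- function(weights, n_select = 10L) {
  rk <- if (inherits(weights, "relieff")) weights$ranking
        else order(-weights, seq_along(weights))
  if (n_select > length(rk)) stop("'n_select' exceeds feature count")
  rk[seq_len(n_select)]
}

#' Cross-validated accuracy as a function of feature count
#'
#' For each `n` in `ns`, evaluates a classifier on the top-`n` features
#' of the ranking by stratified k-fold cross-validation.  The default
#' classifier is 1-nearest-neighbor (`class::knn`); any factory returning
#' a `function(X_train, y_train, X_test) -> predicted labels` can be
#' supplied (for instance one wrapping [lm_mlp()]).
#'
#' @param X feature matrix.
#' @param y labels.
#' @param weights a [relieff_weights()] result.
#' @param ns ascending feature counts to evaluate.
#' @param classifier factory as described above; default 1-NN.
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @return data.frame with columns `n_features` and `accuracy`.
#' @export
weight_curve <- function(X, y, weights, ns = c(5L, 10L, 20L, 40L, 88L),
                         classifier = NULL, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  ns <- sort(unique(pmin(as.integer(ns), ncol(X))))
  if (is.null(classifier)) {
    if (!requireNamespace("class", quietly = TRUE))
      stop("default classifier needs the 'class' package")
    classifier <- function(Xtr, ytr, Xte)
      as.character(class::knn(Xtr, Xte, factor(ytr), k = 1L))
  }
  set.seed(seed)
  fold <- unlist(lapply(split(seq_along(y), y), function(ix)
    stats::setNames(sample(rep_len(seq_len(folds), length(ix))), ix)))
  fold <- fold[order(as.integer(names(fold)))]
  acc <- vapply(ns, function(nf) {
    keep <- select_top(weights, nf)
    hits <- 0L
    for (f in seq_len(folds)) {
      te <- which(fold == f)
      if (length(te) == 0L) next
      pred <- classifier(X[-te, keep, drop = FALSE], y[-te],
                         X[te, keep, drop = FALSE])
      hits <- hits + sum(as.character(pred) == as.character(y[te]))
    }
    hits / length(y)
  }, numeric(1L))
  data.frame(n_features = ns, accuracy = acc)
}
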