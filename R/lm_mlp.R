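#' Feedforward network trained by Levenberg-Marquardt
#'
#' Fits a multilayer perceptron for multiclass classification.  The
#' default architecture follows the pipeline's reference design: three
#' hidden layers of 40, 20 and 10 tanh units and a softmax output layer
#' with one unit per class.  Training minimizes the sum of squared
#' residuals `e = target - output` over one-hot targets with the damped
#' Gauss-Newton (Levenberg-Marquardt) iteration
#' `(J'J + mu I) dw = J'e`, `w <- w - dw`, where `J` is the Jacobian of
#' the residuals with respect to all weights and biases: accepted steps
#' (lower error) shrink the damping `mu`, rejected ones grow it.
#' Multinomial cross-entropy is computed and recorded per epoch as a
#' monitoring metric.  Data are split into stratified training,
#' validation and test subsets; training stops at `max_epochs`, on
#' damping overflow, on a small gradient, or after `val_patience`
#' consecutive validation-error increases.
#'
#' @param x numeric feature matrix, or a model formula.
#' @param y class labels (factor or integer); one output unit per level.
#' @param hidden hidden layer sizes (default `c(40, 20, 10)`).
#' @param layer1_linear use an identity activation in the first hidden
#'   layer instead of tanh (default `FALSE`).
#' @param standardize center/scale inputs by training-split statistics
#'   (default `TRUE`).
#' @param split named or unnamed fractions `(train, val, test)` summing
#'   to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param mu0,mu_inc,mu_dec,mu_max initial damping, its growth and decay
#'   factors, and the overflow bound (defaults 1e-3, 10, 0.1, 1e10).
#' @param max_epochs maximum number of accepted iterations (default 100).
#' @param val_patience consecutive validation-error increases tolerated
#'   before stopping (default 6).
#' @param grad_tol stop when the gradient norm `|J'e|` falls below this
#'   (default 1e-7).
#' @param seed RNG seed for the split and weight initialization.
#' @param trace print per-epoch progress (default `FALSE`).
#' @param data,formula for the formula method: a data frame holding the
#'   model variables.
#' @param ... passed between methods.
#' @return an object of class `lm_mlp` with weights, the class levels,
#'   split indices, per-epoch `history`, and fitted probabilities;
#'   supports `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals` and `simulate`.
#' @examples
#' d <- make_tabular_dataset(n_per_class = c(30, 30), n_informative = 2,
#'                           n_noise = 2, class_sep = 4, seed = 1)
#' fit <- lm_mlp(d$X, d$y, hidden = c(8), max_epochs = 30, seed = 1)
#' mean(predict(fit) == d$y)
#' @export
lm_mlp <- function(x, ...) UseMethod("lm_mlp")

#' @rdname lm_mlp
#' @export
lm_mlp.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- lm_mlp.default(x, y, ...)
  fit$terms <- attr(mf, "terms")
  fit$call <- match.call()
  fit
}

#' @rdname lm_mlp
#' @export
lm_mlp.default <- function(x, y, hidden = c(40L, 20L, 10L),
                           layer1_linear = FALSE, standardize = TRUE,
                           split = c(train = 0.6, val = 0.2, test = 0.2),
                           mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1,
                           mu_max = 1e10, max_epochs = 100L,
                           val_patience = 6L, grad_tol = 1e-7,
                           seed = 1L, trace = FALSE, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) stop("'x' and 'y' sizes differ")
  if (abs(sum(split) - 1) > 1e-8) stop("'split' fractions must sum to 1")
  yf <- factor(y)
  lev <- levels(yf)
  K <- length(lev)
  if (K < 2L) stop("need at least two classes")
  Y <- diag(K)[as.integer(yf), , drop = FALSE]

  set.seed(seed)
  part <- mlp_split(yf, split)
  tr <- part == "train"; va <- part == "val"
  if (!any(tr)) stop("empty training split")
  if (standardize) {
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  Xs <- scale(x, center = ctr, scale = scl)
  spec <- list(sizes = c(ncol(x), hidden, K),
               layer1_linear = layer1_linear)
  net <- mlp_init(spec)

  Xtr <- Xs[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
  Xva <- Xs[va, , drop = FALSE]; Yva <- Y[va, , drop = FALSE]
  n_tr <- nrow(Xtr)
  mu <- mu0
  theta <- mlp_flatten(net)
  je <- mlp_jacobian(net, Xtr, Ytr)
  sse <- sum(je$e^2)
  hist_rows <- list()
  best_val <- Inf; bad_val <- 0L
  stop_reason <- "max_epochs"
  for (epoch in seq_len(max_epochs)) {
    JtJ <- crossprod(je$J)
    Jte <- crossprod(je$J, je$e)
    gnorm <- sqrt(sum(Jte^2))
    if (gnorm < grad_tol) { stop_reason <- "gradient"; break }
    accepted <- FALSE
    while (mu <= mu_max) {
      dw <- tryCatch(
        solve_damped(JtJ, Jte, mu),
        error = function(e) NULL)
      if (!is.null(dw)) {
        cand <- mlp_unflatten(theta - dw, spec)
        e_new <- mlp_residuals(cand, Xtr, Ytr)
        sse_new <- sum(e_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          net <- cand
          theta <- theta - dw
          sse <- sse_new
          mu <- max(mu * mu_dec, .Machine$double.xmin)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * mu_inc
    }
    if (!accepted) { stop_reason <- "mu_overflow"; break }
    je <- mlp_jacobian(net, Xtr, Ytr)
    ptr <- mlp_forward(net, Xtr)
    ce <- -mean(rowSums(Ytr * log(pmax(ptr, 1e-12))))
    val_mse <- if (nrow(Xva) > 0L) {
      ev <- mlp_residuals(net, Xva, Yva)
      mean(ev^2)
    } else NA_real_
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, mse_train = sse / (n_tr * K), mse_val = val_mse,
      cross_entropy = ce, mu = mu, grad_norm = gnorm)
    if (trace)
      cat(sprintf("epoch %3d  mse %.3e  val %.3e  mu %.1e\n",
                  epoch, sse / (n_tr * K), val_mse, mu))
    if (!is.na(val_mse)) {
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse; bad_val <- 0L
      } else {
        bad_val <- bad_val + 1L
        if (bad_val >= val_patience) { stop_reason <- "val_patience"; break }
      }
    }
  }
  history <- if (length(hist_rows)) do.call(rbind, hist_rows) else
    data.frame(epoch = integer(), mse_train = numeric(),
               mse_val = numeric(), cross_entropy = numeric(),
               mu = numeric(), grad_norm = numeric())
  probs <- mlp_forward(net, Xs)
  fit <- structure(list(
    net = net, spec = spec, levels = lev, center = ctr, scale = scl,
    split = part, history = history, stop_reason = stop_reason,
    fitted_prob = probs, y = yf, seed = seed,
    config = list(mu0 = mu0, mu_inc = mu_inc, mu_dec = mu_dec,
                  mu_max = mu_max, max_epochs = max_epochs,
                  val_patience = val_patience, grad_tol = grad_tol),
    call = match.call()), class = "lm_mlp")
  fit
}

# stratified (train, val, test) partition; proportions preserved per class
mlp_split <- function(yf, fractions) {
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  part <- character(length(yf))
  for (ix in split(seq_along(yf), yf)) {
    n <- length(ix)
    n_tr <- round(fractions[["train"]] * n)
    n_va <- round(fractions[["val"]] * n)
    if (n_tr == 0L && n > 0L) n_tr <- 1L
    sh <- sample(ix)
    part[sh[seq_len(n_tr)]] <- "train"
    if (n_va > 0L && n_tr < n)
      part[sh[(n_tr + 1L):min(n, n_tr + n_va)]] <- "val"
    rest <- sh[part[sh] == ""]
    part[rest] <- "test"
  }
  factor(part, levels = c("train", "val", "test"))
}

# Nguyen-Widrow-style scaled uniform init; biases zero
mlp_init <- function(spec) {
  sizes <- spec$sizes
  L <- length(sizes) - 1L
  net <- lapply(seq_len(L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    W <- matrix(stats::runif(fan_out * fan_in, -1, 1), fan_out, fan_in)
    target <- 0.7 * fan_out^(1 / fan_in)
    nrm <- sqrt(rowSums(W^2))
    W <- W * target / ifelse(nrm > 0, nrm, 1)
    list(W = W, b = numeric(fan_out))
  })
  attr(net, "layer1_linear") <- isTRUE(spec$layer1_linear)
  net
}

mlp_flatten <- function(net)
  unlist(lapply(net, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)

mlp_unflatten <- function(theta, spec) {
  sizes <- spec$sizes
  net <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_along(net)) {
    nw <- sizes[l + 1L] * sizes[l]
    W <- matrix(theta[pos + seq_len(nw)], sizes[l + 1L], sizes[l])
    pos <- pos + nw
    b <- theta[pos + seq_len(sizes[l + 1L])]
    pos <- pos + sizes[l + 1L]
    net[[l]] <- list(W = W, b = b)
  }
  attr(net, "layer1_linear") <- isTRUE(spec$layer1_linear)
  net
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# forward pass; returns output probabilities, or all layer activations
mlp_forward <- function(net, X, all = FALSE) {
  L <- length(net)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  a <- X
  for (l in seq_len(L)) {
    z <- a %*% t(net[[l]]$W) +
      matrix(net[[l]]$b, nrow(a), length(net[[l]]$b), byrow = TRUE)
    a <- if (l == L) {
      softmax_rows(z)
    } else if (l == 1L && isTRUE(attr(net, "layer1_linear"))) {
      z
    } else {
      tanh(z)
    }
    acts[[l + 1L]] <- a
  }
  if (all) acts else a
}

mlp_residuals <- function(net, X, Y) as.vector(Y - mlp_forward(net, X))

# Jacobian of the residuals e = vec(Y - P) w.r.t. all weights and biases.
# Rows are ordered output-block-major (all samples for output 1, then
# output 2, ...), matching the column-major vectorization of Y - P.
mlp_jacobian <- function(net, X, Y) {
  L <- length(net)
  acts <- mlp_forward(net, X, all = TRUE)
  P <- acts[[L + 1L]]
  n <- nrow(X); K <- ncol(P)
  npar <- sum(vapply(net, function(l) length(l$W) + length(l$b),
                     numeric(1L)))
  J <- matrix(0, n * K, npar)
  for (k in seq_len(K)) {
    # d p_k / d z_out = p_k (delta_k - p)  (softmax rows)
    delta <- -P * P[, k]
    delta[, k] <- delta[, k] + P[, k]
    # de_k/dtheta = -dp_k/dtheta: propagate the negated seed backwards
    g <- -delta
    pos <- npar
    for (l in L:1) {
      a_prev <- acts[[l]]
      sl <- ncol(g); sp <- ncol(a_prev)
      # per-sample gradient blocks: vec(W_l) then b_l
      blk_w <- g[, rep(seq_len(sl), times = sp), drop = FALSE] *
        a_prev[, rep(seq_len(sp), each = sl), drop = FALSE]
      cols <- (pos - sl - sl * sp + 1L):pos
      J[(k - 1L) * n + seq_len(n), cols] <- cbind(blk_w, g)
      pos <- pos - sl - sl * sp
      if (l > 1L) {
        g <- g %*% net[[l]]$W
        if (!(l - 1L == 1L && isTRUE(attr(net, "layer1_linear"))))
          g <- g * (1 - acts[[l]]^2)
      }
    }
  }
  list(J = J, e = as.vector(Y - P))
}

#' One Levenberg-Marquardt parameter update
#'
#' Solves the damped normal equations `(J'J + mu I) dw = J'e` by a
#' symmetric positive-definite (Cholesky) solve.  As `mu` grows the
#' update tends to the scaled gradient `J'e / mu`; at `mu = 0` it is the
#' Gauss-Newton step.  A singular system raises an error — callers
#' increase `mu` and retry, as the training loop does.
#'
#' @param J residual Jacobian (`n_residuals` x `n_parameters`).
#' @param e residual vector.
#' @param mu nonnegative damping.
#' @return the update vector `dw`.
#' @export
lm_step <- function(J, e, mu) {
  if (mu < 0) stop("'mu' must be nonnegative")
  solve_damped(crossprod(J), crossprod(J, e), mu)
}

solve_damped <- function(JtJ, Jte, mu) {
  A <- JtJ
  diag(A) <- diag(A) + mu
  ch <- chol(A)
  as.vector(backsolve(ch, forwardsolve(t(ch), Jte)))
}

#' @export
predict.lm_mlp <- function(object, newdata = NULL,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- if (is.null(newdata)) {
    object$fitted_prob
  } else {
    x <- if (!is.null(object$terms) && is.data.frame(newdata)) {
      mm <- stats::model.matrix(stats::delete.response(object$terms),
                                newdata)
      mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    } else {
      as.matrix(newdata)
    }
    xs <- scale(x, center = object$center, scale = object$scale)
    mlp_forward(object$net, xs)
  }
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  lab <- object$levels[max.col(p, ties.method = "first")]
  if (!anyNA(suppressWarnings(as.integer(object$levels))))
    lab <- as.integer(lab)
  lab
}

#' @export
print.lm_mlp <- function(x, ...) {
  cat("Feedforward network trained by Levenberg-Marquardt\n")
  cat(sprintf("architecture: %s (tanh hidden, softmax output)\n",
              paste(x$spec$sizes, collapse = "-")))
  cat(sprintf("classes: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("epochs run: %d, stopped on: %s\n",
              nrow(x$history), x$stop_reason))
  if (nrow(x$history))
    cat(sprintf("final training mse: %.4g\n",
                x$history$mse_train[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.lm_mlp <- function(object, ...) {
  pred <- predict(object)
  acc <- vapply(levels(object$split), function(s) {
    ix <- object$split == s
    if (!any(ix)) return(NA_real_)
    mean(as.character(pred[ix]) == as.character(object$y[ix]))
  }, numeric(1L))
  structure(list(fit = object, accuracy = acc,
                 n_parameters = length(mlp_flatten(object$net))),
            class = "summary.lm_mlp")
}

#' @export
print.summary.lm_mlp <- function(x, ...) {
  print(x$fit)
  cat(sprintf("parameters: %d\n", x$n_parameters))
  cat("accuracy by split:\n")
  print(round(x$accuracy, 4))
  invisible(x)
}

#' @export
coef.lm_mlp <- function(object, ...) {
  nm <- unlist(lapply(seq_along(object$net), function(l) {
    d <- dim(object$net[[l]]$W)
    c(sprintf("W%d[%d,%d]", l, rep(seq_len(d[1L]), d[2L]),
              rep(seq_len(d[2L]), each = d[1L])),
      sprintf("b%d[%d]", l, seq_len(d[1L])))
  }))
  stats::setNames(mlp_flatten(object$net), nm)
}

#' @export
residuals.lm_mlp <- function(object, ...) {
  K <- length(object$levels)
  Y <- diag(K)[as.integer(object$y), , drop = FALSE]
  r <- Y - object$fitted_prob
  colnames(r) <- object$levels
  r
}

#' @export
plot.lm_mlp <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$epoch, cbind(h$mse_train, h$mse_val), type = "l",
                    lty = 1, col = c("black", "red"), log = "y",
                    xlab = "epoch", ylab = "mse", ...)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
simulate.lm_mlp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted_prob
  out <- replicate(nsim, apply(p, 1L, function(pr)
    sample(object$levels, 1L, prob = pr)))
  as.data.frame(out)
}
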