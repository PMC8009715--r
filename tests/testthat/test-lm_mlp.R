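test_that("the residual Jacobian matches central finite differences", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(15), 5, 3)
    Y <- diag(2)[sample(1:2, 5, TRUE), ]
    spec <- list(sizes = c(3L, 4L, 2L), layer1_linear = FALSE)
    net <- mammotex:::mlp_init(spec)
    je <- mammotex:::mlp_jacobian(net, X, Y)
    expect_equal(dim(je$J), c(5L * 2L, 4L * 3L + 4L + 2L * 4L + 2L))
    expect_lt(max(abs(je$J - fd_jacobian(net, spec, X, Y))), 1e-5)
  }
})

test_that("forward outputs are row-normalized probabilities", {
  set.seed(1)
  spec <- list(sizes = c(3L, 5L, 4L), layer1_linear = FALSE)
  net <- mammotex:::mlp_init(spec)
  X <- matrix(rnorm(30), 10, 3)
  P <- mammotex:::mlp_forward(net, X)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-9)
  expect_true(all(P > 0 & P < 1))
  # all-zero weights give uniform class probabilities
  zero <- mammotex:::mlp_unflatten(rep(0, 3 * 5 + 5 + 5 * 4 + 4), spec)
  expect_equal(unname(mammotex:::mlp_forward(zero, X)),
               matrix(0.25, 10, 4))
  # batched and single-row forward agree
  expect_equal(mammotex:::mlp_forward(net, X[3, , drop = FALSE]),
               P[3, , drop = FALSE])
})

test_that("the damped step solves the normal equations and limits to gradient descent", {
  expect_equal(lm_step(diag(4), c(1, 2, 3, 4), 0), c(1, 2, 3, 4))
  expect_equal(lm_step(diag(4), c(1, 2, 3, 4), 1), c(1, 2, 3, 4) / 2)
  set.seed(9)
  J <- matrix(rnorm(140), 20, 7)
  e <- rnorm(20)
  dw <- lm_step(J, e, 0.5)
  expect_lt(max(abs((crossprod(J) + 0.5 * diag(7)) %*% dw -
                      crossprod(J, e))), 1e-8)
  big <- lm_step(J, e, 1e12)
  expect_equal(big, as.vector(crossprod(J, e)) / 1e12, tolerance = 1e-6)
})

test_that("one undamped step solves a linear least-squares problem exactly", {
  # residual e = t - J w is linear in w: a single Gauss-Newton step from
  # w0 must land on the least-squares optimum
  set.seed(3)
  A <- matrix(rnorm(60), 20, 3)
  t <- rnorm(20)
  w0 <- rnorm(3)
  e0 <- t - A %*% w0
  dw <- lm_step(-A, e0, 0)          # de/dw = -A
  w1 <- w0 - dw
  expect_equal(w1, unname(stats::coef(stats::lm(t ~ A - 1))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the stratified split preserves class proportions", {
  y <- factor(rep(1:3, c(100, 40, 10)))
  set.seed(1)
  part <- mammotex:::mlp_split(y, c(train = 0.6, val = 0.2, test = 0.2))
  for (cls in levels(y)) {
    n <- sum(y == cls)
    expect_lte(abs(sum(part == "train" & y == cls) - 0.6 * n), 1)
    expect_lte(abs(sum(part == "val" & y == cls) - 0.2 * n), 1)
  }
})

test_that("training separates Gaussian blobs and is reproducible", {
  d <- make_tabular_dataset(n_per_class = c(20, 20), n_informative = 2,
                            n_noise = 0, class_sep = 4, seed = 1)
  fit <- lm_mlp(d$X, d$y, hidden = c(5L), max_epochs = 50L, seed = 1)
  tr <- fit$split == "train"
  expect_equal(mean(predict(fit)[tr] == d$y[tr]), 1)
  expect_lte(nrow(fit$history), 50L)
  # accepted-step training error is nonincreasing
  expect_true(all(diff(fit$history$mse_train) < 1e-15))

  fit2 <- lm_mlp(d$X, d$y, hidden = c(5L), max_epochs = 50L, seed = 1)
  expect_identical(coef(fit), coef(fit2))
  expect_false(identical(
    coef(lm_mlp(d$X, d$y, hidden = c(5L), max_epochs = 2L, seed = 2)),
    coef(lm_mlp(d$X, d$y, hidden = c(5L), max_epochs = 2L, seed = 3))))
})

test_that("model methods expose the classic interface", {
  d <- make_tabular_dataset(n_per_class = c(15, 15), n_informative = 2,
                            n_noise = 1, class_sep = 3, seed = 2)
  df <- data.frame(d$X, y = factor(d$y))
  fit <- lm_mlp(y ~ ., data = df, hidden = c(4L), max_epochs = 20L,
                seed = 1)
  expect_s3_class(fit, "lm_mlp")
  p <- predict(fit, df, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 30), tolerance = 1e-9)
  expect_true(all(predict(fit, df) %in% levels(factor(d$y))))
  expect_equal(dim(residuals(fit)), c(30L, 2L))
  expect_named(summary(fit)$accuracy, c("train", "val", "test"))
  expect_true(is.numeric(coef(fit)))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(30L, 2L))
  # argmax ties resolve to the lowest class index
  fit$fitted_prob <- matrix(0.5, 2, 2)
  expect_equal(predict(fit), c(1L, 1L))
})
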