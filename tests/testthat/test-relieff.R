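test_that("attribute differences are range-normalized with the zero-range convention", {
  expect_equal(relief_diff(3, 3, 10), 0)
  expect_equal(relief_diff(0, 10, 10), 1)
  expect_equal(relief_diff(1, 5, 0), 0)
})

test_that("weights reproduce the hand-derived two-class toy exactly", {
  X <- matrix(c(0, 0, 1, 1, 0.2, 0.8, 0.3, 0.7), 4, 2)
  w <- relieff_weights(X, c(1, 1, 2, 2), k = 1L)
  expect_equal(unname(w$weights), c(1, -2 / 3), tolerance = 1e-10)
  expect_equal(w$ranking, c(1L, 2L))

  # duplicating every instance leaves the ranking unchanged
  w2 <- relieff_weights(rbind(X, X), rep(c(1, 1, 2, 2), 2), k = 1L)
  expect_equal(w2$ranking, w$ranking)
})

test_that("constant features weigh zero and weights stay within [-1, 1]", {
  d <- make_tabular_dataset(n_per_class = c(20, 20, 10), n_informative = 3,
                            n_noise = 2, class_sep = 2, seed = 1)
  X <- cbind(d$X, constant = 5)
  w <- relieff_weights(X, d$y)
  expect_equal(unname(w$weights[ncol(X)]), 0)
  expect_true(all(w$weights >= -1 & w$weights <= 1))
})

test_that("weights are invariant to rescaling a feature column", {
  d <- make_tabular_dataset(n_per_class = c(15, 15), n_informative = 2,
                            n_noise = 2, class_sep = 2, seed = 2)
  w1 <- relieff_weights(d$X, d$y)
  Xs <- d$X
  Xs[, 1] <- Xs[, 1] * 1000
  w2 <- relieff_weights(Xs, d$y)
  expect_equal(unname(w1$weights), unname(w2$weights), tolerance = 1e-10)
})

test_that("informative features outrank label-independent noise", {
  wins <- 0L
  for (seed in 1:20) {
    d <- make_tabular_dataset(n_per_class = c(25, 25, 15),
                              n_informative = 3, n_noise = 3,
                              class_sep = 3, seed = seed)
    w <- relieff_weights(d$X, d$y)
    if (min(w$weights[1:3]) > max(abs(w$weights[4:6]))) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("top-feature selection respects ranking and ties", {
  w <- structure(list(weights = c(a = 0.5, b = 0.5, c = 0.1),
                      ranking = c(1L, 2L, 3L), k = 3L, m = 10L),
                 class = "relieff")
  expect_equal(select_top(w, 2L), c(1L, 2L))
  expect_equal(select_top(c(0.2, 0.9, 0.2), 3L), c(2L, 1L, 3L))
  expect_error(select_top(w, 5L), "n_select")
})

test_that("the accuracy-versus-feature-count curve recovers the informative prefix", {
  d <- make_tabular_dataset(n_per_class = c(30, 30, 30), n_informative = 4,
                            n_noise = 8, class_sep = 4, seed = 3)
  w <- relieff_weights(d$X, d$y)
  curve <- weight_curve(d$X, d$y, w, ns = c(2L, 4L, 12L), seed = 1)
  expect_equal(curve$n_features, c(2L, 4L, 12L))
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  # with all informative features included accuracy is near-perfect
  expect_gte(curve$accuracy[2L], 0.9)
})
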