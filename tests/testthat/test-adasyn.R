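test_that("imbalance ratios and generation counts follow the definitions", {
  expect_equal(imbalance_ratio(67, 220), 67 / 220)
  expect_equal(imbalance_ratio(220, 220), 1)
  expect_equal(round(imbalance_ratio(13, 220), 5), 0.05909)
  expect_error(imbalance_ratio(5, 0), "majority")

  expect_equal(n_to_generate(220, 67, 1), 153L)
  expect_equal(n_to_generate(220, 220, 1), 0L)
  expect_equal(n_to_generate(220, 8, 1), 212L)
})

test_that("difficulty weights match a brute-force neighbor table", {
  X <- rbind(c(0, 0), c(10, 10), c(0, 1), c(1, 0), c(9, 9))
  y <- c(1, 1, 2, 2, 2)
  r <- density_ratios(X, y, 1, K = 2L)
  expect_equal(r, c(0.5, 0.5))  # both minority points: all 2 NN other-class

  set.seed(4)
  Xr <- matrix(rnorm(40), 20, 2)
  yr <- rep(c(1, 2), each = 10)
  rr <- density_ratios(Xr, yr, 1, K = 3L)
  raw <- vapply(which(yr == 1), function(i)
    mean(yr[knn_oracle(Xr, i, 3L)] != 1), numeric(1L))
  expect_equal(rr, raw / sum(raw))

  same <- density_ratios(rbind(Xr, Xr[yr == 1, ] + 100), c(yr, rep(1, 10)),
                         2, K = 3L)
  expect_true(all(same >= 0))
  expect_error(density_ratios(Xr, yr, 1, K = 25L), "K")
})

test_that("largest-remainder allocation conserves the total with stated ties", {
  expect_equal(allocate_counts(c(0.5, 0.5), 3L), c(2L, 1L))
  expect_equal(allocate_counts(c(0.3, 0.7), 0L), c(0L, 0L))
  for (seed in 1:5) {
    set.seed(seed)
    r <- stats::runif(7); r <- r / sum(r)
    g <- allocate_counts(r, 153L)
    expect_equal(sum(g), 153L)
    # harder samples (larger weight) never get fewer synthetics
    expect_true(all(diff(g[order(r)]) >= 0L))
  }
  g <- allocate_counts(c(0.1, 0.2, 0.3, 0.4), 10L)
  expect_true(all(diff(g) >= 0L))
  expect_equal(sum(g), 10L)
})

test_that("synthetic samples are convex combinations of same-class originals", {
  d <- make_tabular_dataset(n_per_class = c(30, 10), n_informative = 3,
                            n_noise = 2, class_sep = 2, seed = 2)
  out <- adasyn(d$X, d$y, seed = 7)
  syn <- out$X[out$synthetic, , drop = FALSE]
  orig <- d$X[d$y == 2, , drop = FALSE]
  for (i in seq_len(nrow(syn)))
    expect_true(all(syn[i, ] >= apply(orig, 2, min) - 1e-9 &
                    syn[i, ] <= apply(orig, 2, max) + 1e-9))
  expect_true(all(out$y[out$synthetic] == 2))
})

test_that("oversampling balances the reference class distribution deterministically", {
  d <- make_tabular_dataset(seed = 3, class_sep = 3)
  b <- adasyn(d$X, d$y, beta = 1, seed = 5)
  tab <- table(b$y)
  expect_equal(length(b$y), 1760L)
  expect_true(all(tab == 220L))
  # originals pass through unchanged, labels conserved
  expect_equal(unname(b$X[seq_len(411), ]), unname(d$X))
  expect_equal(b$y[seq_len(411)], d$y)

  b2 <- adasyn(d$X, d$y, beta = 1, seed = 5)
  expect_identical(b, b2)

  balanced <- list(X = matrix(rnorm(40), 20, 2), y = rep(1:2, each = 10))
  same <- adasyn(balanced$X, balanced$y, seed = 1)
  expect_equal(nrow(same$X), 20L)
  expect_error(adasyn(d$X, rep(1, 411), seed = 1), "two classes")
})
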