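test_that("the default texture dataset reproduces the reference class sizes", {
  specs <- texture_class_specs()
  expect_equal(sum(specs$n_images), 411L)
  expect_equal(specs$n_images, unname(birads_class_counts()))

  small <- texture_class_specs(counts = c(3L, 2L))
  d <- make_texture_dataset(small, size = 32L, seed = 1)
  expect_length(d$images, 5L)
  expect_equal(d$manifest$label, rep(1:2, c(3L, 2L)))
  expect_true(all(vapply(d$images, function(i) max(i$pixels) <= 255L,
                         logical(1L))))
})

test_that("generation is deterministic per seed, including written files", {
  small <- texture_class_specs(counts = c(2L, 2L))
  d1 <- make_texture_dataset(small, size = 32L, seed = 9)
  d2 <- make_texture_dataset(small, size = 32L, seed = 9)
  expect_identical(d1$images, d2$images)
  d3 <- make_texture_dataset(small, size = 32L, seed = 10)
  expect_false(identical(d1$images, d3$images))

  dir <- tempfile()
  make_texture_dataset(small, size = 32L, seed = 9, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- read_image(file.path(dir, "class1_img001.png"))
  expect_equal(img$pixels, d1$images[[1L]]$pixels)
})

test_that("correlation length separates classes through co-occurrence contrast", {
  rough <- texture_class_specs(counts = c(10L), correlation_length = 1,
                               contrast = 45, base_level = 128)
  smooth <- texture_class_specs(counts = c(10L), correlation_length = 8,
                                contrast = 45, base_level = 128)
  mean_contrast <- function(specs, seed) {
    d <- make_texture_dataset(specs, size = 64L, seed = seed)
    mean(vapply(d$images, function(im) {
      unname(glcm_features(glcm(quantize(im, 32L), c(0L, 1L)))["contrast"])
    }, numeric(1L)))
  }
  expect_gt(mean_contrast(rough, 1) / mean_contrast(smooth, 1), 2)
})

test_that("tabular separation behaves as designed at the extremes", {
  # no signal: 1-NN accuracy near chance
  d0 <- make_tabular_dataset(n_per_class = rep(40L, 4L), n_informative = 4,
                             n_noise = 4, class_sep = 0, seed = 1)
  w0 <- relieff_weights(d0$X, d0$y)
  acc0 <- weight_curve(d0$X, d0$y, w0, ns = 8L, seed = 1)$accuracy
  expect_lt(abs(acc0 - 0.25), 0.1)

  # strong signal: informative features dominate the ReliefF ranking
  hits <- 0L
  for (seed in 1:20) {
    d <- make_tabular_dataset(n_per_class = c(30L, 30L, 20L),
                              n_informative = 4, n_noise = 6,
                              class_sep = 3, seed = seed)
    w <- relieff_weights(d$X, d$y)
    if (all(select_top(w, 4L) %in% 1:4)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("pipeline accuracy is monotone-ish in class separation", {
  counts <- pmax(round(birads_class_counts() / 4), 2L)
  acc <- vapply(c(0, 1, 2, 4), function(sep) {
    mean(vapply(1:3, function(seed) {
      d <- make_tabular_dataset(n_per_class = counts, n_informative = 4L,
                                n_noise = 8L, class_sep = sep, seed = seed)
      rep <- suppressWarnings(suppressMessages(
        run_pipeline(X = d$X, y = d$y, n_select = 4L, hidden = c(8L),
                     max_epochs = 20L, seed = seed)))
      sum(diag(rep$confusion)) / sum(rep$confusion)
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(acc) >= -0.02))
})
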