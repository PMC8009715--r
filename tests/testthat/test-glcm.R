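test_that("quantization maps levels monotonically onto the target range", {
  img <- gray_image(matrix(c(0L, 64L, 128L, 192L), 2, 2), n_levels = 256L)
  expect_equal(sort(as.vector(quantize(img, 4)$pixels)), 0:3)

  full <- gray_image(matrix(0:255, 16, 16), n_levels = 256L)
  q <- quantize(full, 32)
  expect_equal(min(q$pixels), 0L)
  expect_equal(max(q$pixels), 31L)
  expect_true(all(diff(as.vector(q$pixels)[order(as.vector(full$pixels))])
                  >= 0))

  const <- gray_image(matrix(7L, 3, 3), n_levels = 256L)
  expect_true(all(quantize(const, 8)$pixels == 0L))
  expect_error(quantize(const, 1), "n_levels")
})

test_that("co-occurrence counts match hand enumeration and the brute-force oracle", {
  img <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE), 2)
  m <- glcm(img, c(0L, 1L))
  expect_equal(m$counts, matrix(c(0.5, 0, 0, 0.5), 2, 2))

  const <- gray_image(matrix(0L, 3, 3), n_levels = 2L)
  expect_equal(glcm(const, c(0L, 1L))$counts[1L, 1L], 1)

  for (seed in 1:4) {
    img <- random_image(8L, 4L, seed)
    for (off in glcm_offsets(1L)) {
      got <- glcm(img, off, symmetric = TRUE, normalized = FALSE)$counts
      want <- glcm_oracle(img, off, symmetric = TRUE)
      expect_equal(got, want)
    }
  }
  expect_error(glcm(random_image(4L), c(0L, 9L)), "offset")
})

test_that("normalized symmetric matrices sum to one and equal their transpose", {
  for (seed in 1:5) {
    img <- random_image(8L, 8L, seed)
    m <- glcm(img, c(-1L, 1L), symmetric = TRUE, normalized = TRUE)
    expect_equal(sum(m$counts), 1, tolerance = 1e-12)
    expect_equal(m$counts, t(m$counts), tolerance = 1e-12)
  }
})

test_that("co-occurrence statistics match closed forms on small matrices", {
  f <- glcm_features(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["entropy"]), 1.0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["max_probability"]), 0.5)

  g <- glcm_features(glcm(gray_image(matrix(3L, 3, 3), 4L), c(0L, 1L)))
  expect_equal(unname(g["energy"]), 1)
  expect_equal(unname(g["entropy"]), 0)
  expect_equal(unname(g["contrast"]), 0)

  expect_error(glcm_features(glcm(random_image(), c(0L, 1L),
                                  normalized = FALSE)),
               "normalized")
})

test_that("feature bounds hold on random normalized matrices", {
  for (seed in 1:10) {
    f <- glcm_features(glcm(random_image(8L, 6L, seed), c(0L, 1L)))
    expect_true(f["energy"] > 0 && f["energy"] <= 1)
    expect_true(f["homogeneity"] > 0 && f["homogeneity"] <= 1)
    expect_gte(f["entropy"], 0)
    expect_gte(f["contrast"], 0)
    expect_true(all(is.finite(f)))
    expect_length(f, 22L)
  }
})
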