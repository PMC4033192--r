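test_that("smooth_volume: constant fields are fixed points and FWHM maps to sigma", {
  v <- tiny_volume(0.5, c(6, 7, 5))
  s <- smooth_volume(v, 8)
  expect_identical(dim(s$data), dim(v$data))
  expect_equal(max(abs(s$data - 0.5)), 0)

  # FWHM = 2 sqrt(2 ln 2) sigma; 8 mm on a 4 mm grid -> 0.8493 voxels
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 4
  expect_equal(sigma, 0.8493218, tolerance = 1e-6)

  expect_error(smooth_volume(v, -1), "non-negative")
  expect_identical(smooth_volume(v, 0)$data, v$data)
})

test_that("smooth_volume matches a dense convolution oracle on an impulse and a random field", {
  d <- c(11, 11, 11)
  a <- array(0, d); a[6, 6, 6] <- 1
  v <- tiny_volume(a)
  sm <- smooth_volume(v, 8)
  oracle <- dense_gauss3_oracle(a, 8 / (2 * sqrt(2 * log(2))) / 4)
  expect_equal(sm$data, oracle, tolerance = 1e-12)

  set.seed(42)
  b <- array(runif(prod(d)), d)
  expect_equal(smooth_volume(tiny_volume(b), 8)$data,
               dense_gauss3_oracle(b, 8 / (2 * sqrt(2 * log(2))) / 4),
               tolerance = 1e-12)
})

test_that("smooth_volume preserves the mean of interior-supported signals", {
  d <- c(12, 12, 12)
  a <- array(0.2, d)
  a[5:8, 5:8, 5:8] <- 0.8   # support far from the boundary
  sm <- smooth_volume(tiny_volume(a), 6)
  expect_equal(mean(sm$data), mean(a), tolerance = 1e-6)
})

test_that("resample_to_grid pools blocks and handles trailing partials", {
  v <- tiny_volume((1:8) / 10, c(2, 2, 2))
  r <- resample_to_grid(v, 8)
  expect_equal(dim(r$data), c(1, 1, 1))
  expect_equal(r$data[1, 1, 1], mean((1:8) / 10))
  expect_equal(r$voxel_size_mm, 8)

  # identity at factor 1
  v2 <- random_volume(c(3, 4, 5))
  expect_equal(resample_to_grid(v2, 4)$data, v2$data)

  # constant volumes stay constant under any factor
  expect_equal(unique(as.vector(
    resample_to_grid(tiny_volume(0.7, c(6, 4, 4)), 8)$data)), 0.7)

  # 3x2x2 with factor 2: second block = mean of the trailing slab
  a <- array(seq(0.01, 0.12, by = 0.01), c(3, 2, 2))
  r3 <- resample_to_grid(tiny_volume(a), 8)
  expect_equal(dim(r3$data), c(2, 1, 1))
  expect_equal(r3$data[1, 1, 1], mean(a[1:2, , ]))
  expect_equal(r3$data[2, 1, 1], mean(a[3, , ]))

  expect_error(resample_to_grid(v2, 6), "integer multiple")
})

test_that("resample_to_grid matches brute-force block enumeration on random input", {
  v <- random_volume(c(7, 6, 5), seed = 3)
  r <- resample_to_grid(v, 8)
  f <- 2L
  d <- dim(v$data)
  for (i in seq_len(dim(r$data)[1])) for (j in seq_len(dim(r$data)[2]))
    for (k in seq_len(dim(r$data)[3])) {
      ix <- ((i - 1) * f + 1):min(i * f, d[1])
      jx <- ((j - 1) * f + 1):min(j * f, d[2])
      kx <- ((k - 1) * f + 1):min(k * f, d[3])
      expect_equal(r$data[i, j, k], mean(v$data[ix, jx, kx]))
    }
})

test_that("build_mask thresholds the training mean GM", {
  v1 <- tiny_volume(0.5, c(3, 3, 3)); v2 <- tiny_volume(0.5, c(3, 3, 3))
  m <- build_mask(list(v1, v2), 0.1)
  expect_true(all(m$flags)); expect_equal(m$n_active, 27)

  a <- array(0.5, c(3, 3, 3)); a[2, 2, 2] <- 0
  m2 <- build_mask(list(tiny_volume(a), tiny_volume(a)), 0.1)
  expect_false(m2$flags[2, 2, 2])
  expect_equal(m2$n_active, 26)

  # elementwise oracle on random volumes
  vols <- lapply(1:4, function(s) random_volume(c(4, 4, 4), seed = s))
  m3 <- build_mask(vols, 0.4)
  mu <- Reduce(`+`, lapply(vols, `[[`, "data")) / 4
  expect_identical(m3$flags, mu > 0.4)

  expect_error(build_mask(list(), 0.1), "non-empty")
  expect_error(build_mask(list(tiny_volume(0, c(2, 2, 2))), 0.5),
               "degenerate mask")
})

test_that("vectorize and scatter_to_volume are mutually inverse", {
  a <- array(c(0.2, 0.4), c(2, 1, 1))
  m <- voxel_mask(array(TRUE, c(2, 1, 1)))
  fm <- vectorize(list(tiny_volume(a)), m)
  expect_equal(unname(fm[1, ]), c(0.2, 0.4))
  expect_identical(attr(fm, "subject_order"), "t")

  v <- random_volume(c(4, 5, 3), seed = 9)
  mask <- build_mask(list(v), 0.3)
  fm2 <- vectorize(list(v), mask)
  expect_equal(ncol(fm2), mask$n_active)
  back <- scatter_to_volume(fm2[1, ], mask, 4)
  expect_equal(back$data[mask$flags], v$data[mask$flags])
  expect_true(all(back$data[!mask$flags] == 0))

  bad <- random_volume(c(3, 3, 3))
  expect_error(vectorize(list(bad), mask), "does not match")
})
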