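test_that("forward projection is linear and zero on the zero image", {
  for (preset in c("parallel_default", "fan_default")) {
    g <- geom_preset(preset, n = 32, n_views = 12)
    z <- forward_project(ct_image(matrix(0, 32, 32), g$pixel_size), g)
    expect_true(all(z$values == 0))
    u <- ct_image(matrix(rnorm(32 * 32), 32), g$pixel_size)
    w <- ct_image(matrix(rnorm(32 * 32), 32), g$pixel_size)
    expect_equal(forward_project(ct_image(2 * u$values + w$values, g$pixel_size), g)$values,
                 2 * forward_project(u, g)$values + forward_project(w, g)$values,
                 tolerance = 1e-12)
  }
})

test_that("central-ray integral of a uniform disk matches the analytic chord", {
  g <- geom_preset("parallel_default", n = 128, n_views = 4)
  ph <- make_phantom("disk", 128, g$pixel_size, seed = 1)
  img <- ct_image(0.02 * (ph$label_map == 1L), g$pixel_size)
  s <- forward_project(img, g)$values
  r_mm <- 0.38 * 128 * g$pixel_size
  expect_equal(max(s[1, ]), 2 * r_mm * 0.02, tolerance = 0.02)
})

test_that("back projection is the exact transpose of forward projection", {
  set.seed(11)
  for (preset in c("parallel_default", "fan_default")) {
    g <- geom_preset(preset, n = 16, n_views = 12)
    for (rep in 1:100) {
      u <- matrix(rnorm(16 * 16), 16)
      y <- matrix(rnorm(12 * g$n_det), 12)
      Fu <- forward_project(ct_image(u, g$pixel_size), g)$values
      Fty <- back_project(ct_sinogram(y, g$angles, g$det_spacing, g$beam_type), g)$values
      rel <- abs(sum(Fu * y) - sum(u * Fty)) /
        max(sqrt(sum(Fu^2)) * sqrt(sum(y^2)), .Machine$double.eps)
      expect_lt(rel, 1e-6)
    }
  }
})

test_that("a single detector bin backprojects to one nonnegative ray footprint", {
  g <- tiny_parallel_geom(n = 8L, n_angles = 4L, n_det = 12L)
  y <- matrix(0, 4, 12); y[2, 7] <- 1
  img <- back_project(ct_sinogram(y, g$angles, g$det_spacing, "parallel"), g)$values
  expect_true(all(img >= 0))
  # explicit sparse-row oracle: the footprint mass equals the matching row
  # sum of the dense forward matrix
  Fm <- dense_forward_matrix(g)
  row_idx <- (7 - 1) * 4 + 2   # column-major (angle, bin) linearization
  expect_equal(sum(img), sum(Fm[row_idx, ]), tolerance = 1e-12)
  expect_equal(as.vector(img), Fm[row_idx, ], tolerance = 1e-12)
})

test_that("shape mismatches are rejected", {
  g <- geom_preset("parallel_default", n = 32, n_views = 12)
  expect_error(forward_project(ct_image(matrix(0, 16, 16), g$pixel_size), g),
               "does not match")
  expect_error(back_project(ct_sinogram(matrix(0, 5, 5), 1:5), g),
               "does not match")
})

test_that("downsample_half averages 2x2 blocks and halves each axis", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # block [1,2;3,4]
  out <- downsample_half(ct_image(m, 1))
  expect_equal(out$values, matrix(2.5, 1, 1))
  expect_equal(out$pixel_size, 2)

  big <- ct_image(matrix(rnorm(448 * 512), 448, 512), 0.122)
  half <- downsample_half(big)
  expect_identical(dim(half$values), c(224L, 256L))

  const <- downsample_half(ct_image(matrix(0.7, 64, 64), 1))
  expect_true(all(const$values == 0.7))
  expect_identical(dim(const$values), c(32L, 32L))

  expect_error(downsample_half(ct_image(matrix(0, 3, 4), 1)), "even")
})

test_that("bilinear upsampling preserves constants and hits midpoints", {
  const <- upsample_bilinear(ct_image(matrix(1.3, 8, 8), 1), 16, 16)
  expect_true(all(abs(const$values - 1.3) < 1e-14))
  up <- upsample_bilinear(ct_image(matrix(rnorm(224 * 256), 224, 256), 1), 448, 512)
  expect_identical(dim(up$values), c(448L, 512L))
  # midpoint between neighbors 0 and 1
  m <- matrix(c(0, 0, 1, 1), 2, 2)
  mid <- upsample_bilinear(ct_image(m, 1), 2, 3)
  expect_equal(mid$values[1, 2], 0.5)
  expect_error(upsample_bilinear(ct_image(m, 1), 1, 2), ">= source")
})

test_that("half-size roundtrip is the identity on constant images", {
  img <- ct_image(matrix(0.42, 32, 32), 1)
  rt <- upsample_bilinear(downsample_half(img), 32, 32)
  expect_equal(rt$values, img$values, tolerance = 1e-14)
})

test_that("geometry validation enforces its invariants", {
  expect_error(ct_geometry("parallel", c(10, 5), 8, 1, 8, 8, 1), "increasing")
  expect_error(ct_geometry("fan", 0:7, 8, 1, 8, 8, 1,
                           source_to_detector = 100, source_to_isocenter = 200),
               "smaller")
  g <- geom_preset("argus_central_slice", n = 64)
  expect_equal(g$source_to_detector, 370.95)
})
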