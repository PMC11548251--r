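test_that("phantoms are deterministic per seed and geometrically sane", {
  a <- make_phantom("shell_skull", 64, 1, seed = 9)
  b <- make_phantom("shell_skull", 64, 1, seed = 9)
  expect_identical(a$label_map, b$label_map)
  expect_identical(a$density_map, b$density_map)
  expect_setequal(unique(as.vector(a$label_map)), c(0L, 1L, 2L))

  d <- make_phantom("disk", 128, 0.5, seed = 1)
  area_px <- sum(d$label_map == 1L)
  r_px <- 0.38 * 128
  expect_equal(area_px, pi * r_px^2, tolerance = 0.02)

  expect_error(make_phantom("disk", 16, 1), ">= 32")
})

test_that("monochromatic projection is the forward projection of the attenuation map", {
  g <- geom_preset("parallel_default", n = 48, n_views = 20)
  ph <- make_phantom("shell_skull", 48, g$pixel_size, seed = 2)
  sp <- spectrum_preset("poly3")
  s <- project_monochromatic(ph, g, 2, sp)
  expect_identical(s$values,
                   forward_project(phantom_attenuation(ph, sp, 2), g)$values)
  # air-only phantom projects to zero
  air <- ct_phantom(matrix(0L, 48, 48), matrix(0, 48, 48), g$pixel_size)
  expect_true(all(project_monochromatic(air, g, 1, sp)$values == 0))
  # doubling density doubles the line integrals
  ph2 <- ct_phantom(ph$label_map, 2 * ph$density_map, ph$pixel_size)
  expect_equal(project_monochromatic(ph2, g, 2, sp)$values, 2 * s$values,
               tolerance = 1e-12)
  expect_error(project_monochromatic(ph, g, 9, sp), "exceeds")
})

test_that("a single-bin spectrum reduces polychromatic to monochromatic projection", {
  g <- geom_preset("parallel_default", n = 48, n_views = 16)
  ph <- make_phantom("shell_skull", 48, g$pixel_size, seed = 2)
  mono <- spectrum_preset("mono60")
  expect_equal(project_polychromatic(ph, g, mono)$values,
               project_monochromatic(ph, g, 1, mono)$values,
               tolerance = 1e-12)
})

test_that("polychromatic signal matches the closed form and Jensen's bound", {
  # two bins, weights 1/2, attenuations 0.10/0.05 per mm, 10 mm path
  n <- 40L
  px <- 0.5
  lab <- matrix(0L, n, n); den <- matrix(0, n, n)
  lab[, 11:30] <- 1L; den[, 11:30] <- 1   # 20 columns x 0.5 mm = 10 mm slab
  ph <- ct_phantom(lab, den, px)
  sp <- ct_spectrum(c(40, 80), c(0.5, 0.5),
                    rbind(air = c(0, 0), soft = c(0.10, 0.05)))
  g <- ct_geometry("parallel", c(0, 90), n_det = 60, det_spacing = px,
                   n_rows = n, n_cols = n, pixel_size = px)
  p <- project_polychromatic(ph, g, sp)$values
  # rays at angle 0 run across the slab's 10 mm thickness
  expect_equal(max(p[1, ]), -log(0.5 * (exp(-1.0) + exp(-0.5))), tolerance = 1e-6)
  # hardening never exceeds the linear mixture, for every ray
  lin <- project_monochromatic(ph, g, 1,
                               effective_mono_spectrum(sp))$values
  expect_true(all(p <= lin + 1e-12))
})

test_that("counting noise is seeded, unbiased at high flux, and flux-ordered", {
  angles <- seq(0, 359, length.out = 100)
  s0 <- ct_sinogram(matrix(0, 100, 100), angles)
  n1 <- add_counting_noise(s0, 1e5, seed = 4)
  n2 <- add_counting_noise(s0, 1e5, seed = 4)
  expect_identical(n1$values, n2$values)
  expect_lt(abs(mean(n1$values)), 0.01)          # 1e4 zero-path draws
  v3 <- var(as.vector(add_counting_noise(s0, 1e3, seed = 5)$values))
  v5 <- var(as.vector(add_counting_noise(s0, 1e5, seed = 5)$values))
  expect_lt(v5, v3)
  expect_error(add_counting_noise(s0, 0), "i0")
})

test_that("sampling schemes select views bit-exactly per their definitions", {
  angles <- seq(0, 359)
  s <- ct_sinogram(matrix(rnorm(360 * 8), 360), angles)

  expect_identical(subsample_projections(s, sampling_scheme("SD"))$values, s$values)

  ld <- subsample_projections(s, sampling_scheme("LD"))
  expect_identical(nrow(ld$values), 180L)
  expect_identical(ld$values, s$values[seq(1, 360, 2), ])
  expect_equal(ld$angles, as.numeric(angles[seq(1, 360, 2)]))

  for (seed in 1:25) {
    lnp <- subsample_projections(s, sampling_scheme("LNP", seed = seed))
    expect_true(nrow(lnp$values) >= 30 && nrow(lnp$values) <= 60)
    kept <- attr(lnp, "kept")
    expect_identical(lnp$values, s$values[kept, ])   # pure selection
    expect_true(all(diff(kept) > 0))

    lsa <- subsample_projections(s, sampling_scheme("LSA", seed = seed))
    ka <- sort(attr(lsa, "kept"))
    span <- length(ka)  # contiguous 1-degree steps
    expect_true(span >= 89 && span <= 161)
    # contiguity modulo the wrap-around
    gaps <- diff(ka)
    expect_lte(sum(gaps != 1), 1L)
  }
  expect_error(subsample_projections(ct_sinogram(matrix(0, 90, 8), 0:89),
                                     sampling_scheme("LNP")), "full-rotation")
})

test_that("bundled spectra are normalized with hardening-consistent bone tables", {
  for (nm in c("poly3", "poly5", "mono60")) {
    sp <- spectrum_preset(nm)
    expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
    expect_true(all(sp$material_atten >= 0))
    bone <- sp$material_atten["bone", ]
    if (length(bone) > 1) expect_true(all(diff(bone) < 0))
  }
  em <- effective_mono_spectrum(spectrum_preset("poly3"))
  expect_identical(length(em$energies), 1L)
  expect_equal(em$material_atten["soft", 1],
               sum(spectrum_preset("poly3")$weights *
                   spectrum_preset("poly3")$material_atten["soft", ]))
})
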