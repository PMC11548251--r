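# Shared fixtures and independent oracles, built in code at test time.

# Assemble the dense matrix of any linear image-to-whatever operator by
# pushing basis images through it.
dense_operator <- function(op, n_rows, n_cols) {
  N <- n_rows * n_cols
  cols <- lapply(seq_len(N), function(j) {
    e <- matrix(0, n_rows, n_cols)
    e[j] <- 1
    as.vector(op(e))
  })
  do.call(cbind, cols)
}

tiny_parallel_geom <- function(n = 6L, n_angles = 8L, n_det = 10L) {
  angles <- seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)]
  ct_geometry("parallel", angles, n_det = n_det, det_spacing = 1.1,
              n_rows = n, n_cols = n, pixel_size = 1)
}

dense_forward_matrix <- function(geom) {
  dense_operator(function(e) forward_project(ct_image(e, geom$pixel_size), geom)$values,
                 geom$n_rows, geom$n_cols)
}

dense_grad_matrices <- function(n_rows, n_cols) {
  list(Dx = dense_operator(piccs:::grad_x, n_rows, n_cols),
       Dy = dense_operator(piccs:::grad_y, n_rows, n_cols))
}

# Small monochromatic test problem: shell phantom, limited views, truth and
# full-view sinogram at the spectrum's effective energy.
small_problem <- function(n = 48L, n_views = 60L, phantom = "shell_skull",
                          seed = 3L) {
  g <- geom_preset("parallel_default", n = n, n_views = n_views)
  ph <- make_phantom(phantom, n, g$pixel_size, seed = seed)
  em <- effective_mono_spectrum(spectrum_preset("poly3"))
  list(geom = g, phantom = ph, spectrum = em,
       truth = phantom_attenuation(ph, em, 1L),
       sino = project_monochromatic(ph, g, 1L, em))
}

# scikit-image structural_similarity / peak_signal_noise_ratio values for
# the 20 random pairs generated by random_metric_pairs() (win_size 11,
# gaussian_weights, sigma 1.5, use_sample_covariance FALSE, data_range =
# reference dynamic range), frozen as the independent reference.
random_metric_pairs <- function() {
  withr::with_seed(107L, lapply(1:20, function(i) {
    n <- 32L
    a <- matrix(rnorm(n * n), n)
    b <- if (i %% 2 == 0) a + 0.3 * matrix(rnorm(n * n), n) else matrix(rnorm(n * n), n)
    if (i %% 3 == 0) {
      a <- piccs:::gaussian_blur(a, 1.2)
      b <- piccs:::gaussian_blur(b, 1.2)
    }
    list(a = a, b = b)
  }))
}

skimage_ssim_ref <- c(
  0.0176963135323311, 0.836964632974994, -0.0210008061983957,
  0.826225788633797, 0.0204305541223892, 0.737705648176368,
  0.0145854549781246, 0.77511435902925, 0.019965697613333,
  0.86732091181797, 0.0246632958739623, 0.702127636029045,
  -0.0121423666510518, 0.850296332022478, 0.109692864471912,
  0.827680784606792, -0.0119052619861904, 0.766509901063311,
  -0.00191651695607952, 0.798464406069949)

skimage_psnr_ref <- c(
  13.6153993917034, 26.4316311555726, 14.8795493388814, 26.7427060106019,
  12.2187177140624, 26.3030744527128, 12.8230052157447, 26.0616640275092,
  11.7349894668502, 27.4417374622798, 13.4817615253393, 27.2369423174627,
  12.5659658128267, 26.5794943254259, 14.9368732960397, 27.6640604008008,
  13.4277357081241, 25.1918327967093, 13.1684729775692, 26.9811230756996)
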