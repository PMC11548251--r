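# Degraded-prior fabrication: emulates what a learned restoration model
# hands the solver -- a smoothed, half-resolution-limited estimate of the
# clean slice, possibly containing hallucinated structure with no support in
# the measured data.

#' Hallucination blob description
#'
#' A smooth, compactly supported radial bump: amplitude at the center with a
#' raised-cosine taper to zero at `radius`. `sign = "add"` models an invented
#' structure, `"remove"` an erased one.
#'
#' @param center length-2 numeric `(row, col)` in pixels (1-based).
#' @param radius blob radius in pixels (> 0).
#' @param amplitude peak amplitude in 1/mm (finite).
#' @param sign `"add"` or `"remove"`.
#' @return A list of class `hallucination`.
#' @export
hallucination <- function(center, radius, amplitude, sign = c("add", "remove")) {
  sign <- match.arg(sign)
  if (length(center) != 2L || !all(is.finite(center)))
    stop_input("`center` must be (row, col)")
  check_scalar_num(radius, "radius", lower = 0)
  check_scalar_num(amplitude, "amplitude")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 amplitude = as.numeric(amplitude), sign = sign),
            class = "hallucination")
}

#' Prior fabrication specification
#'
#' Controls [fabricate_prior()]: an optional half-resolution roundtrip
#' (2x2 block averaging followed by bilinear upsampling, mimicking a model
#' operated at half the reconstruction size), a Gaussian blur, and a list of
#' injected [hallucination()] blobs.
#'
#' @param use_half_size_roundtrip apply the half-size roundtrip first.
#' @param blur_sigma Gaussian blur standard deviation in pixels (0 = none).
#' @param hallucinations list of [hallucination()] objects.
#' @param perturb_rms root-mean-square amplitude (1/mm) of a smooth seeded
#'   random error field, emulating the estimate-dependent residual error of
#'   a learned prior; two seeds give two different priors of identical
#'   degradation magnitude (0 = none).
#' @param seed integer seed driving the perturbation field.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(use_half_size_roundtrip = FALSE, blur_sigma = 0,
                       hallucinations = list(), perturb_rms = 0, seed = 1L) {
  check_scalar_num(blur_sigma, "blur_sigma", lower = 0, allow_zero_lower = TRUE)
  check_scalar_num(perturb_rms, "perturb_rms", lower = 0, allow_zero_lower = TRUE)
  if (!all(vapply(hallucinations, inherits, logical(1), "hallucination")))
    stop_input("`hallucinations` must be a list of hallucination() objects")
  structure(
    list(use_half_size_roundtrip = isTRUE(use_half_size_roundtrip),
         blur_sigma = as.numeric(blur_sigma),
         hallucinations = hallucinations,
         perturb_rms = as.numeric(perturb_rms), seed = as.integer(seed)),
    class = "prior_spec"
  )
}

# Separable Gaussian blur with replicate (Neumann) edges; kernel normalized,
# so constants are preserved exactly.
gaussian_blur <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  blur1 <- function(m) { # along rows (dim 1)
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * mp[seq(t, t + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(v))))
}

radial_bump <- function(nr, nc, center, radius, amplitude) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  ifelse(d < radius, amplitude * 0.5 * (1 + cos(pi * d / radius)), 0)
}

#' Fabricate a degraded prior image
#'
#' Applies, in order: the half-resolution roundtrip (if enabled), a Gaussian
#' blur of `blur_sigma` pixels, and each hallucination blob. With an empty
#' specification the target is returned unchanged. The result emulates a
#' learned prior: structurally faithful at coarse scale, band-limited, and
#' possibly carrying structures with no support in the data.
#'
#' @param target a [ct_image()] (even dimensions if the roundtrip is on).
#' @param spec a [prior_spec()].
#' @return A [ct_image()] on the same grid as `target`.
#' @examples
#' tgt <- ct_image(matrix(0.02, 64, 64), 1)
#' sp <- prior_spec(use_half_size_roundtrip = TRUE, blur_sigma = 1.5)
#' pr <- fabricate_prior(tgt, sp)
#' @export
fabricate_prior <- function(target, spec) {
  v <- target$values
  nr <- nrow(v); nc <- ncol(v)
  if (spec$use_half_size_roundtrip) {
    if (nr %% 2L != 0L || nc %% 2L != 0L)
      stop_input("half-size roundtrip needs even target dimensions")
    half <- downsample_half(target)
    v <- upsample_bilinear(half, nr, nc)$values
  }
  v <- gaussian_blur(v, spec$blur_sigma)
  if (spec$perturb_rms > 0) {
    field <- with_fixed_seed(spec$seed, matrix(rnorm(nr * nc), nr, nc))
    field <- gaussian_blur(field, 4)
    v <- v + field * (spec$perturb_rms / sqrt(mean(field^2)))
  }
  for (h in spec$hallucinations) {
    if (h$center[1] - h$radius < 1 || h$center[1] + h$radius > nr ||
        h$center[2] - h$radius < 1 || h$center[2] + h$radius > nc)
      stop_input("hallucination blob extends outside the image")
    bump <- radial_bump(nr, nc, h$center, h$radius, h$amplitude)
    v <- if (h$sign == "add") v + bump else v - bump
  }
  ct_image(v, target$pixel_size)
}
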