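#' Monochromatic projection of a phantom
#'
#' Line integrals of the phantom's attenuation image at a single energy bin:
#' exactly `forward_project(phantom_attenuation(ph, spec, i), geom)`. This
#' generates hardening-free target data (the simulator's replacement for
#' calibration-corrected reference reconstructions).
#'
#' @param ph a [ct_phantom()] whose grid matches `geom`.
#' @param geom a [ct_geometry()].
#' @param ref_energy_index energy bin of `spec` to evaluate at.
#' @param spec a [ct_spectrum()].
#' @return A [ct_sinogram()].
#' @export
project_monochromatic <- function(ph, geom, ref_energy_index, spec) {
  att <- phantom_attenuation(ph, spec, ref_energy_index)
  forward_project(att, geom)
}

#' Polychromatic projection of a phantom (beam hardening)
#'
#' For each ray, per-material path lengths `L_m` are computed with the same
#' discrete projector as [forward_project()], and the measured log-signal is
#' \deqn{p = -\log \sum_E w(E) \exp(-\sum_m \mu_m(E) L_m).}
#' Because low-energy bins decay fastest, `p` grows sublinearly with path
#' length -- the beam-hardening effect that produces cupping in homogeneous
#' regions and dark bands between dense structures. A single-bin spectrum
#' reduces this to [project_monochromatic()].
#'
#' @inheritParams project_monochromatic
#' @return A [ct_sinogram()].
#' @export
project_polychromatic <- function(ph, geom, spec) {
  if (length(spec$energies) < 1L)
    stop_input("spectrum must have at least one bin")
  if (abs(sum(spec$weights) - 1) > 1e-12)
    stop_input("spectrum weights must be normalized")
  materials <- seq_len(nrow(spec$material_atten)) - 1L
  # per-material path length maps (mm at reference density)
  L <- lapply(materials, function(m) {
    mask <- ph$density_map * (ph$label_map == m)
    if (all(mask == 0)) return(NULL)
    forward_project(ct_image(mask, ph$pixel_size), geom)$values
  })
  trans <- 0
  for (e in seq_along(spec$energies)) {
    expo <- 0
    for (m in seq_along(L)) {
      if (!is.null(L[[m]])) expo <- expo + spec$material_atten[m, e] * L[[m]]
    }
    trans <- trans + spec$weights[e] * exp(-expo)
  }
  ct_sinogram(-log(trans), geom$angles, geom$det_spacing, geom$beam_type)
}

#' Add photon-counting noise to a sinogram
#'
#' Draws transmitted counts per bin as `Poisson(i0 * exp(-p))` and returns
#' the noisy log-signal `-log(max(count, 1) / i0)`. Deterministic for a
#' fixed seed.
#'
#' @param sino a [ct_sinogram()] of line integrals `p`.
#' @param i0 unattenuated photon count per detector bin (> 0).
#' @param seed integer seed.
#' @return A [ct_sinogram()] with noisy values.
#' @export
add_counting_noise <- function(sino, i0, seed = 1L) {
  check_scalar_num(i0, "i0", lower = 0)
  counts <- with_fixed_seed(seed, {
    matrix(rpois(length(sino$values), lambda = i0 * exp(-sino$values)),
           nrow(sino$values))
  })
  ct_sinogram(-log(pmax(counts, 1) / i0), sino$angles,
              sino$det_spacing, sino$beam_type)
}

#' Acquisition sampling scheme
#'
#' The four acquisition scenarios applied to a full-rotation sinogram:
#' * `SD` (standard dose): all views kept;
#' * `LD` (low dose): every second view;
#' * `LSA` (limited span angle): a contiguous arc whose span is drawn
#'   uniformly from `span_range` (default 90--160 degrees), with a uniform
#'   random start angle;
#' * `LNP` (limited number of projections): a uniformly random subset
#'   without replacement, of size drawn from `count_range` (default 30--60).
#'
#' @param kind `"SD"`, `"LD"`, `"LSA"` or `"LNP"`.
#' @param span_range length-2 numeric, LSA span interval in degrees.
#' @param count_range length-2 integer, LNP view-count interval.
#' @param seed integer seed driving the random draws.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(kind = c("SD", "LD", "LSA", "LNP"),
                            span_range = c(90, 160),
                            count_range = c(30L, 60L), seed = 1L) {
  kind <- match.arg(kind)
  if (length(span_range) != 2L || span_range[1] > span_range[2] ||
      span_range[1] <= 0 || span_range[2] > 360)
    stop_input("`span_range` must be an interval within (0, 360]")
  if (length(count_range) != 2L || count_range[1] > count_range[2] ||
      count_range[1] < 1)
    stop_input("`count_range` must be a positive integer interval")
  structure(
    list(kind = kind, span_range = as.numeric(span_range),
         count_range = as.integer(count_range), seed = as.integer(seed)),
    class = "sampling_scheme"
  )
}

#' Subsample a full-rotation sinogram according to a scheme
#'
#' Pure view selection: retained projections are kept bit-exactly, the angle
#' list is updated, and nothing is interpolated. Deterministic per
#' `scheme$seed`.
#'
#' @param sino a [ct_sinogram()] covering (close to) a full rotation.
#' @param scheme a [sampling_scheme()].
#' @return A [ct_sinogram()] with the retained views, plus attribute
#'   `"kept"` holding the retained view indices.
#' @export
subsample_projections <- function(sino, scheme) {
  n <- nrow(sino$values)
  span_in <- diff(range(sino$angles))
  if (span_in < 270)
    stop_input("subsample_projections expects full-rotation input data")
  kept <- switch(scheme$kind,
    SD = seq_len(n),
    LD = seq(1L, n, by = 2L),
    LSA = with_fixed_seed(scheme$seed, {
      span <- runif(1, scheme$span_range[1], scheme$span_range[2])
      start <- runif(1, 0, 360)
      which(((sino$angles - start) %% 360) < span)
    }),
    LNP = with_fixed_seed(scheme$seed, {
      m <- sample(seq(scheme$count_range[1], scheme$count_range[2]), 1L)
      if (m > n) stop_input("requested LNP count exceeds available views")
      sort(sample.int(n, m))
    })
  )
  if (length(kept) < 1L)
    stop_input("sampling scheme retained no views")
  out <- ct_sinogram(sino$values[kept, , drop = FALSE], sino$angles[kept],
                     sino$det_spacing, sino$beam_type)
  attr(out, "kept") <- kept
  out
}

#' Restrict a geometry to a subset of views
#'
#' Companion to [subsample_projections()]: returns the same geometry with
#' only the retained angles.
#'
#' @param geom a [ct_geometry()].
#' @param kept integer indices of retained views (e.g. the `"kept"`
#'   attribute of a subsampled sinogram).
#' @return A [ct_geometry()].
#' @export
subset_geometry <- function(geom, kept) {
  g <- geom
  g$angles <- geom$angles[kept]
  g
}
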