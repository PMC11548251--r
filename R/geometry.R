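#' 2D attenuation image
#'
#' A rectangular grid of linear attenuation coefficients (1/mm) with a
#' physical pixel size. This container holds every image-domain quantity in
#' the toolkit: ground-truth slices, priors, auxiliary solver iterates and
#' reconstructions.
#'
#' @param values numeric matrix of attenuation coefficients (1/mm); all
#'   entries must be finite.
#' @param pixel_size physical edge length of one pixel, in mm.
#' @return An object of class `ct_image`.
#' @examples
#' img <- ct_image(matrix(0.02, 32, 32), pixel_size = 0.5)
#' dim(img$values)
#' @export
ct_image <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`values` must be a numeric matrix")
  if (!all(is.finite(values)))
    stop_input("image values must all be finite")
  check_scalar_num(pixel_size, "pixel_size", lower = 0)
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size)),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d pixels, %.4g mm/pixel, range [%.4g, %.4g] 1/mm\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

as_ct_image <- function(values, like) {
  ct_image(values, like$pixel_size)
}

#' Projection geometry
#'
#' Describes the acquisition that defines the discrete forward operator: the
#' view angles, the (flat, equidistant) detector and the reconstruction grid
#' it is bound to. Parallel-beam and fan-beam (the central slice of a
#' circular cone-beam system with a flat panel) geometries are supported.
#'
#' Angles are in degrees, counterclockwise, with 0 along the +x axis; the
#' physical origin is the grid center and all lengths are in mm.
#'
#' @param beam_type `"parallel"` or `"fan"`.
#' @param angles numeric vector of view angles in degrees, strictly
#'   increasing modulo 360.
#' @param n_det number of detector bins.
#' @param det_spacing detector bin spacing in mm.
#' @param n_rows,n_cols reconstruction grid dimensions.
#' @param pixel_size reconstruction pixel size in mm.
#' @param source_to_detector,source_to_isocenter fan-beam distances in mm
#'   (ignored for parallel beams).
#' @return An object of class `ct_geometry`.
#' @seealso [geom_preset()] for bundled presets.
#' @examples
#' g <- ct_geometry("parallel", angles = seq(0, 359, by = 2), n_det = 96,
#'                  det_spacing = 1, n_rows = 64, n_cols = 64, pixel_size = 1)
#' g
#' @export
ct_geometry <- function(beam_type = c("parallel", "fan"), angles, n_det,
                        det_spacing, n_rows, n_cols, pixel_size,
                        source_to_detector = NULL, source_to_isocenter = NULL) {
  beam_type <- match.arg(beam_type)
  if (!is.numeric(angles) || length(angles) < 1L || anyNA(angles))
    stop_input("`angles` must be a non-empty numeric vector of degrees")
  a360 <- angles %% 360
  if (length(angles) > 1L && any(diff(angles) <= 0))
    stop_input("`angles` must be strictly increasing")
  n_det <- check_count(n_det, "n_det")
  check_scalar_num(det_spacing, "det_spacing", lower = 0)
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  check_scalar_num(pixel_size, "pixel_size", lower = 0)
  if (beam_type == "fan") {
    check_scalar_num(source_to_detector, "source_to_detector", lower = 0)
    check_scalar_num(source_to_isocenter, "source_to_isocenter", lower = 0)
    if (source_to_isocenter >= source_to_detector)
      stop_input("`source_to_isocenter` must be smaller than `source_to_detector`")
  } else {
    source_to_detector <- source_to_isocenter <- NA_real_
  }
  structure(
    list(beam_type = beam_type, angles = as.numeric(angles),
         n_det = n_det, det_spacing = as.numeric(det_spacing),
         n_rows = n_rows, n_cols = n_cols, pixel_size = as.numeric(pixel_size),
         source_to_detector = as.numeric(source_to_detector),
         source_to_isocenter = as.numeric(source_to_isocenter)),
    class = "ct_geometry"
  )
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf("<ct_geometry> %s beam, %d views [%.4g..%.4g deg], %d bins @ %.4g mm, grid %dx%d @ %.4g mm\n",
              x$beam_type, length(x$angles), min(x$angles), max(x$angles),
              x$n_det, x$det_spacing, x$n_rows, x$n_cols, x$pixel_size))
  invisible(x)
}

# Internal list handed to the C++ projectors.
geom_cpp <- function(geom) {
  list(beam_type = geom$beam_type,
       n_rows = geom$n_rows, n_cols = geom$n_cols,
       n_det = geom$n_det, det_spacing = geom$det_spacing,
       pixel_size = geom$pixel_size,
       source_to_detector = geom$source_to_detector,
       source_to_isocenter = geom$source_to_isocenter,
       angles_rad = geom$angles * pi / 180)
}

#' Geometry presets
#'
#' Bundled geometries. `argus_central_slice` mirrors the central slice of a
#' small-animal cone-beam scanner with a flat-panel detector at a
#' source-detector distance of 370.95 mm.
#'
#' @param name preset name: `"parallel_default"`, `"fan_default"` or
#'   `"argus_central_slice"`.
#' @param n reconstruction grid size (square), default 128.
#' @param n_views number of views over 360 degrees, default 360.
#' @return A [ct_geometry()].
#' @export
geom_preset <- function(name = c("parallel_default", "fan_default",
                                 "argus_central_slice"),
                        n = 128L, n_views = 360L) {
  name <- match.arg(name)
  n <- check_count(n, "n", min = 8L)
  n_views <- check_count(n_views, "n_views", min = 2L)
  px <- 64 / n  # 64 mm field of view
  angles <- seq(0, 360, length.out = n_views + 1L)[seq_len(n_views)]
  # detector sampled at half the pixel pitch to keep edge aliasing out of
  # the filtered backprojection
  n_det <- as.integer(3L * n)
  switch(name,
    parallel_default = ct_geometry("parallel", angles, n_det = n_det,
                                   det_spacing = px / 2, n_rows = n, n_cols = n,
                                   pixel_size = px),
    fan_default = ct_geometry("fan", angles, n_det = n_det,
                              det_spacing = px, n_rows = n, n_cols = n,
                              pixel_size = px,
                              source_to_detector = 400, source_to_isocenter = 200),
    argus_central_slice = ct_geometry("fan", angles, n_det = n_det,
                                      det_spacing = px * 370.95 / 200 / 2,
                                      n_rows = n, n_cols = n, pixel_size = px,
                                      source_to_detector = 370.95,
                                      source_to_isocenter = 200)
  )
}

#' Sinogram (line-integral projection data)
#'
#' An (angles x detector bins) array of dimensionless line integrals with
#' the view angles that generated it.
#'
#' @param values numeric matrix, one row per view, one column per detector
#'   bin; all entries finite.
#' @param angles view angles in degrees, one per row of `values`.
#' @param det_spacing detector bin spacing in mm (metadata, carried along).
#' @param beam_type beam type of the generating geometry.
#' @return An object of class `ct_sinogram`.
#' @export
ct_sinogram <- function(values, angles, det_spacing = NA_real_,
                        beam_type = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`values` must be a numeric matrix")
  if (!all(is.finite(values)))
    stop_input("sinogram values must all be finite")
  if (length(angles) != nrow(values))
    stop_input("`angles` length must equal nrow(values)")
  structure(
    list(values = values, angles = as.numeric(angles),
         det_spacing = det_spacing, beam_type = beam_type),
    class = "ct_sinogram"
  )
}

#' @export
print.ct_sinogram <- function(x, ...) {
  cat(sprintf("<ct_sinogram> %d views x %d bins (%s beam), range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values),
              ifelse(is.na(x$beam_type), "?", x$beam_type),
              min(x$values), max(x$values)))
  invisible(x)
}

check_image_geom <- function(image, geom) {
  if (nrow(image$values) != geom$n_rows || ncol(image$values) != geom$n_cols)
    stop_input(sprintf("image grid %dx%d does not match geometry binding %dx%d",
                       nrow(image$values), ncol(image$values),
                       geom$n_rows, geom$n_cols))
  invisible(TRUE)
}

check_sino_geom <- function(sino, geom) {
  if (nrow(sino$values) != length(geom$angles) || ncol(sino$values) != geom$n_det)
    stop_input(sprintf("sinogram %dx%d does not match geometry (%d views x %d bins)",
                       nrow(sino$values), ncol(sino$values),
                       length(geom$angles), geom$n_det))
  invisible(TRUE)
}

#' Forward projection (the system operator F)
#'
#' Computes line integrals of an attenuation image along every
#' (view, detector-bin) ray of the geometry, using a ray-driven projector
#' with linear (Joseph-style) interpolation. The operator is linear, and
#' [back_project()] is its exact matrix transpose.
#'
#' @param image a [ct_image()] whose grid matches `geom`.
#' @param geom a [ct_geometry()].
#' @return A [ct_sinogram()] of dimension `length(geom$angles) x geom$n_det`.
#' @examples
#' g <- geom_preset("parallel_default", n = 32, n_views = 24)
#' img <- ct_image(matrix(0.01, 32, 32), g$pixel_size)
#' s <- forward_project(img, g)
#' dim(s$values)
#' @export
forward_project <- function(image, geom) {
  check_image_geom(image, geom)
  vals <- cpp_forward_project(image$values, geom_cpp(geom))
  ct_sinogram(vals, geom$angles, geom$det_spacing, geom$beam_type)
}

#' Backprojection (the adjoint operator F^T)
#'
#' Applies the exact matrix transpose of [forward_project()]: the same ray
#' weights, scattered back into the image grid. This matched pair is what
#' the normal-operator `K = mu F^T F + ...` of the iterative solver needs;
#' it is not a tomographic inverse (see [fbp_reconstruct()] for that).
#'
#' @param sino a [ct_sinogram()] consistent with `geom`.
#' @param geom a [ct_geometry()].
#' @return A [ct_image()] on the geometry's grid.
#' @export
back_project <- function(sino, geom) {
  check_sino_geom(sino, geom)
  vals <- cpp_back_project(sino$values, geom_cpp(geom))
  ct_image(vals, geom$pixel_size)
}
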