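#' Material-labelled phantom
#'
#' A 2D phantom defined by a material label map (0 = air, 1 = soft tissue,
#' 2 = bone) and a relative density map. Phantoms are the simulator's stand-in
#' for small-animal head slices: soft tissue enclosed by a dense skull shell.
#'
#' @param label_map integer matrix of material indices in \{0, 1, 2\}.
#' @param density_map numeric matrix of nonnegative relative densities,
#'   same shape as `label_map`.
#' @param pixel_size pixel size in mm.
#' @return An object of class `ct_phantom`.
#' @export
ct_phantom <- function(label_map, density_map, pixel_size) {
  if (!is.matrix(label_map) || !all(label_map %in% 0:2))
    stop_input("`label_map` must be a matrix with labels in {0, 1, 2}")
  if (!is.matrix(density_map) || !all(is.finite(density_map)) || any(density_map < 0))
    stop_input("`density_map` must be a finite nonnegative matrix")
  if (!identical(dim(label_map), dim(density_map)))
    stop_input("`label_map` and `density_map` must have the same shape")
  check_scalar_num(pixel_size, "pixel_size", lower = 0)
  structure(
    list(label_map = label_map, density_map = density_map,
         pixel_size = as.numeric(pixel_size)),
    class = "ct_phantom"
  )
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> %d x %d @ %.4g mm, materials present: %s\n",
              nrow(x$label_map), ncol(x$label_map), x$pixel_size,
              paste(sort(unique(as.vector(x$label_map))), collapse = ", ")))
  invisible(x)
}

# Pixel-center coordinate grids (mm), origin at grid center, +y up.
grid_coords <- function(n, pixel_size) {
  cc <- (n - 1) / 2
  x <- matrix((col(matrix(0, n, n)) - 1 - cc) * pixel_size, n, n)
  y <- matrix((cc - (row(matrix(0, n, n)) - 1)) * pixel_size, n, n)
  list(x = x, y = y)
}

in_ellipse <- function(x, y, cx, cy, a, b, phi = 0) {
  xr <- (x - cx) * cos(phi) + (y - cy) * sin(phi)
  yr <- -(x - cx) * sin(phi) + (y - cy) * cos(phi)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Build a test phantom
#'
#' Three families are bundled:
#' * `disk`: a homogeneous soft-tissue disk (the classic cupping-artifact
#'   object);
#' * `shell_skull`: a soft-tissue ellipse enclosed by a dense bone shell with
#'   seeded internal density blobs -- the configuration that elicits dark
#'   bands between dense structures under a polychromatic beam;
#' * `blobs`: a smooth random soft-tissue texture of overlapping ellipses.
#'
#' All randomness is driven by `seed`, so a phantom is fully reproducible.
#'
#' @param kind `"disk"`, `"shell_skull"` or `"blobs"`.
#' @param n square grid size in pixels (>= 32).
#' @param pixel_size pixel size in mm.
#' @param seed integer seed for the randomized internals.
#' @return A [ct_phantom()].
#' @examples
#' ph <- make_phantom("shell_skull", n = 64, pixel_size = 1, seed = 7)
#' table(ph$label_map)
#' @export
make_phantom <- function(kind = c("disk", "shell_skull", "blobs"), n,
                         pixel_size, seed = 1L) {
  kind <- match.arg(kind)
  n <- check_count(n, "n", min = 32L)
  check_scalar_num(pixel_size, "pixel_size", lower = 0)
  fov <- n * pixel_size
  g <- grid_coords(n, pixel_size)
  lab <- matrix(0L, n, n)
  den <- matrix(0, n, n)

  with_fixed_seed(seed, {
    if (kind == "disk") {
      r <- 0.38 * fov
      inside <- (g$x^2 + g$y^2) <= r^2
      lab[inside] <- 1L
      den[inside] <- 1
    } else if (kind == "shell_skull") {
      a_out <- 0.42 * fov; b_out <- 0.34 * fov
      shell <- 0.045 * fov
      outer <- in_ellipse(g$x, g$y, 0, 0, a_out, b_out)
      inner <- in_ellipse(g$x, g$y, 0, 0, a_out - shell, b_out - shell)
      lab[outer] <- 2L; den[outer] <- 1      # bone shell
      lab[inner] <- 1L; den[inner] <- 1      # brain-like interior
      n_blob <- 4L
      for (b in seq_len(n_blob)) {
        cx <- runif(1, -0.15, 0.15) * fov
        cy <- runif(1, -0.12, 0.12) * fov
        ab <- runif(2, 0.03, 0.08) * fov
        phi <- runif(1, 0, pi)
        blob <- in_ellipse(g$x, g$y, cx, cy, ab[1], ab[2], phi) & inner
        den[blob] <- den[blob] * runif(1, 0.85, 1.15)
      }
      # one small internal bone speck (tooth/implant analogue)
      cx <- runif(1, -0.1, 0.1) * fov; cy <- runif(1, 0.1, 0.2) * fov
      speck <- in_ellipse(g$x, g$y, cx, cy, 0.03 * fov, 0.025 * fov) & inner
      lab[speck] <- 2L; den[speck] <- 0.9
    } else { # blobs
      for (b in seq_len(6L)) {
        cx <- runif(1, -0.2, 0.2) * fov
        cy <- runif(1, -0.2, 0.2) * fov
        ab <- runif(2, 0.06, 0.18) * fov
        phi <- runif(1, 0, pi)
        blob <- in_ellipse(g$x, g$y, cx, cy, ab[1], ab[2], phi)
        lab[blob] <- 1L
        den[blob] <- pmax(den[blob], runif(1, 0.7, 1.2))
      }
    }
  })
  ct_phantom(lab, den, pixel_size)
}

#' Monochromatic attenuation image of a phantom
#'
#' The per-pixel linear attenuation map at one energy bin of a spectrum:
#' `mu_material(E) * density`. This is the simulator's ground-truth image,
#' free of beam hardening by construction.
#'
#' @param ph a [ct_phantom()].
#' @param spec a [ct_spectrum()].
#' @param energy_index which energy bin to evaluate at.
#' @return A [ct_image()] in 1/mm.
#' @export
phantom_attenuation <- function(ph, spec, energy_index) {
  energy_index <- check_count(energy_index, "energy_index")
  if (energy_index > length(spec$energies))
    stop_input("`energy_index` exceeds the number of spectrum bins")
  mu <- spec$material_atten[, energy_index]
  vals <- matrix(mu[ph$label_map + 1L], nrow(ph$label_map)) * ph$density_map
  ct_image(vals, ph$pixel_size)
}
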