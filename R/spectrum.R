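#' X-ray source spectrum with material attenuation tables
#'
#' An energy-binned description of a polychromatic source: bin energies,
#' normalized bin weights, and per-material linear attenuation coefficients
#' (1/mm at reference density) for each bin. Beam hardening arises because
#' low-energy bins attenuate faster, so the effective attenuation of a ray
#' decreases with path length.
#'
#' @param energies energies in keV, strictly increasing.
#' @param weights nonnegative bin weights summing to 1 (within 1e-12).
#' @param material_atten numeric matrix, one row per material (rows named
#'   `air`, `soft`, `bone` to match phantom labels 0, 1, 2), one column per
#'   energy bin; all entries nonnegative.
#' @return An object of class `ct_spectrum`.
#' @seealso [spectrum_preset()] for the bundled toy spectra.
#' @export
ct_spectrum <- function(energies, weights, material_atten) {
  if (!is.numeric(energies) || any(diff(energies) <= 0) && length(energies) > 1L)
    stop_input("`energies` must be strictly increasing")
  if (length(weights) != length(energies) || any(weights < 0))
    stop_input("`weights` must be nonnegative, one per energy bin")
  if (abs(sum(weights) - 1) > 1e-12)
    stop_input("`weights` must sum to 1 (within 1e-12)")
  if (!is.matrix(material_atten) || ncol(material_atten) != length(energies) ||
      any(material_atten < 0))
    stop_input("`material_atten` must be a nonnegative materials x bins matrix")
  if (is.null(rownames(material_atten)))
    rownames(material_atten) <- c("air", "soft", "bone")[seq_len(nrow(material_atten))]
  structure(
    list(energies = as.numeric(energies), weights = as.numeric(weights),
         material_atten = material_atten),
    class = "ct_spectrum"
  )
}

#' @export
print.ct_spectrum <- function(x, ...) {
  cat(sprintf("<ct_spectrum> %d bins at [%s] keV, materials: %s\n",
              length(x$energies), paste(x$energies, collapse = ", "),
              paste(rownames(x$material_atten), collapse = ", ")))
  invisible(x)
}

#' Effective monochromatic equivalent of a spectrum
#'
#' The single-bin spectrum whose attenuation coefficients are the
#' weight-averaged coefficients of `spec`: the zero-path-length (Jensen)
#' linearization of the polychromatic signal. Reconstructions of
#' polychromatic data sit at or below this reference everywhere, with the
#' deficit concentrated where rays traverse dense material -- which is what
#' makes it the natural baseline for quantifying cupping and dark bands.
#'
#' @param spec a [ct_spectrum()].
#' @return A single-bin [ct_spectrum()].
#' @export
effective_mono_spectrum <- function(spec) {
  mu <- as.matrix(spec$material_atten %*% spec$weights)
  e <- sum(spec$energies * spec$weights)
  m <- matrix(mu, ncol = 1, dimnames = list(rownames(spec$material_atten),
                                            sprintf("%.3gkeV", e)))
  ct_spectrum(e, 1, m)
}

#' Bundled toy spectra
#'
#' Hand-set spectra with water-like soft tissue and a bone that shows the
#' strong low-energy excess responsible for cupping and dark bands. The
#' attenuation tables are plausible-scale values (1/mm), not measured data;
#' `mono60` is the single-bin reference used to generate hardening-free
#' target data.
#'
#' @param name `"mono60"` (1 bin), `"poly3"` (3 bins) or `"poly5"` (5 bins).
#' @return A [ct_spectrum()].
#' @export
spectrum_preset <- function(name = c("poly3", "poly5", "mono60")) {
  name <- match.arg(name)
  tab <- function(E, soft, bone) {
    m <- rbind(air = rep(0, length(E)), soft = soft, bone = bone)
    colnames(m) <- paste0(E, "keV")
    m
  }
  switch(name,
    mono60 = ct_spectrum(60, 1, tab(60, soft = 0.0206, bone = 0.0732)),
    poly3 = ct_spectrum(
      energies = c(25, 45, 65),
      weights = c(0.35, 0.40, 0.25),
      material_atten = tab(c(25, 45, 65),
                           soft = c(0.0546, 0.0242, 0.0198),
                           bone = c(0.3170, 0.0930, 0.0620))
    ),
    poly5 = ct_spectrum(
      energies = c(25, 35, 45, 60, 80),
      weights = c(0.12, 0.24, 0.28, 0.24, 0.12),
      material_atten = tab(c(25, 35, 45, 60, 80),
                           soft = c(0.0546, 0.0306, 0.0242, 0.0206, 0.0184),
                           bone = c(0.3170, 0.1310, 0.0930, 0.0732, 0.0428))
    )
  )
}
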