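# Image-quality metrics: PSNR, SSIM (11x11 Gaussian window, sigma 1.5,
# standard stabilizers) and Pearson correlation.

as_values <- function(x) if (inherits(x, "ct_image")) x$values else x

check_same_shape <- function(x, ref) {
  if (!identical(dim(x), dim(ref)))
    stop_input("images must have the same shape")
}

resolve_data_range <- function(ref, data_range) {
  if (identical(data_range, "auto")) {
    dr <- max(ref) - min(ref)
    if (dr <= 0) stop_input("auto data range is zero (constant reference)")
    return(dr)
  }
  check_scalar_num(data_range, "data_range", lower = 0)
  data_range
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` in decibels; `Inf` for identical inputs.
#' The default data range is the reference image's dynamic range, which is
#' recorded in every [metrics_report()].
#'
#' @param x,ref images ([ct_image()] or matrices) of identical shape.
#' @param data_range positive number, or `"auto"` (max(ref) - min(ref)).
#' @return PSNR in dB (`Inf` when MSE is 0).
#' @export
psnr <- function(x, ref, data_range = "auto") {
  x <- as_values(x); ref <- as_values(ref)
  check_same_shape(x, ref)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  dr <- resolve_data_range(ref, data_range)
  10 * log10(dr^2 / mse)
}

# Separable Gaussian filtering with replicate edges, matching the standard
# windowed-SSIM computation (11 taps, sigma 1.5); the border half-window is
# cropped before averaging.
ssim_filter <- function(v, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  f1 <- function(m) {
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * mp[seq(t, t + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(f1(t(f1(v))))
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5) and the
#' standard stabilizers `(0.01 R)^2` and `(0.03 R)^2`, computed with
#' population (non-sample) local moments; the half-window border is cropped
#' before averaging, as in the reference formulation.
#'
#' @inheritParams psnr
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, ref, data_range = "auto") {
  x <- as_values(x); ref <- as_values(ref)
  check_same_shape(x, ref)
  win <- 11L
  if (nrow(x) < win || ncol(x) < win)
    stop_input("images smaller than the 11x11 SSIM window")
  dr <- resolve_data_range(ref, data_range)
  sigma <- 1.5
  r <- (win - 1L) %/% 2L
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  ux <- ssim_filter(x, k); uy <- ssim_filter(ref, k)
  uxx <- ssim_filter(x * x, k); uyy <- ssim_filter(ref * ref, k)
  uxy <- ssim_filter(x * ref, k)
  vx <- uxx - ux^2; vy <- uyy - uy^2; vxy <- uxy - ux * uy
  c1 <- (0.01 * dr)^2; c2 <- (0.03 * dr)^2
  smap <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
          ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  core <- smap[(r + 1L):(nrow(x) - r), (r + 1L):(ncol(x) - r)]
  mean(core)
}

#' Pearson correlation coefficient between two images
#'
#' Overall linear similarity over all pixels, in `[-1, 1]`. Errors on
#' constant input, where the coefficient is undefined.
#'
#' @param x,ref images of identical shape, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
cc <- function(x, ref) {
  x <- as_values(x); ref <- as_values(ref)
  check_same_shape(x, ref)
  if (sd(x) == 0 || sd(ref) == 0)
    stop_input("correlation is undefined for constant images")
  cor(as.vector(x), as.vector(ref))
}

#' Combined image-quality report
#'
#' PSNR, SSIM and Pearson correlation of `x` against `ref`, with the data
#' range that was used. For identical (non-constant) inputs SSIM and CC are
#' 1 and PSNR is the `Inf` sentinel.
#'
#' @inheritParams psnr
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(x, ref, data_range = "auto") {
  xv <- as_values(x); rv <- as_values(ref)
  dr <- resolve_data_range(rv, data_range)
  structure(
    list(psnr_db = psnr(xv, rv, dr), ssim = ssim(xv, rv, dr),
         cc = cc(xv, rv), data_range = dr),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> PSNR %.2f dB | SSIM %.4f | CC %.4f (data range %.4g)\n",
              x$psnr_db, x$ssim, x$cc, x$data_range))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname metrics_report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(metric = c("psnr_db", "ssim", "cc"),
                 value = c(x$psnr_db, x$ssim, x$cc))
}
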