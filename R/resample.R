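#' Halve an image by 2x2 block averaging
#'
#' Each output pixel is the arithmetic mean of its 2x2 source block; the
#' pixel size doubles. This is the downsampling step of the half-resolution
#' prior protocol (training and fabricating priors at half size limits the
#' transfer of fine-scale hallucinated structure).
#'
#' @param image a [ct_image()] with even row and column counts.
#' @return A [ct_image()] with dimensions exactly halved.
#' @seealso [upsample_bilinear()] for the matching upsampling step.
#' @export
downsample_half <- function(image) {
  v <- image$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% 2L != 0L || nc %% 2L != 0L)
    stop_input("downsample_half needs even dimensions; pad or crop explicitly")
  odd_r <- seq(1, nr, 2); evn_r <- seq(2, nr, 2)
  odd_c <- seq(1, nc, 2); evn_c <- seq(2, nc, 2)
  out <- (v[odd_r, odd_c, drop = FALSE] + v[evn_r, odd_c, drop = FALSE] +
          v[odd_r, evn_c, drop = FALSE] + v[evn_r, evn_c, drop = FALSE]) / 4
  ct_image(out, image$pixel_size * 2)
}

#' Bilinear upsampling
#'
#' Resamples an image to a larger grid by bilinear interpolation with
#' pixel-center alignment (the corner pixel centers of source and target
#' coincide), so constant images are preserved exactly.
#'
#' @param image a [ct_image()].
#' @param target_rows,target_cols output dimensions; each must be at least
#'   the corresponding source dimension.
#' @return A [ct_image()] of size `target_rows x target_cols`; the pixel
#'   size is rescaled by the row-axis ratio.
#' @export
upsample_bilinear <- function(image, target_rows, target_cols) {
  v <- image$values
  nr <- nrow(v); nc <- ncol(v)
  target_rows <- check_count(target_rows, "target_rows")
  target_cols <- check_count(target_cols, "target_cols")
  if (target_rows < nr || target_cols < nc)
    stop_input("target dimensions must be >= source dimensions")
  rf <- if (target_rows == 1L) rep(1, 1) else seq(1, nr, length.out = target_rows)
  cf <- if (target_cols == 1L) rep(1, 1) else seq(1, nc, length.out = target_cols)
  r0 <- pmin(floor(rf), nr - 1L); r0[nr == 1L] <- 1L
  c0 <- pmin(floor(cf), nc - 1L); c0[nc == 1L] <- 1L
  if (nr == 1L) { r0 <- rep(1L, target_rows); wr <- rep(0, target_rows) } else wr <- rf - r0
  if (nc == 1L) { c0 <- rep(1L, target_cols); wc <- rep(0, target_cols) } else wc <- cf - c0
  r1 <- pmin(r0 + 1L, nr)
  c1 <- pmin(c0 + 1L, nc)
  A <- v[r0, c0, drop = FALSE]; B <- v[r1, c0, drop = FALSE]
  C <- v[r0, c1, drop = FALSE]; D <- v[r1, c1, drop = FALSE]
  WR <- matrix(wr, target_rows, target_cols)
  WC <- matrix(wc, target_rows, target_cols, byrow = TRUE)
  out <- (1 - WR) * (1 - WC) * A + WR * (1 - WC) * B +
         (1 - WR) * WC * C + WR * WC * D
  ct_image(out, image$pixel_size * nr / target_rows)
}
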