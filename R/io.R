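# File I/O. Images travel as single-channel float TIFF (affinely rescaled
# to [0,1], slope/intercept in a JSON sidecar, because TIFF float storage
# outside [0,1] is undefined in the underlying library) or as NIfTI
# (lossless float32, pixel size in the header). Sinograms travel as a CSV
# matrix plus a JSON metadata sidecar (angles, detector spacing, beam type).

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
}

#' Write / read an image as float TIFF with a JSON sidecar
#'
#' Values are affinely mapped to [0, 1] for storage; the slope/intercept
#' and the pixel size live in `<path>.json` and the roundtrip restores the
#' original values to float32 precision.
#'
#' @param image a [ct_image()].
#' @param path output path (`.tif`).
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly (writer); a [ct_image()] (reader).
#' @export
write_image_tiff <- function(image, path, meta = list()) {
  v <- image$values
  lo <- min(v); rg <- max(v) - lo
  if (rg <= 0) rg <- 1
  tiff::writeTIFF((v - lo) / rg, path, bits.per.sample = 32L)
  write_sidecar(path, c(list(format = "ct_image_tiff", pixel_size = image$pixel_size,
                             slope = rg, intercept = lo), meta))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta <- read_sidecar(path)
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  ct_image(v * meta$slope + meta$intercept, meta$pixel_size)
}

#' Write / read an image as NIfTI
#'
#' Lossless float32 storage with the pixel size in the header.
#'
#' @param image a [ct_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (writer); a [ct_image()] (reader).
#' @export
write_image_nifti <- function(image, path) {
  px <- image$pixel_size
  img <- RNifti::asNifti(image$values,
                         reference = list(pixdim = c(-1, px, px, 1, 1, 1, 1, 1)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  px <- RNifti::pixdim(img)[1]
  ct_image(matrix(as.numeric(img), nrow(img)), px)
}

#' Write / read a sinogram as CSV + JSON sidecar
#'
#' The CSV holds the (views x bins) matrix; the sidecar records angles,
#' detector spacing and beam type, plus any extra metadata.
#'
#' @param sino a [ct_sinogram()].
#' @param path output path (`.csv`).
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly (writer); a [ct_sinogram()] (reader).
#' @export
write_sinogram <- function(sino, path, meta = list()) {
  write.csv(sino$values, path, row.names = FALSE)
  write_sidecar(path, c(list(format = "ct_sinogram_csv", angles = sino$angles,
                             det_spacing = sino$det_spacing,
                             beam_type = sino$beam_type), meta))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- read_sidecar(path)
  v <- as.matrix(read.csv(path, check.names = FALSE))
  dimnames(v) <- NULL
  ct_sinogram(v, meta$angles, meta$det_spacing %||% NA_real_,
              meta$beam_type %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
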