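#' Write and read BFP images as 32-bit float TIFF
#'
#' Amplitude (or normalized intensity) images are stored as-is; phase
#' images are mapped from \eqn{(-\pi, \pi]} to [0, 1] via
#' \eqn{(\phi + \pi) / 2\pi} so every value is representable regardless of
#' the TIFF reader's clamping conventions, and mapped back on read.
#'
#' @param image Numeric matrix in [0, 1] (\code{write_image_tiff}) or phase
#'   matrix in rad (\code{write_phase_tiff}).
#' @param path Output file path.
#' @return The path (writers, invisibly) or the matrix (readers).
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image), min(image) >= -1e-9, max(image) <= 1 + 1e-9)
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname write_image_tiff
#' @export
write_phase_tiff <- function(image, path) {
  write_image_tiff((wrap_phase(image) + pi) / (2 * pi), path)
}

#' @rdname write_image_tiff
#' @export
read_phase_tiff <- function(path) {
  wrap_phase(read_image_tiff(path) * 2 * pi - pi)
}

#' Export a full complex BFP field as a two-plane real/imaginary array
#'
#' @param field A \code{bfp_field}.
#' @param path Output \code{.rds} path.
#' @return The path, invisibly.
#' @export
write_bfp_field <- function(field, path) {
  stopifnot(inherits(field, "bfp_field"))
  saveRDS(list(re = Re(field$field), im = Im(field$field),
               size_px = field$grid$size_px, na = field$grid$na), path)
  invisible(path)
}

#' Export dataset records as TIFF pairs for inspection
#'
#' @param dataset An \code{spr_dataset}.
#' @param dir Output directory (created if missing).
#' @param indices Record indices to export (default: all).
#' @return Character vector of written file paths, invisibly.
#' @export
export_record_tiffs <- function(dataset, dir, indices = NULL) {
  stopifnot(inherits(dataset, "spr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  indices <- indices %||% seq_along(dataset$records)
  paths <- unlist(lapply(indices, function(i) {
    r <- dataset$records[[i]]
    pa <- file.path(dir, sprintf("record%04d_amplitude.tif", i))
    pp <- file.path(dir, sprintf("record%04d_phase.tif", i))
    write_image_tiff(r$input, pa)
    write_phase_tiff(r$label, pp)
    c(pa, pp)
  }))
  invisible(paths)
}
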