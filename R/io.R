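# TIFF input/output for raw light-field frames.

#' Read / write raw light-field images as TIFF
#'
#' Images are written as single-channel 32-bit float TIFF.  Intensities are
#' stored as-is (no rescaling), so rendered images round-trip to within float
#' precision.
#'
#' @param image Matrix or `lfm_raw`.
#' @param path File path.
#' @return `write_lightfield_tiff()` returns `path` invisibly;
#'   `read_lightfield_tiff()` returns an `lfm_raw` (without configuration
#'   metadata).
#' @export
write_lightfield_tiff <- function(image, path) {
  img <- unclass(image)
  storage.mode(img) <- "double"
  tiff::writeTIFF(img, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_lightfield_tiff
#' @export
read_lightfield_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  as_lfm_raw(img, NULL)
}
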