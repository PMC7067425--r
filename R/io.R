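# Thin IO layer over the tiff/png packages (Suggests): float TIFF for
# windows and probability maps, PNG/TIFF reading for input images.

.needPkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this operation", call. = FALSE)
}

#' Write a window as a single-channel float TIFF
#'
#' Exports the weight grid of a [Window2D-class] (or any numeric matrix) as
#' a 32-bit float TIFF for visual inspection of the interior, border and
#' corner window shapes.
#'
#' @param window a [Window2D-class] or numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWindowTiff <- function(window, path) {
  .needPkg("tiff")
  w <- if (is(window, "Window2D")) windowWeights(window) else window
  tiff::writeTIFF(w, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a probability map as a multi-channel float TIFF
#'
#' @param pm a [ProbabilityMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProbabilityMapTiff <- function(pm, path) {
  .needPkg("tiff")
  tiff::writeTIFF(probValues(pm), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' Read a grayscale or multi-channel image
#'
#' Reads a PNG or TIFF into a numeric matrix (grayscale) or `H x W x C`
#' array. Multi-sample images are returned with their channels intact.
#'
#' @param path input file (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix or array with values in `[0, 1]`.
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = { .needPkg("png"); png::readPNG(path) },
    tif = ,
    tiff = { .needPkg("tiff"); tiff::readTIFF(path) },
    stop("unsupported image format '.", ext, "'", call. = FALSE))
  if (length(dim(img)) == 3L && dim(img)[3] == 1L)
    img <- img[, , 1L]
  img
}
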