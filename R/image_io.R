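#' Read a microscopy image
#'
#' Reads an 8- or 16-bit TIFF or PNG into an H x W x C array with intensities
#' scaled to `[0, 1]` (the maximum representable value of the bit depth maps
#' to 1). An alpha channel, if present, is dropped.
#'
#' @param path file path ending in .tif, .tiff or .png
#' @return numeric array (H, W, C), C in {1, 3}
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  )
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (length(dim(img)) != 3L) stop("unsupported image layout in ", path)
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- img[, , 1L, drop = FALSE]
  as_image(clamp01(img))
}

#' Write an image to TIFF or PNG
#'
#' Values are clipped to `[0, 1]` and quantized at the requested bit depth
#' (PNG is always written 8-bit).
#'
#' @param img H x W x C array in `[0, 1]`
#' @param path destination path (.tif/.tiff/.png)
#' @param bits 8 or 16 (TIFF only)
#' @export
write_image <- function(img, path, bits = 8L) {
  img <- clamp01(as_image(img))
  if (dim(img)[3] == 1L) dim(img) <- dim(img)[1:2]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
    png = png::writePNG(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
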