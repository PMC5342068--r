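#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' Returns the raster as an `H x W x 3` array of values in `[0, 255]`.
#' Grayscale images are replicated to three channels; an alpha channel, if
#' present, is dropped with a warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return `H x W x 3` numeric array in `[0, 255]`.
#' @export
read_ihc_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (is.null(dim(img)) || length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3L] == 4L) {
    warning("alpha channel dropped from ", basename(path))
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3L] == 2L) {      # gray + alpha
    warning("alpha channel dropped from ", basename(path))
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  }
  if (dim(img)[3L] != 3L) {
    stop("expected a 1-, 3- or 4-channel image", call. = FALSE)
  }
  round(img * 255)
}

#' Write a binary mask or an RGB image as PNG
#'
#' @param x Logical/0-1 matrix (written as grayscale) or `H x W x 3` array
#'   in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  if (is.matrix(x)) {
    png::writePNG(matrix(as.numeric(x), nrow(x), ncol(x)), path)
  } else {
    png::writePNG(x / 255, path)
  }
  invisible(path)
}

#' Append per-image quantification rows to a metrics CSV
#'
#' @param quants List of `"marker_quant"` objects (or a data.frame).
#' @param path Output CSV path.
#' @param patient_id,slide_id Optional identifier columns recycled across
#'   rows.
#' @return The written data.frame, invisibly.
#' @export
write_metrics_csv <- function(quants, path, patient_id = NA_character_,
                              slide_id = NA_character_) {
  df <- if (is.data.frame(quants)) quants else
    do.call(rbind, lapply(quants, as.data.frame))
  df <- cbind(patient_id = patient_id, slide_id = slide_id, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
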