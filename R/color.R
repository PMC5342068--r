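#' Convert an 8-bit RGB image to CIELAB
#'
#' Brightfield IHC images are acquired as sRGB; segmentation operates in the
#' CIELAB space, whose (a*, b*) plane carries the chromatic information that
#' distinguishes DAB brown, hematoxylin blue, eosin pink and white lumen
#' independently of staining intensity. Conversion assumes the sRGB transfer
#' function and the D65 reference white, the convention for color camera
#' output.
#'
#' @param image An `H x W x 3` numeric array of 8-bit sRGB values in
#'   `[0, 255]` (as returned by [read_ihc_image()]), or an `N x 3` matrix of
#'   such values.
#' @return An array (or matrix) of the same shape holding L* in `[0, 100]`
#'   and a*, b* (signed, nominally within `[-128, 128]`).
#' @seealso [extract_ab()], [read_ihc_image()]
#' @examples
#' img <- array(255, dim = c(2, 2, 3))     # uniform white
#' lab <- rgb_to_lab(img)
#' lab[1, 1, ]                             # ~ (100, 0, 0)
#' @export
rgb_to_lab <- function(image) {
  mat_in <- is.matrix(image)
  if (mat_in) {
    if (ncol(image) != 3L) stop("RGB matrix must have 3 columns", call. = FALSE)
    m <- image
  } else {
    d <- dim(image)
    if (length(d) != 3L || d[3L] != 3L) {
      stop("`image` must be an H x W x 3 array of RGB values", call. = FALSE)
    }
    m <- cbind(as.vector(image[, , 1L]),
               as.vector(image[, , 2L]),
               as.vector(image[, , 3L]))
  }
  if (anyNA(m) || min(m) < 0 || max(m) > 255) {
    stop("RGB values must lie in [0, 255]", call. = FALSE)
  }
  lab <- farver::convert_colour(m, from = "rgb", to = "lab")
  if (mat_in) {
    colnames(lab) <- c("L", "a", "b")
    return(lab)
  }
  out <- array(lab, dim = dim(image))
  dimnames(out) <- list(NULL, NULL, c("L", "a", "b"))
  out
}

#' Extract the (a*, b*) chromaticity plane from a CIELAB image
#'
#' Drops L* and flattens the image to an `N x 2` point matrix (column-major
#' pixel order, so point `i` maps back to pixel `i` of the `H x W` raster by
#' linear indexing). This two-dimensional chromaticity representation is the
#' feature space in which pixel clustering is performed.
#'
#' @param lab An `H x W x 3` CIELAB array from [rgb_to_lab()].
#' @return An `N x 2` matrix with columns `a`, `b` and attribute
#'   `"image_dim" = c(H, W)`; `N = H * W`.
#' @examples
#' lab <- rgb_to_lab(array(128, dim = c(4, 4, 3)))
#' ab <- extract_ab(lab)
#' dim(ab)                       # 16 x 2
#' matrix(ab[, "a"], 4, 4)       # reconstructs the a* plane exactly
#' @export
extract_ab <- function(lab) {
  d <- dim(lab)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("`lab` must be an H x W x 3 CIELAB array", call. = FALSE)
  }
  pts <- cbind(a = as.vector(lab[, , 2L]), b = as.vector(lab[, , 3L]))
  attr(pts, "image_dim") <- d[1:2]
  pts
}

image_dim_of <- function(points) {
  d <- attr(points, "image_dim")
  if (is.null(d)) NULL else as.integer(d)
}
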