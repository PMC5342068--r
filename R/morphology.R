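#' Connected-component labeling of a binary mask
#'
#' Finds maximal sets of mutually adjacent foreground pixels under 4- or
#' 8-connectivity. Components are labeled in raster-scan order (column-major,
#' matching R matrix storage): the component containing the first foreground
#' pixel gets label 1, and so on, so labeling is deterministic.
#'
#' Internally the foreground pixel-adjacency graph is built and its
#' connected components extracted with \pkg{igraph}.
#'
#' @param mask Logical (or 0/1) `H x W` matrix.
#' @param connectivity 8 (default; diagonal neighbors touch) or 4.
#' @return List with `labels` (integer `H x W` matrix, 0 = background),
#'   `n` (component count) and `sizes` (integer vector of pixel counts,
#'   indexed by label).
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
#' connected_components(m, connectivity = 8)$n   # 1 (diagonal touch)
#' connected_components(m, connectivity = 4)$n   # 2
#' @export
connected_components <- function(mask, connectivity = 8) {
  m <- validate_mask(mask)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  h <- nrow(m); w <- ncol(m)
  labels <- matrix(0L, h, w)
  fg <- which(m)
  if (length(fg) == 0L) {
    return(list(labels = labels, n = 0L, sizes = integer(0)))
  }
  # vertex ids = position within fg; map pixel index -> vertex id
  vid <- integer(h * w)
  vid[fg] <- seq_along(fg)

  row <- (fg - 1L) %% h + 1L
  col <- (fg - 1L) %/% h + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))              # down, right
  if (connectivity == 8) {
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))  # two diagonals
  }
  edges <- integer(0)
  for (o in offs) {
    r2 <- row + o[1L]; c2 <- col + o[2L]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- vid[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(vid[fg[ok]][hit], vid[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel so that components appear in raster-scan order of first pixel
  first_seen <- !duplicated(comp)
  remap <- integer(max(comp))
  remap[comp[first_seen]] <- seq_len(sum(first_seen))
  lab <- remap[comp]
  labels[fg] <- lab
  list(labels = labels, n = max(lab), sizes = tabulate(lab))
}

#' Remove small connected components from a mask
#'
#' Zeroes every connected component with fewer than `min_pixels` pixels and
#' keeps larger components verbatim. In the cytoplasmic-marker pipeline this
#' step discards small chromatically-brown debris (and nucleus-sized
#' objects) so that only contiguous cytoplasmic staining is measured; the
#' default threshold of 5000 pixels corresponds to the acquisition scale the
#' method was developed at and should be rescaled with image resolution.
#'
#' @param mask Logical (or 0/1) `H x W` matrix.
#' @param min_pixels Minimum component size to keep (components strictly
#'   smaller are removed). Default 5000.
#' @param connectivity Passed to [connected_components()]; default 8.
#' @return Logical matrix of the same shape.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[1:2, 1:2] <- TRUE; m[6, 6] <- TRUE
#' sum(size_filter(m, min_pixels = 2))   # 4: the singleton is removed
#' @export
size_filter <- function(mask, min_pixels = 5000, connectivity = 8) {
  m <- validate_mask(mask)
  stopifnot_scalar_number(min_pixels, "min_pixels", min = 1)
  cc <- connected_components(m, connectivity = connectivity)
  if (cc$n == 0L) return(m)
  keep <- which(cc$sizes >= min_pixels)
  out <- matrix(cc$labels %in% keep, nrow(m), ncol(m))
  out
}

#' Fraction of foreground pixels in a mask
#'
#' The area readout of the segmentation pipeline: number of non-zero pixels
#' divided by the total pixel count of the image.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return A fraction in `[0, 1]`.
#' @examples
#' pixel_fraction(matrix(c(1, 0, 0, 0), 2, 2))   # 0.25
#' @export
pixel_fraction <- function(mask) {
  m <- validate_mask(mask)
  sum(m) / length(m)
}

validate_mask <- function(mask) {
  if (is.null(dim(mask)) || length(dim(mask)) != 2L) {
    stop("`mask` must be a 2-d matrix", call. = FALSE)
  }
  if (is.logical(mask)) return(mask)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) {
    stop("`mask` values must be 0/1 or logical", call. = FALSE)
  }
  mask == 1
}
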