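#' Pipeline configuration
#'
#' Collects every tunable of the segmentation/quantification pipeline with
#' its default. Values not supplied keep their defaults; unknown names are
#' an error, so typos fail loudly.
#'
#' @param seed Integer seed used by every stochastic step (default 0).
#' @param k First-tier cluster count (default 3: tumor, interstitium,
#'   lumen / stain groups).
#' @param restarts,tol,max_iter k-means controls (see [kmeans_ab()]).
#' @param min_component_px Size-filter threshold in pixels (default 5000,
#'   appropriate at the acquisition scale the method was developed for;
#'   rescale proportionally to image area at other resolutions).
#' @param selection Cluster-selection spec for the marker cluster: list
#'   with `mode` in `"auto"` (chromaticity heuristic), `"fixed"` (use
#'   `index`), or `"interactive"` (write previews, read a choice file);
#'   optional `index`, and `dir` for interactive mode.
#' @param nucleus_px_band Length-2 range of plausible nucleus-scale
#'   component areas in pixels (default `c(5, 2000)`); used both for
#'   sub-mask selection (pixel-weighted median component size) and for
#'   counting components as nuclei.
#' @param dab_score_min Minimum DAB-brownness score (`a* + b*`) for a
#'   cluster/sub-mask to count as DAB-stained (default 20); below it the
#'   auto selection is flagged low-confidence.
#' @param blue_b_max Maximum b* for a sub-mask to count as
#'   hematoxylin-blue nuclear staining (default -32: hematoxylin is
#'   strongly blue, whereas eosinophilic/pale tissue rarely drops below
#'   about -28).
#' @param tumor_l_max Maximum mean L* for a cluster to count as cell-dense
#'   tissue in tumor-area estimation (default 75).
#' @param tumor_selection Mode for [quantify_tumor_area()]: `"auto"`
#'   (union of clusters darker than `tumor_l_max`), `"darkest"` (single
#'   lowest-L* cluster) or `"fixed"` (use `tumor_index`).
#' @param tumor_index Cluster index for `tumor_selection = "fixed"`.
#' @return A list of class `"ihc_config"`.
#' @export
ihc_config <- function(seed = 0, k = 3, restarts = 10, tol = 1e-6,
                       max_iter = 300, min_component_px = 5000,
                       selection = list(mode = "auto", index = NULL,
                                        dir = NULL),
                       nucleus_px_band = c(5, 2000),
                       dab_score_min = 20, blue_b_max = -32,
                       tumor_l_max = 75,
                       tumor_selection = c("auto", "darkest", "fixed"),
                       tumor_index = NULL) {
  tumor_selection <- match.arg(tumor_selection)
  if (!selection$mode %in% c("auto", "fixed", "interactive")) {
    stop("selection$mode must be auto, fixed or interactive", call. = FALSE)
  }
  stopifnot_scalar_number(min_component_px, "min_component_px", min = 1)
  if (length(nucleus_px_band) != 2L || nucleus_px_band[1L] > nucleus_px_band[2L]) {
    stop("`nucleus_px_band` must be an increasing length-2 range",
         call. = FALSE)
  }
  structure(
    list(seed = seed, k = k, restarts = restarts, tol = tol,
         max_iter = max_iter, min_component_px = min_component_px,
         selection = selection, nucleus_px_band = nucleus_px_band,
         dab_score_min = dab_score_min, blue_b_max = blue_b_max,
         tumor_l_max = tumor_l_max, tumor_selection = tumor_selection,
         tumor_index = tumor_index),
    class = "ihc_config"
  )
}

#' Select the marker (DAB) cluster from a first-tier segmentation
#'
#' Mechanizes the expert step of identifying which chromatic cluster
#' carries the cytoplasmic DAB signal. In `"auto"` mode the cluster whose
#' centroid maximizes the DAB-brownness score `s = a* + b*` is chosen
#' (brown has both coordinates positive; hematoxylin has b* strongly
#' negative; achromatic background scores near 0). If the best score falls
#' below `dab_score_min` the selection is flagged `"low_confidence"`.
#' `"fixed"` mode returns the configured cluster regardless of color;
#' `"interactive"` mode writes one preview mask PNG per cluster to
#' `selection$dir` and reads the chosen index from a `choice` file there.
#'
#' @param seg An `"ihc_segmentation"` from [kmeans_ab()] whose `labels` is
#'   an `H x W` matrix.
#' @param selection List with `mode` and optionally `index` / `dir`; see
#'   [ihc_config()].
#' @param dab_score_min Low-confidence threshold on the winning score.
#' @return Logical `H x W` mask with attributes `"cluster"` (chosen index)
#'   and `"flags"`.
#' @export
select_marker_cluster <- function(seg, selection = list(mode = "auto"),
                                  dab_score_min = 20) {
  stopifnot(inherits(seg, "ihc_segmentation"))
  if (!is.matrix(seg$labels)) {
    stop("segmentation lacks image dimensions", call. = FALSE)
  }
  flags <- character(0)
  mode <- selection$mode %||% "auto"
  if (mode == "fixed") {
    idx <- selection$index
    if (is.null(idx) || idx < 1L || idx > seg$k) {
      stop("fixed cluster index out of range", call. = FALSE)
    }
  } else if (mode == "interactive") {
    idx <- interactive_cluster_choice(seg, selection$dir)
  } else {
    score <- seg$centroids[, 1L] + seg$centroids[, 2L]
    idx <- which.max(score)
    if (max(score) < dab_score_min) flags <- c(flags, "low_confidence")
  }
  mask <- seg$labels == idx
  attr(mask, "cluster") <- as.integer(idx)
  attr(mask, "flags") <- flags
  mask
}

interactive_cluster_choice <- function(seg, dir) {
  if (is.null(dir)) {
    stop("interactive selection needs selection$dir", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_len(seg$k)) {
    write_mask_png(seg$labels == j,
                   file.path(dir, sprintf("cluster_%d.png", j)))
  }
  choice_file <- file.path(dir, "choice")
  if (!file.exists(choice_file)) {
    stop("previews written to ", dir,
         "; record the chosen cluster index in the `choice` file there",
         call. = FALSE)
  }
  idx <- as.integer(readLines(choice_file, n = 1L))
  if (is.na(idx) || idx < 1L || idx > seg$k) {
    stop("invalid cluster index in choice file", call. = FALSE)
  }
  idx
}

#' Quantify a cytoplasmic DAB marker in one image
#'
#' The cytoplasmic-marker pipeline: CIELAB conversion, k-means (k = 3) on
#' the (a*, b*) plane, selection of the DAB cluster, removal of connected
#' components below `min_component_px` (debris and nucleus-scale objects),
#' and the pixel fraction of what remains. The raw fraction is also
#' normalized to the tumor-area fraction of the same image (see
#' [quantify_tumor_area()]), giving a marker density comparable across
#' images with different tissue content.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param config An [ihc_config()].
#' @param image_id Optional identifier carried into the result.
#' @return Object of class `"marker_quant"`: list with `image_id`, `mode`,
#'   `raw_fraction`, `tumor_fraction`, `normalized_fraction` (NA and
#'   flagged when the tumor fraction is 0) and `flags`.
#' @examples
#' syn <- generate_ihc_image(ihc_image_params(height = 96, width = 96,
#'                                            seed = 3))
#' cfg <- ihc_config(min_component_px = 150)
#' quantify_cytoplasmic_marker(syn$image, cfg)
#' @export
quantify_cytoplasmic_marker <- function(image, config = ihc_config(),
                                        image_id = NA_character_) {
  lab <- as_lab(image)
  ab <- extract_ab(lab)
  seg <- kmeans_ab(ab, k = config$k, seed = config$seed,
                   restarts = config$restarts, tol = config$tol,
                   max_iter = config$max_iter)
  mask <- select_marker_cluster(seg, config$selection,
                                dab_score_min = config$dab_score_min)
  flags <- attr(mask, "flags")
  filtered <- size_filter(mask, min_pixels = config$min_component_px)
  raw <- pixel_fraction(filtered)
  ta <- tumor_area_from_seg(seg, lab, config)
  flags <- c(flags, ta$flags)
  norm <- normalize_to_tumor(raw, ta$fraction)
  flags <- c(flags, attr(norm, "flags"))
  new_marker_quant(image_id, "cytoplasmic", raw, ta$fraction,
                   as.numeric(norm), flags)
}

#' Quantify a nuclear DAB marker in one image
#'
#' The two-tier pipeline: first-tier k = 3 chromatic clustering, second
#' tier k = 2 within each cluster, then automatic selection among the six
#' sub-masks of those that are (i) DAB-brown in mean chromaticity
#' (`mean a* + b* >= dab_score_min`) and (ii) composed of nucleus-scale
#' objects (median connected-component area inside `nucleus_px_band`).
#' The union of selected sub-masks is the nuclear-marker area; its pixel
#' fraction is normalized to the tumor-area fraction. If no sub-mask
#' passes, the raw fraction is 0 and the record is flagged
#' `"no_nuclear_submask"`.
#'
#' @inheritParams quantify_cytoplasmic_marker
#' @return A `"marker_quant"` object (see
#'   [quantify_cytoplasmic_marker()]), with the selected sub-mask indices
#'   in attribute `"selected_submasks"`.
#' @export
quantify_nuclear_marker <- function(image, config = ihc_config(),
                                    image_id = NA_character_) {
  lab <- as_lab(image)
  ms <- two_tier_cluster(lab, seed = config$seed,
                         restarts = config$restarts, tol = config$tol,
                         max_iter = config$max_iter)
  sel <- which(submask_is_dab(ms, config) &
                 submask_is_nucleus_scale(ms, config))
  flags <- character(0)
  if (length(sel) == 0L) {
    raw <- 0
    flags <- c(flags, "no_nuclear_submask")
  } else {
    union_mask <- Reduce(`|`, ms$masks[sel])
    raw <- pixel_fraction(union_mask)
  }
  seg1 <- ms$tier1
  ta <- tumor_area_from_seg(seg1, lab, config)
  flags <- c(flags, ta$flags)
  norm <- normalize_to_tumor(raw, ta$fraction)
  flags <- c(flags, attr(norm, "flags"))
  out <- new_marker_quant(image_id, "nuclear", raw, ta$fraction,
                          as.numeric(norm), flags)
  attr(out, "selected_submasks") <- sel
  out
}

submask_is_dab <- function(ms, config) {
  score <- ms$mean_ab[, 1L] + ms$mean_ab[, 2L]
  !is.na(score) & score >= config$dab_score_min
}

submask_is_blue <- function(ms, config) {
  b <- ms$mean_ab[, 2L]
  !is.na(b) & b <= config$blue_b_max
}

# A sub-mask is "nucleus scale" when the pixel-weighted median of its
# connected-component sizes (the component size seen by the median
# foreground pixel) falls inside the configured band. Pixel weighting
# keeps stray single-pixel noise speckle from dominating the median while
# still rejecting masks dominated by large tissue blobs.
submask_is_nucleus_scale <- function(ms, config) {
  band <- config$nucleus_px_band
  vapply(ms$masks, function(m) {
    if (!any(m)) return(FALSE)
    sz <- sort(connected_components(m)$sizes)
    cum <- cumsum(sz)
    med <- sz[which(cum >= cum[length(cum)] / 2)[1L]]
    med >= band[1L] && med <= band[2L]
  }, logical(1L))
}

#' Estimate the tumor-area fraction of an image
#'
#' First-tier k = 3 clustering nominally separates the three fundamental
#' tissue compartments: cell-dense tumor (chromatic, low L*), interstitium
#' (pale, intermediate L*) and lumen (near-white). The default `"auto"`
#' selection takes the union of all clusters whose mean L* falls below
#' `tumor_l_max`, because on DAB-stained sections the tumor compartment
#' (brown cytoplasm + blue nuclei + tissue base) legitimately spans more
#' than one chromatic cluster; `"darkest"` picks only the single lowest-L*
#' cluster (the classic three-compartment reading), and `"fixed"` uses
#' `tumor_index`. If no cluster is darker than the threshold the fraction
#' is 0 with a `"low_confidence"` flag (e.g. an all-white image).
#'
#' @inheritParams quantify_cytoplasmic_marker
#' @return Numeric tumor-area fraction in `[0, 1]` with attributes
#'   `"flags"` and `"selected_clusters"`.
#' @export
quantify_tumor_area <- function(image, config = ihc_config()) {
  lab <- as_lab(image)
  ab <- extract_ab(lab)
  seg <- kmeans_ab(ab, k = config$k, seed = config$seed,
                   restarts = config$restarts, tol = config$tol,
                   max_iter = config$max_iter)
  ta <- tumor_area_from_seg(seg, lab, config)
  out <- ta$fraction
  attr(out, "flags") <- ta$flags
  attr(out, "selected_clusters") <- ta$selected
  out
}

# Shared tumor-area logic on an existing first-tier segmentation.
tumor_area_from_seg <- function(seg, lab, config) {
  lstar <- as.vector(lab[, , 1L])
  labv <- as.vector(seg$labels)
  mean_l <- vapply(seq_len(seg$k),
                   function(j) mean(lstar[labv == j]), numeric(1L))
  flags <- character(0)
  sel <- switch(config$tumor_selection,
    fixed = {
      if (is.null(config$tumor_index) || config$tumor_index < 1L ||
          config$tumor_index > seg$k) {
        stop("tumor_index out of range", call. = FALSE)
      }
      config$tumor_index
    },
    darkest = which.min(mean_l),
    auto = which(mean_l < config$tumor_l_max)
  )
  if (config$tumor_selection == "darkest" &&
      mean_l[sel] >= config$tumor_l_max) {
    flags <- c(flags, "low_confidence")
    sel <- integer(0)
  }
  if (length(sel) == 0L) {
    if (!"low_confidence" %in% flags) flags <- c(flags, "low_confidence")
    return(list(fraction = 0, flags = flags, selected = integer(0),
                mean_l = mean_l))
  }
  frac <- sum(seg$sizes[sel]) / sum(seg$sizes)
  list(fraction = frac, flags = flags, selected = sel, mean_l = mean_l)
}

#' Count marker-positive nuclei in an image
#'
#' Builds a nucleus mask as the union of hematoxylin-blue and DAB-brown
#' nucleus-scale sub-masks of the two-tier clustering, takes its connected
#' components inside the configured nucleus size band as nuclei, and calls
#' a nucleus positive when more than half of its pixels fall in the
#' DAB-brown sub-mask union. The readout is the percentage of positive
#' nuclei among all nuclei, the standard proliferation / nuclear-marker
#' index.
#'
#' @inheritParams quantify_cytoplasmic_marker
#' @return Object of class `"nucleus_count"`: list with `image_id`,
#'   `positive_nuclei`, `total_nuclei`, `percent_positive` (NA and flagged
#'   `"no_nuclei"` when no nucleus is found) and `flags`.
#' @export
count_positive_nuclei <- function(image, config = ihc_config(),
                                  image_id = NA_character_) {
  lab <- as_lab(image)
  ms <- two_tier_cluster(lab, seed = config$seed,
                         restarts = config$restarts, tol = config$tol,
                         max_iter = config$max_iter)
  scale_ok <- submask_is_nucleus_scale(ms, config)
  dab <- submask_is_dab(ms, config)
  blue <- submask_is_blue(ms, config)
  nuclear_masks <- ms$masks[scale_ok & (dab | blue)]
  dab_masks <- ms$masks[dab]
  empty <- matrix(FALSE, ms$image_dim[1L], ms$image_dim[2L])
  nuc_mask <- Reduce(`|`, nuclear_masks, empty)
  dab_mask <- Reduce(`|`, dab_masks, empty)

  cc <- connected_components(nuc_mask)
  band <- config$nucleus_px_band
  keep <- which(cc$sizes >= band[1L] & cc$sizes <= band[2L])
  total <- length(keep)
  if (total == 0L) {
    return(structure(list(image_id = image_id, positive_nuclei = 0L,
                          total_nuclei = 0L,
                          percent_positive = NA_real_,
                          flags = "no_nuclei"),
                     class = "nucleus_count"))
  }
  labs <- cc$labels[dab_mask]
  dab_px <- tabulate(labs[labs > 0L], nbins = cc$n)
  positive <- sum(dab_px[keep] / cc$sizes[keep] > 0.5)
  structure(
    list(image_id = image_id, positive_nuclei = as.integer(positive),
         total_nuclei = as.integer(total),
         percent_positive = 100 * positive / total,
         flags = character(0)),
    class = "nucleus_count"
  )
}

#' @export
print.nucleus_count <- function(x, ...) {
  if (x$total_nuclei == 0L) {
    cat("nucleus count: no nuclei detected (flagged)\n")
  } else {
    cat(sprintf("nucleus count: %d / %d positive (%.1f%%)\n",
                x$positive_nuclei, x$total_nuclei, x$percent_positive))
  }
  invisible(x)
}

#' Normalize a marker fraction to the tumor-area fraction
#'
#' `normalized = raw / tumor` when `tumor > 0`; a zero tumor fraction
#' leaves the ratio undefined (`NA`, flagged `"zero_tumor_area"`), and such
#' records are excluded from downstream cohort statistics.
#'
#' @param raw_fraction Marker pixel fraction in `[0, 1]`.
#' @param tumor_fraction Tumor pixel fraction in `[0, 1]`.
#' @return Normalized fraction (>= 0) with attribute `"flags"`.
#' @examples
#' normalize_to_tumor(0.1, 0.5)   # 0.2
#' @export
normalize_to_tumor <- function(raw_fraction, tumor_fraction) {
  if (raw_fraction < 0 || raw_fraction > 1 ||
      tumor_fraction < 0 || tumor_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (tumor_fraction == 0) {
    out <- NA_real_
    attr(out, "flags") <- "zero_tumor_area"
    return(out)
  }
  out <- raw_fraction / tumor_fraction
  attr(out, "flags") <- character(0)
  out
}

new_marker_quant <- function(image_id, mode, raw, tumor, norm, flags) {
  structure(
    list(image_id = image_id, mode = mode, raw_fraction = raw,
         tumor_fraction = tumor, normalized_fraction = norm,
         flags = unique(flags)),
    class = "marker_quant"
  )
}

#' @export
print.marker_quant <- function(x, ...) {
  cat(sprintf(
    "%s marker quantification%s\n  raw %.4f | tumor %.4f | normalized %s%s\n",
    x$mode,
    if (is.na(x$image_id)) "" else paste0(" [", x$image_id, "]"),
    x$raw_fraction, x$tumor_fraction,
    if (is.na(x$normalized_fraction)) "NA" else
      sprintf("%.4f", x$normalized_fraction),
    if (length(x$flags)) paste0(" | flags: ", paste(x$flags, collapse = ","))
    else ""))
  invisible(x)
}

#' @export
as.data.frame.marker_quant <- function(x, ...) {
  data.frame(image_id = x$image_id, mode = x$mode,
             raw_fraction = x$raw_fraction,
             tumor_fraction = x$tumor_fraction,
             normalized_fraction = x$normalized_fraction,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
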