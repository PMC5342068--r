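#' Parameters for the synthetic IHC image generator
#'
#' Bundles the knobs of [generate_ihc_image()] with defaults emulating a
#' DAB-stained, hematoxylin-counterstained colorectal tumor section: white
#' glandular lumen, pale pink interstitium, a chromatically dark tumor
#' compartment containing brown (DAB) cytoplasmic staining, and blue
#' elliptical nuclei of which a configurable fraction are rendered
#' DAB-positive (brown).
#'
#' Default stain colors are chosen so the four compartments are well
#' separated on the CIELAB (a*, b*) plane: DAB brown has a* and b* both
#' positive, hematoxylin blue has strongly negative b*, interstitial pink
#' has positive a* with near-zero b*, and lumen white is achromatic.
#'
#' @param height,width Image size in pixels (default 256).
#' @param tumor_coverage Fraction of the image occupied by tumor (default
#'   0.55).
#' @param interstitium_coverage Fraction occupied by interstitium; must fit
#'   in the non-tumor remainder (default half of it).
#' @param cytoplasm_dab_coverage Fraction of the image covered by DAB-brown
#'   cytoplasmic staining; carved out of the tumor region, so it must not
#'   exceed `tumor_coverage` (default 0.25).
#' @param n_nuclei Number of elliptical nuclei to place inside the tumor
#'   (default 120; fewer may fit, see the `n_nuclei` ground-truth field).
#' @param positive_nucleus_fraction Fraction of placed nuclei rendered
#'   DAB-brown (default 0.25).
#' @param nucleus_radius Range (min, max) of nucleus semi-major axis in
#'   pixels (default c(3.5, 6)).
#' @param colors Named list of mean 8-bit RGB triples for `dab`,
#'   `hematoxylin`, `interstitium`, `lumen`, `tumor_base`.
#' @param noise_sd Gaussian pixel noise SD in 8-bit units (default 4).
#' @param seed Integer seed (default 0).
#' @return A list of class `"ihc_image_params"`.
#' @export
ihc_image_params <- function(height = 256, width = 256,
                             tumor_coverage = 0.55,
                             interstitium_coverage = NULL,
                             cytoplasm_dab_coverage = 0.25,
                             n_nuclei = 120,
                             positive_nucleus_fraction = 0.25,
                             nucleus_radius = c(3.5, 6),
                             colors = list(
                               dab          = c(120, 70, 40),
                               hematoxylin  = c(60, 60, 130),
                               interstitium = c(240, 205, 218),
                               lumen        = c(245, 245, 245),
                               tumor_base   = c(140, 130, 185)),
                             noise_sd = 4, seed = 0) {
  stopifnot_scalar_number(height, "height", min = 1)
  stopifnot_scalar_number(width, "width", min = 1)
  for (nm in c("tumor_coverage", "cytoplasm_dab_coverage",
               "positive_nucleus_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (cytoplasm_dab_coverage > tumor_coverage) {
    stop("cytoplasm_dab_coverage cannot exceed tumor_coverage ",
         "(DAB cytoplasm lies inside the tumor)", call. = FALSE)
  }
  if (is.null(interstitium_coverage)) {
    interstitium_coverage <- (1 - tumor_coverage) / 2
  }
  if (tumor_coverage + interstitium_coverage > 1) {
    stop("tumor + interstitium coverage exceeds 1", call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         tumor_coverage = tumor_coverage,
         interstitium_coverage = interstitium_coverage,
         cytoplasm_dab_coverage = cytoplasm_dab_coverage,
         n_nuclei = as.integer(n_nuclei),
         positive_nucleus_fraction = positive_nucleus_fraction,
         nucleus_radius = nucleus_radius, colors = colors,
         noise_sd = noise_sd, seed = seed),
    class = "ihc_image_params"
  )
}

#' Generate a synthetic IHC-like image with exact ground truth
#'
#' Lays down a white-lumen background, a blob-shaped interstitial region,
#' a blob-shaped tumor region hitting the requested coverage exactly (up to
#' one pixel of rounding), DAB-brown cytoplasmic patches inside the tumor,
#' and elliptical nuclei (hematoxylin blue, with a seeded random subset
#' DAB-brown), then adds Gaussian pixel noise. Region geometry comes from
#' thresholded smooth random fields, so compartments are large contiguous
#' blobs like real tissue rather than salt-and-pepper.
#'
#' The returned ground truth holds the exact pixel masks used to paint the
#' image, so estimated area fractions can be scored against the truth
#' without rasterization ambiguity. The cytoplasm mask excludes pixels
#' later overpainted by nuclei (the truth describes what is visible).
#'
#' Generation is a pure function of the parameters: the same
#' `ihc_image_params` (including seed) reproduces the image byte for byte.
#'
#' @param params An [ihc_image_params()] object.
#' @return A list of class `"synthetic_ihc_image"`:
#'   \describe{
#'     \item{image}{`H x W x 3` integer array, 8-bit RGB;}
#'     \item{truth}{list of logical masks (`tumor`, `interstitium`,
#'       `lumen`, `cytoplasm_dab`, `nuclei`, `positive_nuclei`), the exact
#'       fractions derived from them, and nucleus bookkeeping
#'       (`n_nuclei`, `n_positive`, `nucleus_labels`).}
#'   }
#' @examples
#' syn <- generate_ihc_image(ihc_image_params(height = 96, width = 96,
#'                                            seed = 7))
#' syn$truth$tumor_fraction
#' @export
generate_ihc_image <- function(params = ihc_image_params()) {
  stopifnot(inherits(params, "ihc_image_params"))
  p <- params
  h <- p$height; w <- p$width; N <- h * w

  with_seed(p$seed, {
    # --- region geometry from smooth random fields -----------------------
    tumor <- top_k_mask(random_field(h, w, n_bumps = 5L),
                        round(N * p$tumor_coverage))
    inter_field <- random_field(h, w, n_bumps = 5L)
    inter_field[tumor] <- -Inf
    interstitium <- top_k_mask(inter_field, round(N * p$interstitium_coverage))
    lumen <- !(tumor | interstitium)

    cyt_field <- random_field(h, w, n_bumps = 4L)
    cyt_field[!tumor] <- -Inf
    cytoplasm <- top_k_mask(cyt_field, round(N * p$cytoplasm_dab_coverage))

    # --- nuclei: non-overlapping ellipses fully inside the tumor ---------
    nuc <- place_nuclei(tumor, p$n_nuclei, p$nucleus_radius)
    n_placed <- nuc$n
    n_pos <- round(p$positive_nucleus_fraction * n_placed)
    pos_ids <- if (n_pos > 0L) sample.int(n_placed, n_pos) else integer(0)
    nuclei <- nuc$labels > 0L
    positive <- matrix(nuc$labels %in% pos_ids, h, w)

    # --- paint -----------------------------------------------------------
    col <- p$colors
    r <- matrix(col$lumen[1L], h, w)
    g <- matrix(col$lumen[2L], h, w)
    b <- matrix(col$lumen[3L], h, w)
    paint <- function(mask, rgb) {
      r[mask] <<- rgb[1L]; g[mask] <<- rgb[2L]; b[mask] <<- rgb[3L]
    }
    paint(interstitium, col$interstitium)
    paint(tumor, col$tumor_base)
    paint(cytoplasm, col$dab)
    paint(nuclei, col$hematoxylin)
    paint(positive, col$dab)

    img <- array(0L, dim = c(h, w, 3L))
    img[, , 1L] <- r; img[, , 2L] <- g; img[, , 3L] <- b
    if (p$noise_sd > 0) {
      img <- img + array(stats::rnorm(3L * N, 0, p$noise_sd), dim = dim(img))
    }
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim = c(h, w, 3L))

    cyt_visible <- cytoplasm & !nuclei
    truth <- list(
      tumor = tumor, interstitium = interstitium, lumen = lumen,
      cytoplasm_dab = cyt_visible, nuclei = nuclei,
      positive_nuclei = positive,
      tumor_fraction = sum(tumor) / N,
      interstitium_fraction = sum(interstitium) / N,
      lumen_fraction = sum(lumen) / N,
      cytoplasm_fraction = sum(cyt_visible) / N,
      nuclei_fraction = sum(nuclei) / N,
      positive_nuclei_fraction = sum(positive) / N,
      n_nuclei = n_placed, n_positive = n_pos,
      nucleus_labels = nuc$labels
    )
    structure(list(image = img, truth = truth, params = p),
              class = "synthetic_ihc_image")
  })
}

#' @export
print.synthetic_ihc_image <- function(x, ...) {
  t <- x$truth
  cat(sprintf(
    "synthetic IHC image %d x %d: tumor %.3f, DAB cytoplasm %.3f,\n  %d nuclei (%d DAB-positive), interstitium %.3f, lumen %.3f\n",
    x$params$height, x$params$width, t$tumor_fraction,
    t$cytoplasm_fraction, t$n_nuclei, t$n_positive,
    t$interstitium_fraction, t$lumen_fraction))
  invisible(x)
}

#' @export
plot.synthetic_ihc_image <- function(x, ...) {
  img <- x$image / 255
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, ncol(img)), ylim = c(0, nrow(img)),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = "synthetic IHC image", ...)
  graphics::rasterImage(img, 0, 0, ncol(img), nrow(img))
  invisible(x)
}

# Smooth random field: sum of Gaussian bumps with random centers, widths
# and signed amplitudes, evaluated separably.
random_field <- function(h, w, n_bumps = 5L) {
  f <- matrix(0, h, w)
  s_min <- 0.15 * min(h, w); s_max <- 0.45 * min(h, w)
  for (i in seq_len(n_bumps)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    s <- stats::runif(1, s_min, s_max)
    amp <- stats::runif(1, 0.4, 1.2) * sample(c(-1, 1), 1, prob = c(.3, .7))
    f <- f + amp * (exp(-(seq_len(h) - cy)^2 / (2 * s^2)) %o%
                      exp(-(seq_len(w) - cx)^2 / (2 * s^2)))
  }
  f
}

# Mask of the k largest field values (deterministic tie-break by index),
# giving exact pixel-count coverage.
top_k_mask <- function(field, k) {
  m <- matrix(FALSE, nrow(field), ncol(field))
  if (k <= 0) return(m)
  k <- min(k, sum(is.finite(field)))
  ord <- order(field, decreasing = TRUE)
  m[ord[seq_len(k)]] <- TRUE
  m
}

# Rejection-sample ellipse nuclei fully inside `tumor`, centers separated
# enough that components never merge. Returns a label matrix (0 background).
place_nuclei <- function(tumor, n_nuclei, radius_range) {
  h <- nrow(tumor); w <- ncol(tumor)
  labels <- matrix(0L, h, w)
  if (n_nuclei < 1L) return(list(labels = labels, n = 0L))
  inside <- which(tumor)
  if (length(inside) == 0L) return(list(labels = labels, n = 0L))
  min_sep <- 2 * radius_range[2L] + 2
  centers <- matrix(numeric(0), ncol = 2L)
  placed <- 0L
  tries <- 0L
  max_tries <- 60L * n_nuclei
  while (placed < n_nuclei && tries < max_tries) {
    tries <- tries + 1L
    px <- inside[sample.int(length(inside), 1L)]
    cy <- (px - 1L) %% h + 1L
    cx <- (px - 1L) %/% h + 1L
    if (nrow(centers) > 0L &&
        min((centers[, 1L] - cy)^2 + (centers[, 2L] - cx)^2) < min_sep^2) {
      next
    }
    a <- stats::runif(1, radius_range[1L], radius_range[2L])
    b <- a * stats::runif(1, 0.55, 0.9)
    th <- stats::runif(1, 0, pi)
    box_r <- ceiling(a) + 1L
    ys <- max(1L, cy - box_r):min(h, cy + box_r)
    xs <- max(1L, cx - box_r):min(w, cx + box_r)
    dy <- ys - cy; dx <- xs - cx
    # rotated-ellipse membership on the bounding box
    u <- outer(dy, dx, function(y, x) x * cos(th) + y * sin(th))
    v <- outer(dy, dx, function(y, x) -x * sin(th) + y * cos(th))
    hit <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(hit)) next
    cells <- cbind(rep(ys, times = length(xs))[as.vector(hit)],
                   rep(xs, each = length(ys))[as.vector(hit)])
    idx <- (cells[, 2L] - 1L) * h + cells[, 1L]
    if (!all(tumor[idx])) next
    placed <- placed + 1L
    labels[idx] <- placed
    centers <- rbind(centers, c(cy, cx))
  }
  list(labels = labels, n = placed)
}

#' Generate a synthetic patient cohort with a target rank correlation
#'
#' Emulates a biomarker cohort in which each patient contributes several
#' images and two tumor-normalized marker measurements (cytoplasmic c-Cbl
#' and nuclear beta-catenin) are negatively associated across patients.
#' Patient-level latent values are drawn from a bivariate Gaussian copula
#' whose Pearson parameter is set to `2 * sin(pi * rho_s / 6)` so the
#' population Spearman correlation equals `target_spearman`; latents are
#' mapped to lognormal marker scales (strictly nonnegative, right-skewed,
#' matching normalized pixel fractions), and per-image values add
#' within-patient lognormal noise representing intra-tumor heterogeneity.
#'
#' @param n_patients Number of patients (default 83).
#' @param images_per_patient Images per patient: a single count (default 5)
#'   or a vector of length `n_patients` for unequal designs.
#' @param target_spearman Target patient-level Spearman correlation
#'   (default -0.64); must lie in (-1, 1).
#' @param meanlog,sdlog Length-2 vectors giving the lognormal location and
#'   scale of the two markers (order: bcat, cbl) across patients.
#' @param within_patient_sd Log-scale SD of the within-patient,
#'   between-image noise (default 0.25).
#' @param seed Integer seed (default 0).
#' @return A `data.frame` of per-image records with columns `patient_id`,
#'   `image_id`, `normalized_bcat`, `normalized_cbl`; attribute
#'   `"patient_truth"` holds the latent patient-level values.
#' @examples
#' rec <- generate_cohort(seed = 1)
#' nrow(rec)   # 415 = 83 patients x 5 images
#' @export
generate_cohort <- function(n_patients = 83, images_per_patient = 5,
                            target_spearman = -0.64,
                            meanlog = c(bcat = log(0.05), cbl = log(0.30)),
                            sdlog = c(bcat = 0.8, cbl = 0.6),
                            within_patient_sd = 0.25, seed = 0) {
  stopifnot_scalar_number(n_patients, "n_patients", min = 2)
  if (abs(target_spearman) >= 1) {
    stop("|target_spearman| must be < 1", call. = FALSE)
  }
  n_img <- if (length(images_per_patient) == 1L) {
    rep(as.integer(images_per_patient), n_patients)
  } else {
    if (length(images_per_patient) != n_patients) {
      stop("images_per_patient must have length 1 or n_patients",
           call. = FALSE)
    }
    as.integer(images_per_patient)
  }
  if (any(n_img < 1L)) stop("each patient needs >= 1 image", call. = FALSE)

  r <- 2 * sin(pi * target_spearman / 6)   # Spearman -> Pearson, Gaussian copula
  with_seed(seed, {
    z1 <- stats::rnorm(n_patients)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_patients)
    pat_bcat <- exp(meanlog[[1L]] + sdlog[[1L]] * z1)
    pat_cbl <- exp(meanlog[[2L]] + sdlog[[2L]] * z2)

    pid <- rep(seq_len(n_patients), times = n_img)
    eps1 <- stats::rnorm(length(pid), 0, within_patient_sd)
    eps2 <- stats::rnorm(length(pid), 0, within_patient_sd)
    rec <- data.frame(
      patient_id = sprintf("P%03d", pid),
      image_id = sprintf("P%03d_img%d", pid,
                         unlist(lapply(n_img, seq_len), use.names = FALSE)),
      normalized_bcat = pat_bcat[pid] * exp(eps1),
      normalized_cbl = pat_cbl[pid] * exp(eps2),
      stringsAsFactors = FALSE
    )
    attr(rec, "patient_truth") <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      bcat = pat_bcat, cbl = pat_cbl, n_images = n_img,
      stringsAsFactors = FALSE
    )
    rec
  })
}

#' Generate a densitometry decay series
#'
#' Simulates a translation-block (emetine chase) experiment: the marker
#' band decays exponentially with the given half-life while the loading
#' control stays constant, both subject to multiplicative lognormal
#' measurement noise. With `noise_sd = 0` the normalized series is exactly
#' `2^(-t / t_half)`.
#'
#' @param t_half Half-life in minutes (> 0).
#' @param timepoints Sampling times in minutes, strictly increasing from 0
#'   (default `c(0, 15, 30, 60, 120)`).
#' @param noise_sd SD of the lognormal band noise (default 0).
#' @param amplitude Marker band intensity at time zero (default 100).
#' @param loading Constant loading-control intensity (default 80).
#' @param seed Integer seed (default 0).
#' @return A `data.frame` of class `"decay_series"` with columns `time`,
#'   `marker`, `loading_control`.
#' @examples
#' s <- generate_decay_series(48)
#' normalize_decay(s)    # 2^(-t/48) exactly
#' @export
generate_decay_series <- function(t_half, timepoints = c(0, 15, 30, 60, 120),
                                  noise_sd = 0, amplitude = 100,
                                  loading = 80, seed = 0) {
  stopifnot_scalar_number(t_half, "t_half", min = 0, strict = TRUE)
  with_seed(seed, {
    n <- length(timepoints)
    marker <- amplitude * 2^(-timepoints / t_half) *
      exp(stats::rnorm(n, 0, noise_sd))
    ctrl <- loading * exp(stats::rnorm(n, 0, noise_sd))
    decay_series(timepoints, marker, ctrl)
  })
}
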