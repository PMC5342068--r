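#' Construct and validate a densitometry decay series
#'
#' A translation-block (e.g. emetine) chase experiment yields band
#' intensities for the protein of interest and a loading control at a
#' series of timepoints starting at zero. This constructor validates the
#' invariants the half-life estimator relies on.
#'
#' @param time Timepoints in minutes, strictly increasing, first element 0.
#' @param marker Marker band intensities, positive, same length as `time`.
#' @param loading_control Loading-control band intensities, positive, same
#'   length.
#' @return A `data.frame` of class `"decay_series"`.
#' @export
decay_series <- function(time, marker, loading_control) {
  if (length(time) < 2L || length(marker) != length(time) ||
      length(loading_control) != length(time)) {
    stop("need >= 2 equal-length timepoints, marker and loading values",
         call. = FALSE)
  }
  if (time[1L] != 0) stop("the series must start at time 0", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(marker)) || any(marker <= 0) ||
      any(!is.finite(loading_control)) || any(loading_control <= 0)) {
    stop("band intensities must be positive and finite", call. = FALSE)
  }
  structure(
    data.frame(time = time, marker = marker,
               loading_control = loading_control),
    class = c("decay_series", "data.frame")
  )
}

#' Normalize a decay series to its loading control and time zero
#'
#' Each marker reading is divided by the matched loading-control reading
#' (correcting for lane loading), then by the corrected value at time zero,
#' so the result is the fraction of the initial protein amount remaining:
#' `r(t) = (marker(t)/loading(t)) / (marker(0)/loading(0))`, with
#' `r(0) = 1` exactly.
#'
#' @param series A [decay_series()] (or data.frame with columns `time`,
#'   `marker`, `loading_control`).
#' @return Numeric vector of remaining fractions, same length as the
#'   series, named by timepoint.
#' @examples
#' s <- decay_series(c(0, 30), c(100, 50), c(80, 80))
#' normalize_decay(s)   # 1.0 0.5
#' @export
normalize_decay <- function(series) {
  if (!all(c("time", "marker", "loading_control") %in% names(series))) {
    stop("`series` must have columns time, marker, loading_control",
         call. = FALSE)
  }
  s <- decay_series(series$time, series$marker, series$loading_control)
  ratio <- s$marker / s$loading_control
  out <- ratio / ratio[1L]
  names(out) <- s$time
  out
}

#' Estimate protein half-life from a normalized decay series
#'
#' The half-life is the time at which the normalized amount reaches 50% of
#' its time-zero value. Between the two samples bracketing 0.5 the decay is
#' assumed first-order (exponential), so interpolation is linear in
#' `log(fraction)`; for a pure exponential sampled anywhere this recovers
#' the true half-life to machine precision. If no sample falls at or below
#' 0.5, a log-linear regression over all points is extrapolated instead and
#' the result is flagged `"extrapolated"`. If the series crosses 0.5 more
#' than once (non-monotone noise), the first crossing is used and the
#' result is flagged `"multiple_crossings"`.
#'
#' @param timepoints Times in minutes, strictly increasing, starting at 0.
#' @param fractions Normalized fractions from [normalize_decay()];
#'   `fractions[1]` must be 1.
#' @param method `"loglinear"` (default, first-order kinetics) or
#'   `"linear"` interpolation between the bracketing samples.
#' @return Half-life in minutes (numeric scalar), with attribute `"flags"`
#'   (character vector, possibly empty).
#' @examples
#' t <- c(0, 15, 30, 60, 120)
#' estimate_half_life(t, 2^(-t / 48))   # 48
#' @export
estimate_half_life <- function(timepoints, fractions,
                               method = c("loglinear", "linear")) {
  method <- match.arg(method)
  if (length(timepoints) != length(fractions) || length(timepoints) < 2L) {
    stop("need >= 2 matching timepoints and fractions", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0) || timepoints[1L] != 0) {
    stop("`timepoints` must be strictly increasing from 0", call. = FALSE)
  }
  if (abs(fractions[1L] - 1) > 1e-8) {
    stop("`fractions` must be normalized to 1 at time zero", call. = FALSE)
  }
  if (any(fractions <= 0)) {
    stop("fractions must be positive (log-linear kinetics)", call. = FALSE)
  }
  flags <- character(0)
  below <- which(fractions <= 0.5)
  if (length(below) == 0L) {
    # never reaches 50%: extrapolate a first-order fit over all points
    if (all(diff(fractions) >= 0)) {
      stop("series never decays below 50% and is non-decreasing; ",
           "half-life undefined", call. = FALSE)
    }
    fit <- stats::lm(log(fractions) ~ timepoints)
    slope <- stats::coef(fit)[[2L]]
    if (slope >= 0) {
      stop("no net decay; half-life undefined", call. = FALSE)
    }
    t_half <- (log(0.5) - stats::coef(fit)[[1L]]) / slope
    attr(t_half, "flags") <- "extrapolated"
    return(t_half)
  }
  i <- below[1L]
  crossings <- sum(diff(fractions <= 0.5) == 1L) + (fractions[1L] <= 0.5)
  if (crossings > 1L) flags <- c(flags, "multiple_crossings")
  if (i == 1L) {
    t_half <- timepoints[1L]
  } else if (fractions[i] == 0.5) {
    t_half <- timepoints[i]
  } else {
    t0 <- timepoints[i - 1L]; t1 <- timepoints[i]
    f0 <- fractions[i - 1L]; f1 <- fractions[i]
    w <- if (method == "loglinear") {
      (log(f0) - log(0.5)) / (log(f0) - log(f1))
    } else {
      (f0 - 0.5) / (f0 - f1)
    }
    t_half <- t0 + w * (t1 - t0)
  }
  attr(t_half, "flags") <- flags
  t_half
}

#' Xenograft tumor volume from caliper measurements
#'
#' The standard caliper formula for a subcutaneous tumor approximated as an
#' ellipsoid: `V = l * w^2 / 2` (mm^3), where `l` is the longer and `w` the
#' shorter axis in mm. A literal product reading `V = l * w` is available
#' behind `literal = TRUE` for auditing against legacy spreadsheets.
#'
#' @param length Tumor length in mm (longer axis); vectorized.
#' @param width Tumor width in mm; must satisfy `0 < width <= length`.
#' @param literal If `TRUE`, compute `0.5 * l * 2 * w = l * w` instead of
#'   the ellipsoid formula. Default `FALSE`.
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 5)    # 125
#' @export
tumor_volume <- function(length, width, literal = FALSE) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    stop("caliper measurements must be positive", call. = FALSE)
  }
  if (any(width > length)) {
    stop("`width` cannot exceed `length` (length is the longer axis)",
         call. = FALSE)
  }
  if (literal) length * width else 0.5 * length * width^2
}
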