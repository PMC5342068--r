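#' Aggregate per-image marker records to patient level
#'
#' Each patient contributes several images; the patient-level value of each
#' marker is the arithmetic mean of that patient's image values, with the
#' standard error of the mean (SEM) carried along (NA for single-image
#' patients).
#'
#' @param records Data frame with columns `patient_id`, `normalized_bcat`,
#'   `normalized_cbl` (one row per image), e.g. from [generate_cohort()] or
#'   the quantification pipeline.
#' @return Data frame with one row per patient, sorted by `patient_id`:
#'   columns `patient_id`, `mean_bcat`, `mean_cbl`, `n_images`, `sem_bcat`,
#'   `sem_cbl`.
#' @examples
#' rec <- data.frame(patient_id = c("a", "a"), normalized_bcat = c(.2, .4),
#'                   normalized_cbl = c(1, 3))
#' aggregate_by_patient(rec)$mean_bcat   # 0.3
#' @export
aggregate_by_patient <- function(records) {
  need <- c("patient_id", "normalized_bcat", "normalized_cbl")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  if (any(!is.finite(records$normalized_bcat)) ||
      any(!is.finite(records$normalized_cbl))) {
    stop("marker values must be finite", call. = FALSE)
  }
  ids <- sort(unique(records$patient_id))
  f <- factor(records$patient_id, levels = ids)
  sem <- function(x) if (length(x) < 2L) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  out <- data.frame(
    patient_id = ids,
    mean_bcat = as.numeric(tapply(records$normalized_bcat, f, mean)),
    mean_cbl = as.numeric(tapply(records$normalized_cbl, f, mean)),
    n_images = as.integer(tapply(records$normalized_bcat, f, length)),
    sem_bcat = as.numeric(tapply(records$normalized_bcat, f, sem)),
    sem_cbl = as.numeric(tapply(records$normalized_cbl, f, sem)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' The correlation coefficient is the Pearson correlation of average ranks
#' (ties receive their midrank). The two-sided p-value uses the exact
#' permutation null distribution for `n <= 10` without ties, and otherwise
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @return Object of class `"ihc_correlation"`: list with `rho`, `p_value`,
#'   `n`, `method` (`"exact_permutation"` or `"t_approximation"`).
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5))$rho   # 0.7
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: Spearman correlation undefined", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 10L && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE,
                      alternative = "two.sided")$p.value)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n, method = method),
            class = "ihc_correlation")
}

#' @export
print.ihc_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.3g, %s)\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' Dichotomize a cohort at the marker means into a 2x2 table
#'
#' Each patient is classed high/low on each marker relative to the cohort
#' arithmetic mean of the patient-level values (strictly greater = high;
#' values exactly at the mean count as low). Cells follow the marker
#' cross-classification used for inverse-relationship counting:
#' \describe{
#'   \item{a}{bcat high, cbl low (discordant)}
#'   \item{b}{bcat high, cbl high}
#'   \item{c}{bcat low, cbl low}
#'   \item{d}{bcat low, cbl high (discordant)}
#' }
#'
#' @param summaries Patient-level data frame from [aggregate_by_patient()]
#'   (columns `mean_bcat`, `mean_cbl`), at least 2 patients.
#' @return Object of class `"contingency2x2"`: list with integer cells
#'   `a`, `b`, `c`, `d`, the `thresholds` used, and `n` patients.
#' @examples
#' s <- data.frame(mean_bcat = c(2, 2, 0, 0), mean_cbl = c(0, 0, 2, 2))
#' dichotomize_at_means(s)$a   # 2
#' @export
dichotomize_at_means <- function(summaries) {
  if (!all(c("mean_bcat", "mean_cbl") %in% names(summaries))) {
    stop("`summaries` needs columns mean_bcat, mean_cbl", call. = FALSE)
  }
  if (nrow(summaries) < 2L) stop("need >= 2 patients", call. = FALSE)
  thr_b <- mean(summaries$mean_bcat)
  thr_c <- mean(summaries$mean_cbl)
  hi_b <- summaries$mean_bcat > thr_b
  hi_c <- summaries$mean_cbl > thr_c
  structure(
    list(a = sum(hi_b & !hi_c), b = sum(hi_b & hi_c),
         c = sum(!hi_b & !hi_c), d = sum(!hi_b & hi_c),
         thresholds = c(bcat = thr_b, cbl = thr_c),
         n = nrow(summaries)),
    class = "contingency2x2"
  )
}

#' Build a 2x2 marker contingency table from its cell counts
#'
#' For entering a published or externally computed table directly.
#' Cell layout as in [dichotomize_at_means()].
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param thresholds Optional named thresholds used for the split.
#' @return A `"contingency2x2"` object.
#' @examples
#' contingency_table(26, 5, 9, 43)$n   # 83
#' @export
contingency_table <- function(a, b, c, d, thresholds = NULL) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), thresholds = thresholds,
                 n = as.integer(sum(cells))),
            class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("bcat high", "bcat low"),
                              c("cbl low", "cbl high")))
  cat(sprintf("2x2 marker table (n = %d patients)\n", x$n))
  print(m)
  if (!is.null(x$thresholds)) {
    cat(sprintf("thresholds: bcat > %.4g, cbl > %.4g\n",
                x$thresholds[[1L]], x$thresholds[[2L]]))
  }
  invisible(x)
}

#' Summary percentages of a 2x2 marker table
#'
#' Derives the cohort-level headline numbers: prevalence of high nuclear
#' beta-catenin, the count and percentage of discordant (inverse
#' relationship) patients, and the two conditional percentages. Percentages
#' are returned at full precision together with a nearest-integer rendering
#' (half away from zero). Conditionals with a zero margin are `NA` and
#' flagged.
#'
#' @param table A `"contingency2x2"` object.
#' @return List with `prevalence_bcat_high_pct`, `discordant_count`,
#'   `discordant_pct`, `pct_bcat_high_with_low_cbl`,
#'   `pct_cbl_high_with_low_bcat`, a `rounded` integer rendering of each
#'   percentage, and `flags`.
#' @examples
#' s <- contingency_summaries(contingency_table(26, 5, 9, 43))
#' s$rounded[["prevalence_bcat_high_pct"]]   # 37
#' @export
contingency_summaries <- function(table) {
  stopifnot(inherits(table, "contingency2x2"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  N <- table$n
  if (N < 1L) stop("empty table", call. = FALSE)
  flags <- character(0)
  cond_a <- if (a + b > 0L) 100 * a / (a + b) else {
    flags <- c(flags, "zero_bcat_high_margin"); NA_real_
  }
  cond_d <- if (b + d > 0L) 100 * d / (b + d) else {
    flags <- c(flags, "zero_cbl_high_margin"); NA_real_
  }
  pct <- c(prevalence_bcat_high_pct = 100 * (a + b) / N,
           discordant_pct = 100 * (a + d) / N,
           pct_bcat_high_with_low_cbl = cond_a,
           pct_cbl_high_with_low_bcat = cond_d)
  list(
    prevalence_bcat_high_pct = pct[["prevalence_bcat_high_pct"]],
    discordant_count = a + d,
    discordant_pct = pct[["discordant_pct"]],
    pct_bcat_high_with_low_cbl = pct[["pct_bcat_high_with_low_cbl"]],
    pct_cbl_high_with_low_bcat = pct[["pct_cbl_high_with_low_bcat"]],
    rounded = round_half_up(pct),
    flags = flags
  )
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Computes the U statistic for the first group directly from rank sums and
#' a two-sided p-value: exact enumeration when both groups have at most 8
#' observations and no ties are present, otherwise the tie-corrected normal
#' approximation (both via [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric vectors, each nonempty.
#' @return List with `U` (statistic for `group_a`), `p_two_sided`, `n_a`,
#'   `n_b`, `method` (`"exact"` or `"normal_approximation"`).
#' @examples
#' rank_sum_test(1:3, 4:6)$p_two_sided   # 0.1
#' @export
rank_sum_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 1L || nb < 1L) stop("both groups must be nonempty", call. = FALSE)
  if (anyNA(group_a) || anyNA(group_b)) stop("NA values", call. = FALSE)
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- na <= 8L && nb <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact)
  )
  list(U = U, p_two_sided = wt$p.value, n_a = na, n_b = nb,
       method = if (exact) "exact" else "normal_approximation")
}

#' Percent reduction relative to a control mean
#'
#' For drug-response readouts: each treated value is expressed as the
#' percent reduction relative to the mean of the control values,
#' `100 * (mean(control) - v) / mean(control)`.
#'
#' @param treated Numeric vector of treated readouts.
#' @param control Numeric vector of control readouts; mean must be nonzero.
#' @return Numeric vector of per-value percent reductions.
#' @examples
#' percent_reduction(c(2, 4, 6), c(8, 12))   # 80 60 40
#' @export
percent_reduction <- function(treated, control) {
  if (length(control) < 1L) stop("`control` is empty", call. = FALSE)
  m <- mean(control)
  if (!is.finite(m) || m == 0) {
    stop("control mean must be nonzero", call. = FALSE)
  }
  100 * (m - treated) / m
}
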