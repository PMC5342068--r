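#' Run the end-to-end cohort analysis
#'
#' Ties the modules together: per-image marker quantification (when images
#' are supplied), patient-level aggregation, Spearman correlation at both
#' the image and the patient level, mean-based dichotomization into a 2x2
#' table with its summary percentages, and a reproducibility manifest.
#'
#' Input is either `records` — a per-image data.frame with columns
#' `patient_id`, `image_id`, `normalized_bcat`, `normalized_cbl` (e.g. from
#' [generate_cohort()] or a previous quantification run) — or `images`, a
#' data.frame with columns `patient_id`, `image_id`, `bcat_path`,
#' `cbl_path` naming paired marker image files, which are quantified with
#' [quantify_nuclear_marker()] and [quantify_cytoplasmic_marker()]
#' respectively. Records flagged by the pipeline (e.g. zero tumor area) are
#' excluded from the statistics and counted in the report.
#'
#' @param config An [ihc_config()].
#' @param records Per-image marker records (see above), or `NULL`.
#' @param images Data frame of image paths (see above), or `NULL`.
#' @param out_dir Optional directory; when given, the report JSON, the
#'   per-image and per-patient CSV tables and the manifest are written
#'   there.
#' @return Object of class `"ihc_report"`: list with `records`,
#'   `patients`, `correlation` (list with `patient` and `image`
#'   [spearman()] results), `table` (the 2x2), `summaries`, `n_flagged`,
#'   and `manifest`.
#' @examples
#' rep <- run_full_analysis(records = generate_cohort(seed = 1))
#' rep$correlation$patient$rho
#' @export
run_full_analysis <- function(config = ihc_config(), records = NULL,
                              images = NULL, out_dir = NULL) {
  if (is.null(records) && is.null(images)) {
    stop("supply `records` or `images`; see ?run_full_analysis",
         call. = FALSE)
  }
  if (is.null(records)) {
    if (nrow(images) == 0L) stop("empty image list", call. = FALSE)
    records <- quantify_image_pairs(images, config)
  }
  flagged <- if ("flags" %in% names(records)) {
    !is.na(records$flags) & nzchar(records$flags)
  } else {
    rep(FALSE, nrow(records))
  }
  flagged <- flagged | !is.finite(records$normalized_bcat) |
    !is.finite(records$normalized_cbl)
  if (any(flagged)) {
    warning(sum(flagged), " flagged record(s) excluded from statistics")
  }
  use <- records[!flagged, , drop = FALSE]
  patients <- aggregate_by_patient(use)
  cor_pat <- spearman(patients$mean_bcat, patients$mean_cbl)
  cor_img <- spearman(use$normalized_bcat, use$normalized_cbl)
  tab <- dichotomize_at_means(patients)
  summ <- contingency_summaries(tab)
  manifest <- list(
    package = "ihcquant",
    version = as.character(utils::packageVersion("ihcquant")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "selection")],
    n_records = nrow(records), n_flagged = sum(flagged),
    n_patients = nrow(patients)
  )
  report <- structure(
    list(records = records, patients = patients,
         correlation = list(patient = cor_pat, image = cor_img),
         table = tab, summaries = summ, n_flagged = sum(flagged),
         manifest = manifest),
    class = "ihc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

quantify_image_pairs <- function(images, config) {
  need <- c("patient_id", "image_id", "bcat_path", "cbl_path")
  if (!all(need %in% names(images))) {
    stop("`images` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(images)), function(i) {
    qb <- quantify_nuclear_marker(read_ihc_image(images$bcat_path[i]),
                                  config, image_id = images$image_id[i])
    qc <- quantify_cytoplasmic_marker(read_ihc_image(images$cbl_path[i]),
                                      config, image_id = images$image_id[i])
    data.frame(patient_id = images$patient_id[i],
               image_id = images$image_id[i],
               normalized_bcat = qb$normalized_fraction,
               normalized_cbl = qc$normalized_fraction,
               flags = paste(unique(c(qb$flags, qc$flags)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$patients, file.path(out_dir, "patients.csv"),
                   row.names = FALSE)
  json <- list(
    correlation = list(
      patient = unclass(report$correlation$patient),
      image = unclass(report$correlation$image)
    ),
    contingency = unclass(report$table),
    summaries = report$summaries[setdiff(names(report$summaries), "rounded")],
    summaries_rounded = as.list(report$summaries$rounded),
    n_flagged = report$n_flagged,
    manifest = report$manifest
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ihc_report <- function(x, ...) {
  cat(sprintf("IHC cohort report: %d patients, %d image records (%d flagged)\n",
              nrow(x$patients), nrow(x$records), x$n_flagged))
  cat(sprintf("  patient-level Spearman rho = %.3f (p = %.3g)\n",
              x$correlation$patient$rho, x$correlation$patient$p_value))
  cat(sprintf("  image-level   Spearman rho = %.3f (p = %.3g)\n",
              x$correlation$image$rho, x$correlation$image$p_value))
  print(x$table)
  s <- x$summaries
  cat(sprintf("  bcat-high prevalence %.1f%%; discordant %d (%.1f%%)\n",
              s$prevalence_bcat_high_pct, s$discordant_count,
              s$discordant_pct))
  invisible(x)
}

#' @export
summary.ihc_report <- function(object, ...) {
  s <- object$summaries
  out <- data.frame(
    quantity = c("patient_rho", "patient_p", "image_rho", "image_p",
                 "prevalence_bcat_high_pct", "discordant_count",
                 "discordant_pct", "pct_bcat_high_with_low_cbl",
                 "pct_cbl_high_with_low_bcat"),
    value = c(object$correlation$patient$rho,
              object$correlation$patient$p_value,
              object$correlation$image$rho,
              object$correlation$image$p_value,
              s$prevalence_bcat_high_pct, s$discordant_count,
              s$discordant_pct, s$pct_bcat_high_with_low_cbl,
              s$pct_cbl_high_with_low_bcat)
  )
  out
}

#' @export
plot.ihc_report <- function(x, ...) {
  p <- x$patients
  graphics::plot(p$mean_cbl, p$mean_bcat, pch = 19,
                 col = grDevices::adjustcolor("steelblue", 0.7),
                 xlab = "normalized c-Cbl (patient mean)",
                 ylab = "normalized nuclear beta-catenin (patient mean)",
                 main = sprintf("patient-level Spearman rho = %.2f",
                                x$correlation$patient$rho), ...)
  graphics::abline(v = x$table$thresholds[["cbl"]], lty = 2)
  graphics::abline(h = x$table$thresholds[["bcat"]], lty = 2)
  invisible(x)
}
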