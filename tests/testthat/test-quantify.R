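# Shared synthetic scenes: a DAB-cytoplasm (c-Cbl-like) image and a
# nuclear-marker image, at 256 x 256 with the size filter scaled to that
# area (1250 px here ~ 5000 px at 512 x 512).
cfg <- ihc_config(min_component_px = 1250)

cyto_scene <- generate_ihc_image(
  ihc_image_params(height = 256, width = 256, tumor_coverage = 0.6,
                   cytoplasm_dab_coverage = 0.3, n_nuclei = 60, seed = 101))

nuclear_scene <- generate_ihc_image(
  ihc_image_params(height = 256, width = 256, tumor_coverage = 0.55,
                   cytoplasm_dab_coverage = 0, n_nuclei = 120,
                   positive_nucleus_fraction = 0.4, seed = 102))

test_that("auto selection picks the DAB-brown cluster by chromaticity", {
  seg <- structure(
    list(labels = matrix(rep(1:3, each = 4), 2, 6), k = 3L,
         centroids = rbind(c(0, 0), c(12, 28), c(8, -30)),
         sizes = c(4L, 4L, 4L), within_cluster_sse = 0),
    class = "ihc_segmentation")
  mask <- select_marker_cluster(seg, list(mode = "auto"))
  expect_equal(attr(mask, "cluster"), 2L)      # a* + b* = 40 wins
  expect_length(attr(mask, "flags"), 0)

  fixed <- select_marker_cluster(seg, list(mode = "fixed", index = 1))
  expect_equal(attr(fixed, "cluster"), 1L)
  expect_error(select_marker_cluster(seg, list(mode = "fixed", index = 9)),
               "out of range")
})

test_that("an achromatic image yields a low-confidence selection", {
  white <- rgb_to_lab(array(250, dim = c(8, 8, 3)))
  seg <- kmeans_ab(extract_ab(white), k = 3, seed = 0)
  mask <- select_marker_cluster(seg, list(mode = "auto"))
  expect_true("low_confidence" %in% attr(mask, "flags"))
})

test_that("cytoplasmic quantification recovers the generator truth", {
  q <- quantify_cytoplasmic_marker(cyto_scene$image, cfg)
  t <- cyto_scene$truth
  expect_lt(abs(q$raw_fraction - t$cytoplasm_fraction), 0.03)
  expect_lt(abs(q$tumor_fraction - t$tumor_fraction), 0.05)
  expect_lt(abs(q$normalized_fraction -
                  t$cytoplasm_fraction / t$tumor_fraction), 0.06)
})

test_that("DAB blobs below the size threshold quantify to zero", {
  # nuclei-only DAB (each ~50 px) with a filter far above nucleus scale
  q <- quantify_cytoplasmic_marker(nuclear_scene$image, cfg)
  expect_equal(q$raw_fraction, 0)
})

test_that("estimated cytoplasmic fractions preserve ground-truth order", {
  lo <- generate_ihc_image(
    ihc_image_params(height = 256, width = 256, tumor_coverage = 0.6,
                     cytoplasm_dab_coverage = 0.12, n_nuclei = 60,
                     seed = 101))
  q_lo <- quantify_cytoplasmic_marker(lo$image, cfg)
  q_hi <- quantify_cytoplasmic_marker(cyto_scene$image, cfg)
  expect_lt(q_lo$raw_fraction, q_hi$raw_fraction)
})

test_that("nuclear quantification recovers the positive-nucleus area", {
  q <- quantify_nuclear_marker(nuclear_scene$image, cfg)
  t <- nuclear_scene$truth
  expect_lt(abs(q$raw_fraction - t$positive_nuclei_fraction), 0.02)
  sel <- attr(q, "selected_submasks")
  expect_gt(length(sel), 0)
  expect_true(all(sel %in% 1:6))
  expect_lte(q$raw_fraction, 1)
})

test_that("an image with no positive nuclei quantifies to zero, flagged", {
  none <- generate_ihc_image(
    ihc_image_params(height = 128, width = 128, cytoplasm_dab_coverage = 0,
                     n_nuclei = 60, positive_nucleus_fraction = 0,
                     seed = 103))
  q <- quantify_nuclear_marker(none$image, cfg)
  expect_equal(q$raw_fraction, 0)
  expect_true("no_nuclear_submask" %in% q$flags)
})

test_that("tumor-area estimation recovers the generator coverage", {
  est <- quantify_tumor_area(nuclear_scene$image, cfg)
  expect_lt(abs(as.numeric(est) - nuclear_scene$truth$tumor_fraction), 0.05)

  white <- array(250, dim = c(32, 32, 3))
  est0 <- quantify_tumor_area(white, cfg)
  expect_equal(as.numeric(est0), 0)
  expect_true("low_confidence" %in% attr(est0, "flags"))
})

test_that("tumor and lumen fractions sum to one on a two-compartment image", {
  two <- generate_ihc_image(
    ihc_image_params(height = 128, width = 128, tumor_coverage = 0.5,
                     interstitium_coverage = 0, cytoplasm_dab_coverage = 0,
                     n_nuclei = 40, seed = 104))
  est <- quantify_tumor_area(two$image, cfg)
  expect_lt(abs(as.numeric(est) + two$truth$lumen_fraction - 1), 0.03)
})

test_that("nucleus counting recovers counts and positivity percentage", {
  q <- count_positive_nuclei(nuclear_scene$image, cfg)
  t <- nuclear_scene$truth
  expect_lt(abs(q$total_nuclei - t$n_nuclei), 0.1 * t$n_nuclei)
  truth_pct <- 100 * t$n_positive / t$n_nuclei
  expect_lt(abs(q$percent_positive - truth_pct), 5)
})

test_that("all-positive and no-nucleus images hit the count extremes", {
  allpos <- generate_ihc_image(
    ihc_image_params(height = 128, width = 128, cytoplasm_dab_coverage = 0,
                     n_nuclei = 40, positive_nucleus_fraction = 1,
                     seed = 105))
  q <- count_positive_nuclei(allpos$image, cfg)
  expect_equal(q$percent_positive, 100)

  bare <- generate_ihc_image(
    ihc_image_params(height = 64, width = 64, cytoplasm_dab_coverage = 0,
                     n_nuclei = 0, seed = 106))
  q0 <- count_positive_nuclei(bare$image, cfg)
  expect_equal(q0$total_nuclei, 0L)
  expect_true("no_nuclei" %in% q0$flags)
  expect_true(is.na(q0$percent_positive))
})

test_that("tumor normalization divides raw by tumor fraction", {
  expect_equal(as.numeric(normalize_to_tumor(0.1, 0.5)), 0.2)
  expect_equal(as.numeric(normalize_to_tumor(0, 0.3)), 0)
  expect_equal(as.numeric(normalize_to_tumor(0.4, 0.4)), 1)
  z <- normalize_to_tumor(0.2, 0)
  expect_true(is.na(z))
  expect_equal(attr(z, "flags"), "zero_tumor_area")
  expect_error(normalize_to_tumor(1.2, 0.5), "\\[0, 1\\]")
})

test_that("every emitted fraction respects its bounds", {
  for (q in list(quantify_cytoplasmic_marker(cyto_scene$image, cfg),
                 quantify_nuclear_marker(nuclear_scene$image, cfg))) {
    expect_gte(q$raw_fraction, 0); expect_lte(q$raw_fraction, 1)
    expect_gte(q$tumor_fraction, 0); expect_lte(q$tumor_fraction, 1)
    expect_gte(q$normalized_fraction, 0)
  }
  nc <- count_positive_nuclei(nuclear_scene$image, cfg)
  expect_gte(nc$percent_positive, 0)
  expect_lte(nc$percent_positive, 100)
})

test_that("the full quantification is deterministic for a fixed seed", {
  a <- quantify_cytoplasmic_marker(cyto_scene$image, cfg)
  b <- quantify_cytoplasmic_marker(cyto_scene$image, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
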