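test_that("ground-truth masks partition the image and match fractions", {
  syn <- generate_ihc_image(ihc_image_params(height = 96, width = 96,
                                             seed = 1))
  t <- syn$truth
  region_sum <- t$tumor + t$interstitium + t$lumen
  expect_true(all(region_sum == 1))     # disjoint cover
  expect_true(all(t$cytoplasm_dab <= t$tumor))
  expect_true(all(t$nuclei <= t$tumor))
  expect_true(all(t$positive_nuclei <= t$nuclei))
  expect_false(any(t$cytoplasm_dab & t$nuclei))
  N <- 96 * 96
  expect_equal(t$tumor_fraction, sum(t$tumor) / N)
  expect_equal(t$positive_nuclei_fraction, sum(t$positive_nuclei) / N)
})

test_that("requested coverages are hit to rasterization accuracy", {
  for (cov in c(0.2, 0.5)) {
    syn <- generate_ihc_image(
      ihc_image_params(height = 128, width = 128, tumor_coverage = cov,
                       cytoplasm_dab_coverage = cov / 3, seed = 9))
    expect_lt(abs(syn$truth$tumor_fraction - cov), 0.02)
  }
})

test_that("zero tumor coverage gives a pure lumen/interstitium image", {
  syn <- generate_ihc_image(
    ihc_image_params(height = 64, width = 64, tumor_coverage = 0,
                     cytoplasm_dab_coverage = 0, n_nuclei = 0, seed = 2))
  expect_equal(syn$truth$tumor_fraction, 0)
  expect_equal(syn$truth$cytoplasm_fraction, 0)
  expect_equal(syn$truth$n_nuclei, 0)
})

test_that("image generation is a pure function of the parameters", {
  p <- ihc_image_params(height = 64, width = 64, seed = 33)
  a <- generate_ihc_image(p)
  b <- generate_ihc_image(p)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$tumor, b$truth$tumor)
  c <- generate_ihc_image(ihc_image_params(height = 64, width = 64,
                                           seed = 34))
  expect_false(identical(a$image, c$image))
})

test_that("infeasible coverage combinations are rejected", {
  expect_error(ihc_image_params(tumor_coverage = 0.3,
                                cytoplasm_dab_coverage = 0.4),
               "cannot exceed")
  expect_error(ihc_image_params(tumor_coverage = 0.8,
                                interstitium_coverage = 0.5),
               "exceeds 1")
})

test_that("cohort generator produces the requested design", {
  rec <- generate_cohort(n_patients = 83, images_per_patient = 5, seed = 1)
  expect_equal(nrow(rec), 415)
  expect_equal(length(unique(rec$patient_id)), 83)
  expect_true(all(rec$normalized_bcat > 0))
  expect_true(all(rec$normalized_cbl > 0))
  # unequal designs supported
  uneq <- generate_cohort(n_patients = 4, images_per_patient = c(2, 5, 3, 1),
                          seed = 1)
  expect_equal(nrow(uneq), 11)
})

test_that("a zero-correlation target yields a near-zero patient rho", {
  rec <- generate_cohort(target_spearman = 0, seed = 7)
  p <- aggregate_by_patient(rec)
  expect_lt(abs(spearman(p$mean_bcat, p$mean_cbl)$rho), 0.25)
})

test_that("copula rank correlation converges to the target at large n", {
  rec <- generate_cohort(n_patients = 2000, images_per_patient = 1,
                         within_patient_sd = 1e-6, seed = 5)
  truth <- attr(rec, "patient_truth")
  rho <- spearman(truth$bcat, truth$cbl)$rho
  expect_lt(abs(rho - (-0.64)), 0.03)
})

test_that("cohort generation is deterministic per seed", {
  expect_identical(generate_cohort(seed = 11), generate_cohort(seed = 11))
})

test_that("noiseless decay series follow the closed form exactly", {
  s <- generate_decay_series(48, noise_sd = 0)
  f <- normalize_decay(s)
  expect_equal(unname(f), 2^(-c(0, 15, 30, 60, 120) / 48))
  s2 <- generate_decay_series(35, timepoints = c(0, 35), noise_sd = 0)
  expect_equal(unname(normalize_decay(s2))[2], 0.5)
})
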