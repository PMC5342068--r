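test_that("patient aggregation averages images per patient", {
  rec <- data.frame(patient_id = c("p1", "p1"),
                    normalized_bcat = c(0.2, 0.4),
                    normalized_cbl = c(1, 2))
  s <- aggregate_by_patient(rec)
  expect_equal(s$mean_bcat, 0.3)
  expect_equal(s$n_images, 2L)

  single <- aggregate_by_patient(
    data.frame(patient_id = "x", normalized_bcat = 0.7,
               normalized_cbl = 0.1))
  expect_equal(single$mean_bcat, 0.7)
  expect_true(is.na(single$sem_bcat))
})

test_that("a full synthetic cohort aggregates to the right bookkeeping", {
  rec <- generate_cohort(seed = 2)
  expect_equal(nrow(rec), 415)
  s <- aggregate_by_patient(rec)
  expect_equal(nrow(s), 83)
  expect_equal(sum(s$n_images), 415)
  expect_identical(s$patient_id, sort(s$patient_id))
})

test_that("spearman handles the textbook cases", {
  expect_equal(spearman(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman(1:8, -(1:8))$rho, -1)
  # closed form 1 - 6*sum(d^2)/(n(n^2-1)): d^2 sums to 4 -> rho = 0.8
  r <- spearman(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_equal(r$method, "exact_permutation")
  expect_equal(r$p_value,
               stats::cor.test(1:5, c(2, 1, 4, 3, 5), method = "spearman",
                               exact = TRUE)$p.value)
})

test_that("spearman switches to the t approximation for larger n", {
  set.seed(4)
  x <- stats::rnorm(40); y <- x + stats::rnorm(40)
  r <- spearman(x, y)
  expect_equal(r$method, "t_approximation")
  tstat <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * stats::pt(-abs(tstat), r$n - 2))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- stats::rnorm(25); y <- stats::rnorm(25)
  base <- spearman(x, y)$rho
  expect_equal(spearman(exp(x), y)$rho, base)
  expect_equal(spearman(x, y^3)$rho, base)
  expect_equal(spearman(rank(x), y)$rho, base)
})

test_that("spearman rejects degenerate input", {
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(spearman(1:2, 2:1), "n >= 3")
  expect_error(spearman(1:4, 1:3), "lengths")
})

test_that("mean dichotomization fills the expected cells", {
  s <- data.frame(mean_bcat = c(2, 2, 0, 0), mean_cbl = c(0, 0, 2, 2))
  tab <- dichotomize_at_means(s)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 0, 0, 2))

  same <- data.frame(mean_bcat = rep(1, 5), mean_cbl = rep(2, 5))
  tab2 <- dichotomize_at_means(same)   # ties at the mean count as low
  expect_equal(tab2$c, 5)
  expect_equal(tab2$a + tab2$b + tab2$d, 0)
})

test_that("dichotomization conserves patients on random cohorts", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    s <- data.frame(mean_bcat = stats::rlnorm(n), mean_cbl = stats::rlnorm(n))
    tab <- dichotomize_at_means(s)
    expect_equal(tab$a + tab$b + tab$c + tab$d, n)
  }
})

test_that("a strongly negative cohort is mostly discordant", {
  rec <- generate_cohort(seed = 3)
  tab <- dichotomize_at_means(aggregate_by_patient(rec))
  expect_gt((tab$a + tab$d) / tab$n, 0.5)
})

test_that("contingency summaries reproduce the published worked example", {
  s <- contingency_summaries(contingency_table(26, 5, 9, 43))
  expect_equal(s$rounded[["prevalence_bcat_high_pct"]], 37)
  expect_equal(s$discordant_count, 69)
  expect_equal(s$rounded[["pct_cbl_high_with_low_bcat"]], 90)
  expect_equal(s$prevalence_bcat_high_pct, 100 * 31 / 83)
  expect_equal(s$pct_bcat_high_with_low_cbl, 100 * 26 / 31)
})

test_that("contingency summaries handle edge tables", {
  one <- contingency_summaries(contingency_table(1, 0, 0, 0))
  expect_equal(one$prevalence_bcat_high_pct, 100)
  expect_equal(one$discordant_count, 1)

  lowlow <- contingency_summaries(contingency_table(0, 0, 12, 0))
  expect_equal(lowlow$prevalence_bcat_high_pct, 0)
  expect_equal(lowlow$discordant_count, 0)
  expect_true(is.na(lowlow$pct_bcat_high_with_low_cbl))
  expect_true("zero_bcat_high_margin" %in% lowlow$flags)
})

test_that("discordant and concordant percentages always sum to 100", {
  set.seed(12)
  for (i in 1:10) {
    cells <- sample(0:30, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    s <- contingency_summaries(tab)
    concordant_pct <- 100 * (tab$b + tab$c) / tab$n
    expect_equal(s$discordant_pct + concordant_pct, 100)
  }
})

test_that("rank-sum test gives the exact tail for separated small groups", {
  r <- rank_sum_test(1:3, 4:6)
  expect_equal(r$p_two_sided, 0.1)       # 2 * 1/20 arrangements
  expect_equal(r$method, "exact")
  expect_equal(r$U, 0)
})

test_that("identical groups give U at its mean and p near 1", {
  r <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$U, 8)                   # n_a*n_b/2
  expect_gt(r$p_two_sided, 0.95)
})

test_that("U statistics of the two orderings sum to n_a * n_b", {
  set.seed(19)
  for (i in 1:10) {
    a <- stats::rnorm(sample(3:12, 1))
    b <- stats::rnorm(sample(3:12, 1))
    expect_equal(rank_sum_test(a, b)$U + rank_sum_test(b, a)$U,
                 length(a) * length(b))
  }
})

test_that("large or tied samples use the normal approximation", {
  set.seed(6)
  a <- stats::rnorm(20); b <- stats::rnorm(20, 1)
  expect_equal(rank_sum_test(a, b)$method, "normal_approximation")
  expect_equal(rank_sum_test(c(1, 2, 2), c(2, 3, 4))$method,
               "normal_approximation")
})

test_that("percent reduction is relative to the control mean", {
  expect_equal(percent_reduction(5, c(10, 10)), 50)
  expect_equal(percent_reduction(10, c(10, 10)), 0)
  expect_equal(percent_reduction(c(2, 4, 6), c(8, 12)), c(80, 60, 40))
  expect_error(percent_reduction(1, c(-1, 1)), "nonzero")
})
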