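test_that("k points in k clusters give zero SSE", {
  X <- cbind(c(0, 10, 20, 35), c(0, -5, 8, 2))
  seg <- kmeans_ab(X, k = 4, seed = 1)
  expect_equal(seg$within_cluster_sse, 0)
  expect_equal(sort(seg$sizes), rep(1L, 4))
})

test_that("k = 2 SSE matches the exhaustive-bipartition oracle", {
  pts <- rbind(c(0, 0), c(1, 0.5), c(0.2, 1), c(8, 8), c(9, 7.5), c(7, 9))
  seg <- kmeans_ab(pts, k = 2, seed = 3)
  expect_equal(seg$within_cluster_sse, oracle_best_bipartition_sse(pts),
               tolerance = 1e-10)

  # property: optimal on 100 random small instances
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    X <- matrix(stats::rnorm(2 * n, sd = 3), ncol = 2)
    seg <- kmeans_ab(X, k = 2, seed = i, restarts = 10)
    expect_equal(seg$within_cluster_sse, oracle_best_bipartition_sse(X),
                 tolerance = 1e-8)
  }
})

test_that("labels always form a partition and match cluster sizes", {
  set.seed(11)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(60), ncol = 2)
    k <- sample(2:4, 1)
    seg <- kmeans_ab(X, k = k, seed = i)
    expect_setequal(unique(seg$labels), seq_len(k))
    expect_equal(sum(seg$sizes), nrow(X))
    expect_equal(tabulate(seg$labels, k), seg$sizes)
  }
})

test_that("centroids equal the mean of their members, in canonical order", {
  set.seed(2)
  X <- matrix(stats::rnorm(80, sd = 4), ncol = 2)
  seg <- kmeans_ab(X, k = 3, seed = 5)
  for (j in 1:3) {
    expect_equal(unname(seg$centroids[j, ]),
                 unname(colMeans(X[seg$labels == j, , drop = FALSE])),
                 tolerance = 1e-8)
  }
  expect_true(!is.unsorted(seg$centroids[, 1]))
})

test_that("same input and seed reproduce identical output", {
  X <- matrix(stats::rnorm(200), ncol = 2)
  a <- kmeans_ab(X, k = 3, seed = 9)
  b <- kmeans_ab(X, k = 3, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
})

test_that("multi-restart SSE is no worse than stats::kmeans on the same data", {
  set.seed(13)
  X <- matrix(stats::rnorm(400, sd = 5), ncol = 2)
  seg <- kmeans_ab(X, k = 3, seed = 1)
  ref <- stats::kmeans(X, centers = 3, nstart = 10,
                       algorithm = "Lloyd", iter.max = 300)
  expect_lte(seg$within_cluster_sse, ref$tot.withinss * (1 + 1e-6))
})

test_that("degenerate requests error cleanly", {
  expect_error(kmeans_ab(cbind(1, 1), k = 2), "at least")
  expect_error(kmeans_ab(cbind(c(1, NA), c(1, 2)), k = 1), "finite")
})

test_that("two-tier clustering yields 6 disjoint masks covering the image", {
  syn <- generate_ihc_image(ihc_image_params(height = 96, width = 96,
                                             seed = 4))
  ms <- two_tier_cluster(syn$image, seed = 1)
  expect_length(ms$masks, 6)
  expect_equal(ms$tier1_parent, rep(1:3, each = 2))
  total <- Reduce(`+`, lapply(ms$masks, function(m) m * 1L))
  expect_true(all(total == 1L))    # disjoint AND covering
})

test_that("six well-separated patches land in six distinct masks", {
  sp <- six_patch_image()
  ms <- two_tier_cluster(sp$image, seed = 2)
  # every ground-truth patch is exactly one recovered mask
  for (truth in sp$masks) {
    match <- vapply(ms$masks, function(m) identical(m, truth), logical(1))
    expect_equal(sum(match), 1)
  }
})

test_that("a uniform image puts all pixels in one mask, five empty", {
  img <- array(128, dim = c(8, 8, 3))
  ms <- two_tier_cluster(img, seed = 0)
  px <- vapply(ms$masks, sum, numeric(1))
  expect_equal(sum(px > 0), 1)
  expect_equal(sum(px), 64)
})
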