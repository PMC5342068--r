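#' k-means clustering of chromaticity points
#'
#' Partitions the (a*, b*) pixel cloud into `k` clusters with Lloyd's
#' algorithm under squared Euclidean distance. Each restart is initialized
#' with k-means++ seeding; the restart with the lowest within-cluster sum of
#' squares (SSE) wins. For tiny inputs (at most 64 distinct k-point
#' subsets) every subset of points is tried as an initialization instead,
#' which is deterministic and in practice recovers the global optimum. Cluster labels are relabeled canonically — clusters
#' sorted by centroid a*, ties by b* — so that output is reproducible and
#' downstream cluster selection can reason about stable indices.
#'
#' Empty clusters arising during iteration are reseeded to the point
#' farthest from its current centroid, keeping exactly `k` populated
#' clusters as the downstream pipeline assumes.
#'
#' @param points `N x 2` numeric matrix of (a*, b*) values, typically from
#'   [extract_ab()]; any `N x d` matrix with finite entries is accepted.
#' @param k Number of clusters, `1 <= k <= N`.
#' @param seed Integer seed controlling all randomness (default 0).
#' @param restarts Number of k-means++ restarts (default 10).
#' @param tol Convergence tolerance on the SSE decrease (default 1e-6).
#' @param max_iter Iteration cap per restart (default 300).
#' @return An object of class `"ihc_segmentation"`: a list with
#'   \describe{
#'     \item{labels}{integer vector of length N with values in `1..k` (an
#'       `H x W` matrix when `points` carries an `"image_dim"` attribute);}
#'     \item{k, centroids, sizes}{cluster count, `k x d` centroid matrix in
#'       canonical order, cluster sizes;}
#'     \item{within_cluster_sse}{total within-cluster SSE;}
#'     \item{iterations, restarts}{bookkeeping.}
#'   }
#' @examples
#' pts <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 10), 20))
#' seg <- kmeans_ab(pts, k = 2, seed = 1)
#' seg$sizes
#' @export
kmeans_ab <- function(points, k, seed = 0, restarts = 10, tol = 1e-6,
                      max_iter = 300) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    stop("`points` must be finite", call. = FALSE)
  }
  n <- nrow(X)
  stopifnot_scalar_number(k, "k", min = 1)
  k <- as.integer(k)
  if (n < k) stop("need at least `k` points", call. = FALSE)
  stopifnot_scalar_number(restarts, "restarts", min = 1)

  # For tiny inputs every k-subset of points is tried as an initialization
  # (deterministic and in practice exact); otherwise k-means++ restarts.
  small <- n <= 16 && choose(n, k) <= 64
  fit <- with_seed(seed, {
    best <- NULL
    inits <- if (small) {
      utils::combn(n, k, simplify = FALSE)
    } else {
      vector("list", restarts)          # NULL = fresh k-means++ draw
    }
    for (init in inits) {
      cen <- if (is.null(init)) NULL else X[init, , drop = FALSE]
      cand <- lloyd_once(X, k, tol, max_iter, init = cen)
      if (is.null(best) || cand$sse < best$sse) best <- cand
    }
    best
  })

  # canonical order: centroid a* ascending, ties broken by b*
  ord <- do.call(order, lapply(seq_len(ncol(X)), function(j) fit$centers[, j]))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  labels <- remap[fit$labels]
  centroids <- fit$centers[ord, , drop = FALSE]
  colnames(centroids) <- colnames(X)

  dims <- image_dim_of(points)
  lab_out <- if (!is.null(dims)) matrix(labels, dims[1L], dims[2L]) else labels

  structure(
    list(labels = lab_out, k = k, centroids = centroids,
         sizes = tabulate(labels, nbins = k),
         within_cluster_sse = fit$sse, iterations = fit$iter,
         restarts = restarts, image_dim = dims),
    class = "ihc_segmentation"
  )
}

#' @export
print.ihc_segmentation <- function(x, ...) {
  cat(sprintf("k-means segmentation: k = %d, n = %d, SSE = %.4g\n",
              x$k, sum(x$sizes), x$within_cluster_sse))
  tab <- cbind(size = x$sizes, round(x$centroids, 2))
  rownames(tab) <- paste0("cluster", seq_len(x$k))
  print(tab)
  invisible(x)
}

# squared distances from all rows of X to a single center
dist2_to <- function(X, center) {
  if (ncol(X) == 2L) {
    (X[, 1L] - center[1L])^2 + (X[, 2L] - center[2L])^2
  } else {
    rowSums(sweep(X, 2L, center)^2)
  }
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  if (k == 1L) return(centers)
  d2 <- dist2_to(X, centers[1L, ])
  for (j in 2:k) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    centers <- rbind(centers, X[i, ])
    d2 <- pmin(d2, dist2_to(X, centers[j, ]))
  }
  centers
}

lloyd_once <- function(X, k, tol, max_iter, init = NULL) {
  n <- nrow(X)
  centers <- if (is.null(init)) kmeanspp_init(X, k) else init
  labels <- integer(n)
  sse <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- vapply(seq_len(k), function(j) dist2_to(X, centers[j, ]),
                numeric(n))
    new_labels <- max.col(-D, ties.method = "first")
    point_d2 <- D[cbind(seq_len(n), new_labels)]

    # reseed any empty cluster to the point farthest from its centroid;
    # if every point already sits on a centroid (coincident data) the
    # cluster is left empty rather than splitting identical points
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.max(point_d2)
      if (point_d2[far] <= 0) next
      centers[j, ] <- X[far, ]
      new_labels[far] <- j
      point_d2[far] <- 0
    }

    new_sse <- sum(point_d2)
    no_change <- identical(new_labels, labels)
    labels <- new_labels
    for (j in which(tabulate(labels, k) > 0L)) {
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    }
    if (no_change || (is.finite(sse) && sse - new_sse < tol) ||
        iter >= max_iter) {
      sse <- new_sse
      break
    }
    sse <- new_sse
  }
  list(labels = labels, centers = centers, sse = sse, iter = iter)
}

#' Two-tier chromaticity clustering into six sub-masks
#'
#' The nuclear-marker pipeline: pixels are first clustered into three
#' chromatic groups (k = 3 on the (a*, b*) plane), then each first-tier
#' cluster is re-clustered with k = 2, yielding six pairwise-disjoint binary
#' masks whose union covers the image. Sub-dividing each coarse cluster
#' separates, e.g., marker-positive nuclei from surrounding tissue that
#' shares its coarse chromatic group.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`, or a CIELAB array of
#'   the same shape (detected by an L* channel within `[0, 100]` plus signed
#'   chroma).
#' @param seed Integer seed (default 0).
#' @param restarts,tol,max_iter Passed to [kmeans_ab()].
#' @return Object of class `"ihc_maskset"`: list with `masks` (list of 6
#'   logical `H x W` matrices, ordered by tier-1 cluster then tier-2
#'   sub-cluster), `tier1_parent` (integer vector, parent cluster of each
#'   mask), `mean_ab` (6 x 2 mean chromaticity of each mask, `NA` for empty
#'   masks), `mean_l` (mean L* per mask), and `provenance` strings.
#'
#' A first-tier cluster with fewer than two pixels still contributes two
#' masks (one holding its pixels, one empty) so the six-mask contract holds
#' on degenerate inputs.
#' @examples
#' syn <- generate_ihc_image(ihc_image_params(height = 64, width = 64,
#'                                            seed = 1))
#' ms <- two_tier_cluster(syn$image, seed = 1)
#' length(ms$masks)    # 6
#' @export
two_tier_cluster <- function(image, seed = 0, restarts = 10, tol = 1e-6,
                             max_iter = 300) {
  lab <- as_lab(image)
  d <- dim(lab)
  if (prod(d[1:2]) < 6L) stop("image must have at least 6 pixels", call. = FALSE)
  ab <- extract_ab(lab)
  lstar <- as.vector(lab[, , 1L])

  tier1 <- kmeans_ab(ab, k = 3L, seed = seed, restarts = restarts,
                     tol = tol, max_iter = max_iter)
  lab1 <- as.vector(tier1$labels)

  masks <- vector("list", 6L)
  parent <- integer(6L)
  prov <- character(6L)
  for (c1 in 1:3) {
    idx <- which(lab1 == c1)
    sub <- c(rep(list(integer(0)), 2L))
    if (length(idx) >= 2L) {
      seg2 <- kmeans_ab(ab[idx, , drop = FALSE], k = 2L,
                        seed = seed + c1, restarts = restarts,
                        tol = tol, max_iter = max_iter)
      sub <- list(idx[seg2$labels == 1L], idx[seg2$labels == 2L])
    } else {
      # degenerate tier-1 cluster: one populated + one empty sub-mask
      sub <- list(idx, integer(0))
    }
    for (c2 in 1:2) {
      m <- 2L * (c1 - 1L) + c2
      mk <- matrix(FALSE, d[1L], d[2L])
      mk[sub[[c2]]] <- TRUE
      masks[[m]] <- mk
      parent[m] <- c1
      prov[m] <- sprintf("tier1 cluster %d / tier2 sub-cluster %d", c1, c2)
    }
  }
  mean_ab <- t(vapply(masks, function(m) {
    i <- which(m)
    if (length(i) == 0L) c(a = NA_real_, b = NA_real_) else
      c(a = mean(ab[i, 1L]), b = mean(ab[i, 2L]))
  }, numeric(2L)))
  mean_l <- vapply(masks, function(m) {
    i <- which(m)
    if (length(i) == 0L) NA_real_ else mean(lstar[i])
  }, numeric(1L))

  structure(
    list(masks = masks, tier1_parent = parent, mean_ab = mean_ab,
         mean_l = mean_l, provenance = prov, tier1 = tier1,
         image_dim = d[1:2]),
    class = "ihc_maskset"
  )
}

#' @export
print.ihc_maskset <- function(x, ...) {
  n <- vapply(x$masks, sum, numeric(1L))
  cat(sprintf("two-tier mask set: %d masks, %d x %d image\n",
              length(x$masks), x$image_dim[1L], x$image_dim[2L]))
  tab <- data.frame(parent = x$tier1_parent, pixels = n,
                    mean_a = round(x$mean_ab[, 1L], 1),
                    mean_b = round(x$mean_ab[, 2L], 1),
                    mean_L = round(x$mean_l, 1))
  print(tab)
  invisible(x)
}

# Accept either an RGB or an already converted CIELAB array. CIELAB arrays
# are recognized by the channel names set by rgb_to_lab() or by the
# presence of signed chroma values (impossible in 8-bit RGB).
as_lab <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  }
  nm <- dimnames(image)[[3L]]
  if (identical(nm, c("L", "a", "b")) || min(image) < 0) {
    return(image)
  }
  rgb_to_lab(image)
}
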