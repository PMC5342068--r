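# Independent oracles used to validate the package implementations.
# Each is coded from first principles (standards formulas, exhaustive
# enumeration, flood fill) and shares no code with the package internals.

# sRGB (0-255, D65) -> CIELAB by the standards formulas.
oracle_rgb_to_lab <- function(rgb) {
  s <- rgb / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  white <- c(0.95047, 1, 1.08883)
  t <- xyz / white
  f <- ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16,
    a = 500 * (f[1] - f[2]),
    b = 200 * (f[2] - f[3]))
}

# Minimum within-cluster SSE over all nonempty bipartitions (k = 2),
# by exhaustive enumeration. Feasible for n <= ~12.
oracle_best_bipartition_sse <- function(X) {
  n <- nrow(X)
  sse_of <- function(idx) {
    A <- X[idx, , drop = FALSE]
    B <- X[-idx, , drop = FALSE]
    sum(sweep(A, 2, colMeans(A))^2) + sum(sweep(B, 2, colMeans(B))^2)
  }
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {          # point n always in group B
    idx <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    best <- min(best, sse_of(idx))
  }
  best
}

# Connected-component count and sizes by iterative flood fill.
oracle_flood_fill <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  sizes <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      r <- (px - 1) %% h + 1
      c <- (px - 1) %/% h + 1
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          q <- (c2 - 1) * h + r2
          if (mask[q] && !seen[q]) {
            seen[q] <- TRUE
            stack <- c(stack, q)
          }
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(n = length(sizes), sizes = sizes)
}

# Small test image: six uniform color patches in a 2 x 3 grid, plus the
# ground-truth patch masks. The palette forms three chromatic pairs
# (white/pink, blue/purple, dark/light brown) so the first clustering tier
# groups pairs and the second tier separates them.
six_patch_image <- function(cell = 16) {
  cols <- list(c(245, 245, 245), c(240, 205, 218), c(60, 60, 130),
               c(140, 130, 185), c(120, 70, 40), c(190, 120, 60))
  h <- 2 * cell; w <- 3 * cell
  img <- array(0, dim = c(h, w, 3))
  masks <- vector("list", 6)
  i <- 0
  for (r in 0:1) for (cc in 0:2) {
    i <- i + 1
    rows <- (r * cell + 1):((r + 1) * cell)
    colsx <- (cc * cell + 1):((cc + 1) * cell)
    m <- matrix(FALSE, h, w)
    m[rows, colsx] <- TRUE
    masks[[i]] <- m
    for (ch in 1:3) img[rows, colsx, ch] <- cols[[i]][ch]
  }
  list(image = img, masks = masks)
}

# Mask with rectangular components of the requested sizes, spaced apart.
components_mask <- function(sizes, width = 500) {
  heights <- vapply(sizes, function(s) ceiling(s / 50), numeric(1))
  h <- sum(heights) + 2 * length(sizes) + 2
  m <- matrix(FALSE, h, width)
  row <- 2
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    full_rows <- s %/% 50
    rem <- s %% 50
    if (full_rows > 0) {
      m[row:(row + full_rows - 1), 1:50] <- TRUE
    }
    if (rem > 0) m[row + full_rows, 1:rem] <- TRUE
    row <- row + heights[i] + 2
  }
  stopifnot(identical(as.integer(sort(oracle_flood_fill(m)$sizes)),
                      as.integer(sort(sizes))))
  m
}
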