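# Independent oracles used by the unit tests. These deliberately take the
# dumbest correct route (dense convolution, per-pixel loops, BFS) so they
# share no code path with the implementation they check.

# dense Gaussian smoothing with reflective padding, O(n^2 k^2)
oracle_smooth <- function(img, sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  n <- nrow(img); m <- ncol(img)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  pad <- img[refl((1 - r):(n + r), n), refl((1 - r):(m + r), m)]
  out <- matrix(0, n, m)
  for (di in -r:r)
    for (dj in -r:r)
      out <- out + k2[di + r + 1, dj + r + 1] *
        pad[(1 + r + di):(n + r + di), (1 + r + dj):(m + r + dj)]
  out
}

# finite-difference Hessian of a matrix (interior only, NA on the 1-px rim)
oracle_hessian <- function(g) {
  n <- nrow(g); m <- ncol(g)
  dxx <- dyy <- dxy <- matrix(NA_real_, n, m)
  i <- 2:(n - 1); j <- 2:(m - 1)
  dyy[i, j] <- g[i + 1, j] - 2 * g[i, j] + g[i - 1, j]
  dxx[i, j] <- g[i, j + 1] - 2 * g[i, j] + g[i, j - 1]
  i2 <- 3:(n - 2); j2 <- 3:(m - 2)
  dxy[i2, j2] <- (g[i2 + 1, j2 + 1] - g[i2 + 1, j2 - 1] -
                  g[i2 - 1, j2 + 1] + g[i2 - 1, j2 - 1]) / 4
  list(dxx = dxx, dyy = dyy, dxy = dxy)
}

# 8-connected component enumeration by literal BFS flood fill
oracle_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  comp <- list()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    id <- length(comp) + 1L
    queue <- list(c(i, j)); lab[i, j] <- id
    px <- integer(0)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      px <- c(px, (p[2] - 1L) * n + p[1])
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- id
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
    comp[[id]] <- sort(px)
  }
  comp
}

# exhaustive min Euclidean distance from every pixel to the core, row-chunked
oracle_distance_to_core <- function(core) {
  n <- nrow(core); m <- ncol(core)
  idx <- which(core)
  ci <- (idx - 1L) %% n + 1L
  cj <- (idx - 1L) %/% n + 1L
  d <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    di2 <- (i - ci)^2
    for_row <- vapply(seq_len(m), function(j) sqrt(min(di2 + (j - cj)^2)),
                      numeric(1))
    d[i, ] <- for_row
  }
  d
}

# total variation (sum of absolute neighbour differences)
total_variation <- function(img) {
  sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
}

# small, fast phantom + config used across test files
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(size_px = 128L, avascular_radius_um = 450, n_vessels = 8L,
         seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

small_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(ntree = 60L, band_widths_um = c(320, 640, 960), min_area_px = 30L,
         seed = seed),
    list(...))
  do.call(pipeline_config, args)
}

# cache expensive shared fixtures within one test file run
fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, expr, envir = fixture_env)
  get(key, envir = fixture_env)
}
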