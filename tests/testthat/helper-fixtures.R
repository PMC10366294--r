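# Shared fixture builders; everything is generated in code at test time.

# Wrap a bare point matrix as a boundary trace in pixel units.
make_trace <- function(pts, ppr = 1) {
  structure(list(points = pts, px_per_tube_radius = ppr),
            class = "boundary_trace")
}

# Sampled circle (x0, y0, r) as an m-point counter-clockwise trace.
circle_trace <- function(m = 200, r = 30, x0 = 40, y0 = 40) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  cbind(x0 + r * cos(th), y0 + r * sin(th))
}

# Binary raster of a disk, row = y up, pixel-centre convention.
disk_binary <- function(r, cx, cy, side) {
  g <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))
  b <- matrix(FALSE, side, side)
  b[cbind(g$y + 1, g$x + 1)] <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  b
}

# Discrete 3-point signed curvature at node i of a closed CCW polygon.
node_curvature <- function(p, i) {
  p <- unclass(p)
  n <- nrow(p)
  A <- p[(i - 2) %% n + 1, ]; B <- p[(i - 1) %% n + 1, ]; C <- p[i %% n + 1, ]
  2 * ((B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])) /
    (sqrt(sum((B - A)^2)) * sqrt(sum((C - B)^2)) * sqrt(sum((C - A)^2)))
}

# Chord lengths of a closed polygon.
node_spacings <- function(p) {
  p <- unclass(p)
  sqrt(rowSums(diff(rbind(p, p[1, , drop = FALSE]))^2))
}

# Independent solid-of-revolution oracle: Pappus' theorem on the upper-half
# polygon (area times 2 pi times centroid height), a different route than
# the package's line-integral formula.
pappus_volume <- function(profile) {
  p <- unclass(profile)
  upper <- p[p[, 2] >= -1e-9, , drop = FALSE]
  x <- upper[, 1]; y <- upper[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  ybar <- sum((y + yn) * cr) / (6 * A)
  2 * pi * abs(A) * ybar
}

# Well-separated three-class toy set for optimiser sanity checks.
toy_classification_set <- function(seed = 11) {
  withr::with_seed(seed, {
    mk <- function(n, mx, my) cbind(rnorm(n, mx, 0.3), rnorm(n, my, 0.3))
    x <- rbind(mk(14, 2, 0), mk(13, -2, 2), mk(13, -2, -2))
    list(x = x, kind = rep(c("NH", "SK", "HK"), c(14, 13, 13)),
         y = cbind(0.05 + 0.01 * x[, 1]^2, 0.1 + 0.01 * x[, 2]^2))
  })
}

# Node matrix of sample i of a dataset.
dataset_profile_for_test <- function(ds, i)
  matrix(ds$samples[[i]]$vector, ncol = 2, byrow = TRUE)

# The full-scale recovery runs are expensive (six trainings); several test
# blocks read different aspects of the same runs, so they are computed once
# per session and memoised.
.recovery_cache <- new.env(parent = emptyenv())
recovery_runs <- function(node_count) {
  key <- paste0("n", node_count)
  if (is.null(.recovery_cache[[key]]))
    .recovery_cache[[key]] <- run_recovery_study(
      node_counts = node_count, seeds = 1:3, n_train = 400, n_test = 100)
  .recovery_cache[[key]]
}
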