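# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Signed area of a closed polygon (shoelace); positive when counter-clockwise.
polygon_area <- function(nodes) {
  x <- nodes[, 1]; y <- nodes[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Area-weighted centroid of a closed polygon.
polygon_centroid <- function(nodes) {
  x <- nodes[, 1]; y <- nodes[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Perimeter of a closed polygon.
polygon_perimeter <- function(nodes) {
  d <- diff(rbind(nodes, nodes[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Volume of the solid of revolution of a closed footprint profile
#'
#' Revolves the region bounded by a closed, axisymmetric (about the x axis)
#' profile around the x axis and returns the enclosed volume, computed as
#' the line integral \eqn{V = -\pi \oint y^2 \, dx} over the
#' counter-clockwise contour, restricted to its upper half. Handles
#' non-convex (parachute-like) rears where the upper generatrix folds in x.
#'
#' @param nodes Two-column matrix of contour coordinates (closed polyline,
#'   last edge implicit), counter-clockwise, in tube-radius units, or a
#'   [steady_profile()] object.
#' @return Enclosed volume of revolution (tube-radius units cubed).
#' @export
revolution_volume <- function(nodes) {
  if (inherits(nodes, "capsule_profile")) nodes <- unclass(nodes)
  x <- nodes[, 1]; y <- nodes[, 2]
  # upper-half contribution only; the axisymmetric lower half would cancel
  yu <- pmax(y, 0)
  xn <- c(x[-1], x[1]); yn <- c(yu[-1], yu[1])
  -pi * sum((yu^2 + yu * yn + yn^2) / 3 * (xn - x))
}

# Even-odd (ray casting) point-in-polygon test, vectorised over query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    crosses <- (ys[k] > py) != (ye[k] > py)
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}
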