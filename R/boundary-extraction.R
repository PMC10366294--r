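#' @title Image-processing chain: camera image to feature vector
#' @description
#' Converts a camera-style grayscale image of a capsule in tube flow into
#' the 1D boundary-coordinate feature vector consumed by the network:
#' background subtraction and binarisation ([preprocess_image()]), border
#' following ([trace_boundary()]), piecewise-quadratic smoothing with equal
#' arc-length resampling ([smooth_and_resample()]), and flattening
#' ([to_feature_vector()]). [extract_profile()] chains the four steps.
#' @name boundary_extraction
NULL

#' Background-subtract, binarise and centre a capsule image
#'
#' Subtracts the background frame (when given) to remove the channel and
#' static noise, thresholds the absolute difference (Otsu's rule by
#' default), keeps the largest connected foreground component, and centres
#' it in a square region of interest whose side is the tube diameter in
#' pixels.
#'
#' @param image A `capsule_image` or a numeric pixel matrix (row = y from
#'   the bottom, col = x).
#' @param background Optional background frame of the same shape.
#' @param tube_diameter_px Side of the square RoI. Defaults to the full
#'   image width for a `capsule_image` (whose frame spans the tube
#'   diameter).
#' @param threshold `"otsu"` (default) or a fixed numeric threshold on the
#'   background-subtracted gray values.
#' @return Logical matrix of side `tube_diameter_px` (TRUE = capsule), with
#'   attribute `px_per_tube_radius = tube_diameter_px / 2`.
#' @export
preprocess_image <- function(image, background = NULL,
                             tube_diameter_px = NULL, threshold = "otsu") {
  px <- if (inherits(image, "capsule_image")) image$pixels else
    as.matrix(image)
  if (is.null(tube_diameter_px)) {
    if (!inherits(image, "capsule_image"))
      stop("'tube_diameter_px' is required for a bare pixel matrix")
    tube_diameter_px <- ncol(px)
  }
  if (!is.null(background)) {
    bg <- if (inherits(background, "capsule_image")) background$pixels else
      as.matrix(background)
    if (!all(dim(bg) == dim(px)))
      stop("image and background must have the same shape")
    d <- abs(px - bg)
  } else {
    d <- px - min(px)
  }
  thr <- if (identical(threshold, "otsu")) {
    rg <- range(d)
    if (diff(rg) <= 0) Inf else EBImage::otsu(d, range = rg, levels = 256L)
  } else {
    as.numeric(threshold)
  }
  binary <- d > thr
  if (!any(binary)) stop("no foreground component")
  lab <- EBImage::bwlabel(binary)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  comp <- which(lab == keep, arr.ind = TRUE)  # [row = y + 1, col = x + 1]
  side <- as.integer(tube_diameter_px)
  ctr <- round(colMeans(comp))
  shift <- c((side + 1L) %/% 2L, (side + 1L) %/% 2L) - ctr
  moved <- sweep(comp, 2, -shift)
  if (any(moved < 2L) || any(moved > side - 1L))
    stop("capsule touches the RoI border after centring; ",
         "increase 'tube_diameter_px'")
  roi <- matrix(FALSE, side, side)
  roi[moved] <- TRUE
  structure(roi, px_per_tube_radius = side / 2)
}

#' Trace the outer boundary of a binary object
#'
#' Border following in the style of Suzuki and Abe's algorithm
#' (Moore-neighbour tracing with Jacob's stopping criterion): starting from
#' the first foreground pixel in raster order, walks the 8-connected outer
#' border and returns the border pixels sorted counter-clockwise in
#' mathematical (y up) orientation. For blob-like objects every border
#' pixel appears exactly once; for degenerately thin parts (1 px wide) the
#' walk passes both sides and duplicate visits are dropped, keeping
#' first-visit order.
#'
#' @param binary Logical (or 0/1) matrix, row = y from the bottom. Must
#'   contain exactly one 8-connected foreground component of at least 4
#'   pixels.
#' @return A `boundary_trace`: list with `points` (m x 2 matrix of 0-based
#'   pixel-centre (x, y) coordinates, counter-clockwise, first adjacent to
#'   last) and `px_per_tube_radius` (carried over from [preprocess_image()],
#'   `NA` otherwise).
#' @export
trace_boundary <- function(binary) {
  b <- binary > 0
  npix <- sum(b)
  if (npix == 0) stop("no foreground component")
  if (npix < 4) stop("component has fewer than 4 pixels")
  if (max(EBImage::bwlabel(b)) > 1L)
    stop("multiple foreground components")
  nr <- nrow(b); nc <- ncol(b)
  fg <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc &&
    b[p[1], p[2]]
  # Moore neighbourhood ring (row = y up), fixed scanning order; consecutive
  # ring positions are mutually adjacent. Final orientation is enforced by
  # the polygon area sign below.
  offs <- rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  start <- which(b, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  start <- as.integer(start)
  # raster scan arrives at `start` from its (background) west neighbour
  ring_index <- function(p, q) {
    d <- q - p
    which(offs[, 1] == d[1] & offs[, 2] == d[2])
  }
  path <- matrix(0L, 8L * npix + 8L, 2L)
  p <- start
  bk <- start + offs[5L, ]              # last background pixel examined
  k <- 1L
  path[k, ] <- p
  state0 <- c(p, ring_index(p, bk))
  repeat {
    ci <- ring_index(p, bk)
    nxt <- NULL
    for (j in 1:8) {
      d <- (ci + j - 1L) %% 8L + 1L
      q <- p + offs[d, ]
      if (fg(q)) { nxt <- q; break }
      bk <- q
    }
    if (is.null(nxt)) break              # isolated pixel; excluded by npix >= 4
    p <- nxt
    if (all(c(p, ring_index(p, bk)) == state0) || k >= nrow(path)) break
    k <- k + 1L
    path[k, ] <- p
  }
  pts <- path[seq_len(k), , drop = FALSE]
  pts <- pts[!duplicated(pts), , drop = FALSE]
  xy <- cbind(pts[, 2] - 1L, pts[, 1] - 1L)  # (x, y), 0-based
  if (nrow(xy) >= 3 && polygon_area(xy) < 0)
    xy <- xy[c(1L, rev(seq_len(nrow(xy))[-1L])), , drop = FALSE]
  structure(list(points = xy,
                 px_per_tube_radius =
                   attr(binary, "px_per_tube_radius") %||% NA_real_),
            class = "boundary_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("boundary trace: %d border pixels\n", nrow(x$points)))
  invisible(x)
}

#' Smooth a pixel boundary and resample it at equal arc length
#'
#' The raw border-following trace is a staircase of pixel centres. Each
#' trace point is replaced by the value of a least-squares quadratic fitted
#' to a window of `window_px` consecutive points in a local frame rotated
#' onto the window's chord (so the fit is single-valued along the local
#' tangent). The smoothed closed polyline is then interpolated by a
#' periodic spline, re-parametrised by cumulative chord length, and sampled
#' at `n_nodes` equal arc increments starting from the leading tip (the
#' maximum-x point; ties broken towards smaller y), counter-clockwise.
#' Coordinates are rescaled to tube-radius units and centred on the polygon
#' centroid.
#'
#' @param trace A `boundary_trace` (or a closed m x 2 point matrix).
#' @param n_nodes Number of equally spaced membrane nodes (>= 3).
#' @param window_px Smoothing window in trace points (>= 5; odd values
#'   centre exactly).
#' @param px_per_tube_radius Pixel-to-tube-radius scale; defaults to the
#'   value carried by the trace. Use 1 to stay in pixel units.
#' @return A `capsule_profile` in tube-radius units.
#' @export
smooth_and_resample <- function(trace, n_nodes = 60, window_px = 9,
                                px_per_tube_radius = NULL) {
  pts <- if (inherits(trace, "boundary_trace")) trace$points else
    as.matrix(trace)
  if (is.null(px_per_tube_radius))
    px_per_tube_radius <-
      if (inherits(trace, "boundary_trace")) trace$px_per_tube_radius else
        NA_real_
  if (is.na(px_per_tube_radius))
    stop("'px_per_tube_radius' is unknown; pass it explicitly")
  m <- nrow(pts)
  if (window_px < 5) stop("'window_px' must be at least 5")
  if (window_px > m) stop("smoothing window larger than the trace")
  if (n_nodes < 3) stop("'n_nodes' must be at least 3")
  h <- window_px %/% 2L
  sm <- pts
  for (i in seq_len(m)) {
    idx <- ((i - h - 1L):(i + h - 1L)) %% m + 1L
    w <- pts[idx, , drop = FALSE]
    mu <- colMeans(w)
    chord <- pts[idx[length(idx)], ] - pts[idx[1L], ]
    len <- sqrt(sum(chord^2))
    if (len < .Machine$double.eps) { sm[i, ] <- mu; next }
    u <- chord / len; v <- c(-u[2], u[1])
    wc <- sweep(w, 2, mu)
    tau <- wc %*% u; nu <- wc %*% v
    A <- cbind(1, tau, tau^2)
    beta <- tryCatch(qr.coef(qr(A), nu), error = function(e) NULL)
    if (is.null(beta) || any(is.na(beta))) { sm[i, ] <- mu; next }
    ti <- sum((pts[i, ] - mu) * u)
    ni <- beta[1] + beta[2] * ti + beta[3] * ti^2
    sm[i, ] <- mu + ti * u + ni * v
  }
  if (polygon_area(sm) < 0) sm <- sm[rev(seq_len(m)), , drop = FALSE]
  dense <- densify_closed(sm, 4096L)
  # canonical start: leading tip = maximum-x point, ties towards smaller y
  lead <- order(-dense[, 1], dense[, 2])[1]
  dense <- dense[c(lead:nrow(dense), seq_len(lead - 1L)), , drop = FALSE]
  nodes <- resample_closed(dense, n_nodes) / px_per_tube_radius
  nodes <- sweep(nodes, 2, polygon_centroid(nodes))
  new_capsule_profile(nodes)
}

# Piecewise-linear densification of a closed polyline, parametrised by
# cumulative chord length. Linear (not spline) interpolation: the smoothed
# polyline may still carry pixel-scale residual noise, and an interpolating
# spline would overshoot between points.
densify_closed <- function(xy, n_out) {
  closed <- rbind(xy, xy[1, , drop = FALSE])
  s <- c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; closed <- closed[keep, , drop = FALSE]
  L <- s[length(s)]
  so <- seq(0, L, length.out = n_out + 1L)[-(n_out + 1L)]
  cbind(stats::approx(s, closed[, 1], xout = so)$y,
        stats::approx(s, closed[, 2], xout = so)$y)
}

#' Flatten a profile into the 1D feature vector
#'
#' Canonicalises the node ordering (counter-clockwise, starting at the
#' maximum-x node with ties broken towards smaller y — the leading tip on
#' the symmetry axis), centres the polygon on its area centroid, and
#' interleaves the coordinates as `(x1, y1, x2, y2, ...)` in tube-radius
#' units. The same shape presented with a rotated node numbering or
#' reversed orientation therefore yields the identical vector.
#'
#' @param profile A `capsule_profile` (or bare two-column matrix).
#' @return Numeric vector of length `2 * n_nodes`.
#' @export
to_feature_vector <- function(profile) {
  nodes <- unclass(as.matrix(profile))
  if (polygon_area(nodes) < 0)
    nodes <- nodes[rev(seq_len(nrow(nodes))), , drop = FALSE]
  nodes <- sweep(nodes, 2, polygon_centroid(nodes))
  lead <- order(-nodes[, 1], nodes[, 2])[1]
  nodes <- nodes[c(lead:nrow(nodes), seq_len(lead - 1L)), , drop = FALSE]
  as.vector(t(nodes))
}

#' Rebuild a profile from a feature vector
#'
#' @param vector Numeric feature vector of even length (interleaved x, y).
#' @param diam0 Optional undeformed capsule diameter (tube-radius units).
#' @return A `capsule_profile`.
#' @export
profile_from_vector <- function(vector, diam0 = NA_real_) {
  if (length(vector) %% 2L != 0L) stop("feature vector length must be even")
  new_capsule_profile(matrix(vector, ncol = 2, byrow = TRUE), diam0 = diam0)
}

#' Full image-to-profile extraction chain
#'
#' Runs [preprocess_image()], [trace_boundary()] and
#' [smooth_and_resample()] in sequence.
#'
#' @inheritParams preprocess_image
#' @inheritParams smooth_and_resample
#' @return A `capsule_profile` with `n_nodes` nodes in tube-radius units.
#' @examples
#' img <- rasterize_profile(steady_profile("SK", 0.04, 0.12),
#'                          px_per_diameter = 138)
#' prof <- extract_profile(img)
#' @export
extract_profile <- function(image, background = NULL, n_nodes = 60,
                            window_px = 9, tube_diameter_px = NULL,
                            threshold = "otsu") {
  roi <- preprocess_image(image, background = background,
                          tube_diameter_px = tube_diameter_px,
                          threshold = threshold)
  smooth_and_resample(trace_boundary(roi), n_nodes = n_nodes,
                      window_px = window_px)
}

#' Read and write capsule images as PNG or TIFF
#'
#' Grayscale raster I/O for camera frames. Multi-channel input is averaged
#' to one channel; rows are flipped so that row 1 of the pixel matrix is
#' the bottom of the image (mathematical orientation).
#'
#' @param path File path; extension selects PNG or TIFF.
#' @param px_per_diameter Resolution descriptor to attach (pixels across
#'   the undeformed capsule diameter).
#' @param background_level Optional gray value of the empty field.
#' @return `read_capsule_image()` returns a `capsule_image`;
#'   `write_capsule_image()` returns `path` invisibly.
#' @export
read_capsule_image <- function(path, px_per_diameter = NA_real_,
                               background_level = NA_real_) {
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:3, drop = FALSE], c(1, 2), mean)
  px <- arr[rev(seq_len(nrow(arr))), , drop = FALSE]
  structure(list(pixels = px, px_per_diameter = px_per_diameter,
                 background_level = background_level, diam0 = NA_real_),
            class = "capsule_image")
}

#' @rdname read_capsule_image
#' @param image A `capsule_image` or pixel matrix; values are clipped to
#'   [0, 1] on write.
#' @export
write_capsule_image <- function(image, path) {
  px <- if (inherits(image, "capsule_image")) image$pixels else
    as.matrix(image)
  px <- pmin(pmax(px, 0), 1)
  px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(px, path) else png::writePNG(px, path)
  invisible(path)
}
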