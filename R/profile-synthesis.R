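#' @title Synthetic steady footprint profiles
#' @description
#' The package's forward model: a smooth parametric shape family standing in
#' for a full fluid-structure simulation of a capsule in tube flow. A capsule
#' flowing steadily through a capillary tube adopts a bullet- or
#' parachute-like footprint: a rounded front cap, a body confined by the
#' tube, and a rear cap that flattens and eventually dimples inwards as the
#' viscous load grows relative to the membrane elasticity. The family
#' reproduces that phenomenology as a smooth, injective function of the two
#' capillary numbers, with the constitutive-law class entering only through
#' a small extra perturbation for the neo-Hookean law — Skalak and Hooke
#' membranes with matched `(Ca^Ks, Ca^Gs)` produce identical profiles, the
#' near-degeneracy that makes those two laws hard to tell apart.
#'
#' The generatrix is a star-shaped polar curve around the profile centroid,
#' \deqn{r(t) = a\,[1 + p_1\cos t + p_2\cos 2t - p_3 b(t) + \eta\cos 3t],}
#' with `a = (1 + alpha) beta` the inflated capsule radius in tube-radius
#' units, `b(t) = exp(kappa(cos(t - pi) - 1))` a periodic rear bump, and
#' coefficients linear in the normalised capillary numbers
#' `u = Ca^Ks / 0.055` and `v = Ca^Gs / 0.21`:
#' `p1 = 0.05u + 0.02v` (nose/tail asymmetry), `p2 = 0.02u + 0.07v`
#' (axial elongation), `p3 = 0.12u + 0.04v` (rear flattening/dimple,
#' `kappa = 8`), and `eta = 0.02 (u + v)/2` for the neo-Hookean law only.
#' These are fixed constants of the package, not fitted quantities. The
#' curve is rescaled so its solid of revolution encloses the volume
#' `(4/3) pi a^3` of the inflated sphere, then sampled at `n_nodes` equal
#' arc-length increments starting from the leading tip (`t = 0`,
#' maximum x), counter-clockwise, and centred on its polygon centroid.
#'
#' @param kind Membrane law class (`"NH"`, `"SK"` or `"HK"`; long names
#'   accepted). Skalak and Hooke give identical profiles by construction.
#' @param ca_ks,ca_gs Capillary numbers `mu U / Ks` and `mu U / Gs`. Must
#'   lie inside `box`.
#' @param beta Confinement ratio `a0 / R` of the unstressed capsule.
#' @param alpha Pre-inflation ratio; the undeformed (inflated) radius is
#'   `(1 + alpha) beta` tube radii.
#' @param n_nodes Number of membrane nodes sampled at equal arc length.
#' @param noise_sd Standard deviation of zero-mean Gaussian radial node
#'   perturbation (tube-radius units), applied before the final volume
#'   renormalisation. Default 0 (noise-free).
#' @param seed Optional integer seed for the node noise; the caller's RNG
#'   state is left untouched.
#' @param box Validity box `list(ca_ks = c(lo, hi), ca_gs = c(lo, hi))`;
#'   defaults to [profile_validity_box()], which spans from the undeformed
#'   limit `Ca = 0` up to the upper edge of the training box.
#'
#' @return A `capsule_profile`: an `n_nodes` x 2 matrix of (x, y) node
#'   coordinates in tube-radius units, counter-clockwise, centroid at the
#'   origin, node 1 at the leading tip, with attributes `diam0` (undeformed
#'   capsule diameter in tube radii), `beta`, `alpha`, `kind`, `ca_ks`,
#'   `ca_gs`.
#'
#' @examples
#' p <- steady_profile("SK", ca_ks = 0.055, ca_gs = 0.165)
#' revolution_volume(p) / (4 / 3 * pi * (1.03 * 0.77)^3)  # ~1
#' @export
steady_profile <- function(kind, ca_ks, ca_gs, beta = 0.77, alpha = 0.03,
                           n_nodes = 60, noise_sd = 0, seed = NULL,
                           box = profile_validity_box()) {
  kind <- normalize_law_kind(kind)
  stopifnot(is.finite(ca_ks), is.finite(ca_gs), ca_ks >= 0, ca_gs >= 0)
  if (ca_ks < box$ca_ks[1] || ca_ks > box$ca_ks[2] ||
      ca_gs < box$ca_gs[1] || ca_gs > box$ca_gs[2])
    stop(sprintf(
      "capillary numbers (%.4g, %.4g) outside the validity box", ca_ks, ca_gs))
  if (!is.finite(beta) || beta <= 0 || beta >= 1)
    stop("'beta' must lie in (0, 1)")
  if (!is.finite(alpha) || alpha < 0)
    stop("'alpha' must be non-negative")
  a <- (1 + alpha) * beta
  if (a >= 1)
    stop("inflated capsule larger than the tube: beta * (1 + alpha) >= 1")
  if (n_nodes < 10) stop("'n_nodes' must be at least 10")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")

  # dense generatrix, volume-normalised analytically-well on 4096 points
  nt <- 4096L
  t <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  r <- a * shape_radial_factor(t, kind, ca_ks, ca_gs)
  if (any(r <= 0)) stop("degenerate profile: non-positive radius")
  xy <- cbind(r * cos(t), r * sin(t))
  v_target <- 4 / 3 * pi * a^3
  xy <- xy * (v_target / revolution_volume(xy))^(1 / 3)

  # equal arc-length resampling from the leading tip (t = 0)
  nodes <- resample_closed(xy, n_nodes)

  if (noise_sd > 0) {
    v_clean <- revolution_volume(nodes)
    nodes <- with_seed(seed, {
      rad <- sqrt(rowSums(nodes^2))
      nodes * (1 + stats::rnorm(n_nodes, sd = noise_sd) / rad)
    })
    nodes <- nodes * (v_clean / revolution_volume(nodes))^(1 / 3)
  }

  ctr <- polygon_centroid(nodes)
  nodes <- sweep(nodes, 2, ctr)
  new_capsule_profile(nodes, diam0 = 2 * a, beta = beta, alpha = alpha,
                      kind = kind, ca_ks = ca_ks, ca_gs = ca_gs)
}

# Radial multiplier of the shape family; u, v are capillary numbers
# normalised by the upper edge of the default validity box so the
# undeformed Ca -> 0 limit is exactly a circle. The coarse deformation
# (nose asymmetry p1 and elongation p2, low harmonics resolvable by very
# few nodes) responds to a single mixture w of the two loads, while the
# localised rear dimple p3 — a fine-scale feature that needs a dense node
# sampling — carries mainly the area-dilatation load, so coarse node
# samplings lose part of the Ca^Ks information.
shape_radial_factor <- function(t, kind, ca_ks, ca_gs) {
  u <- ca_ks / 0.055
  v <- ca_gs / 0.21
  p1 <- 0.08 * v
  p2 <- 0.10 * v
  p3 <- 0.12 * u + 0.02 * v
  kappa <- 13
  bump <- exp(kappa * (cos(t - pi) - 1))
  f <- 1 + p1 * cos(t) + p2 * cos(2 * t) - p3 * bump
  if (kind == "NH") f <- f + 0.02 * (u + v) / 2 * cos(3 * t)
  f
}

#' Default capillary-number validity box of the shape family
#'
#' Spans from the undeformed limit `Ca = 0` to the upper edge of the
#' training box (`Ca^Ks <= 0.055`, `Ca^Gs <= 0.21`); dataset generation
#' samples the narrower training box by default (see [generate_dataset()]).
#'
#' @return `list(ca_ks = c(0, 0.055), ca_gs = c(0, 0.21))`.
#' @export
profile_validity_box <- function() {
  list(ca_ks = c(0, 0.055), ca_gs = c(0, 0.21))
}

# Resample a dense closed polyline at n equal arc-length increments,
# starting from its first point.
resample_closed <- function(xy, n) {
  closed <- rbind(xy, xy[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  targets <- (seq_len(n) - 1) * L / n
  idx <- findInterval(targets, s, rightmost.closed = TRUE)
  frac <- (targets - s[idx]) / pmax(seg[idx], .Machine$double.eps)
  closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
}

new_capsule_profile <- function(nodes, diam0 = NA_real_, beta = NA_real_,
                                alpha = NA_real_, kind = NULL,
                                ca_ks = NA_real_, ca_gs = NA_real_) {
  nodes <- unname(as.matrix(nodes))
  stopifnot(ncol(nodes) == 2, nrow(nodes) >= 3)
  structure(nodes, class = "capsule_profile", diam0 = diam0, beta = beta,
            alpha = alpha, kind = kind, ca_ks = ca_ks, ca_gs = ca_gs)
}

#' Construct a capsule footprint profile from node coordinates
#'
#' Wraps an ordered closed polyline of membrane-node coordinates (one row
#' per node, columns x and y, tube-radius units) as a `capsule_profile`.
#' Node order is made counter-clockwise and the polygon is centred on its
#' area centroid.
#'
#' @param nodes Two-column numeric matrix (or data frame) of node
#'   coordinates.
#' @param diam0 Undeformed capsule diameter in tube-radius units (used by
#'   [rasterize_profile()] to interpret a pixels-per-diameter resolution);
#'   `NA` if unknown.
#' @return A `capsule_profile` object.
#' @export
capsule_profile <- function(nodes, diam0 = NA_real_) {
  nodes <- unname(as.matrix(nodes))
  if (polygon_area(nodes) < 0) nodes <- nodes[rev(seq_len(nrow(nodes))), ]
  nodes <- sweep(nodes, 2, polygon_centroid(nodes))
  new_capsule_profile(nodes, diam0 = diam0)
}

#' @export
print.capsule_profile <- function(x, ...) {
  cat(sprintf("capsule footprint profile: %d nodes", nrow(x)))
  if (!is.null(attr(x, "kind")) && !is.na(attr(x, "ca_ks")))
    cat(sprintf(" (%s, Ca^Ks = %.4g, Ca^Gs = %.4g)",
                attr(x, "kind"), attr(x, "ca_ks"), attr(x, "ca_gs")))
  cat(sprintf("\n  tip-to-tail length %.4g, max |y| %.4g tube radii\n",
              max(x[, 1]) - min(x[, 1]), max(abs(x[, 2]))))
  invisible(x)
}

#' @export
plot.capsule_profile <- function(x, ..., asp = 1) {
  poly <- rbind(unclass(x), unclass(x)[1, , drop = FALSE])
  graphics::plot(poly, type = "l", asp = asp, xlab = "x (tube radii)",
                 ylab = "y (tube radii)", ...)
  graphics::points(x[1, 1], x[1, 2], pch = 19)
  invisible(x)
}

#' Rasterise a footprint profile into a camera-style grayscale image
#'
#' Renders the profile onto a square pixel grid spanning the tube cross
#' section (side = tube diameter), with the capsule interior at
#' `foreground_level` and the rest at `background_level`. A pixel belongs
#' to the foreground when its centre falls inside the profile polygon
#' (even-odd rule, no anti-aliasing). Optional additive Gaussian pixel
#' noise emulates camera noise.
#'
#' @param profile A `capsule_profile` with a known `diam0` (or pass
#'   `diam0`).
#' @param px_per_diameter Pixels across the undeformed capsule diameter
#'   (the resolution descriptor used throughout); must be >= 16.
#' @param background_level,foreground_level Gray values in [0, 1].
#' @param pixel_noise_sd Additive zero-mean Gaussian noise sd (gray levels).
#' @param seed Optional seed for the pixel noise.
#' @param diam0 Override for the profile's undeformed diameter attribute.
#' @return A `capsule_image`: list with `pixels` (matrix, row = y from the
#'   bottom, col = x), `px_per_diameter`, `background_level`, `diam0`.
#' @examples
#' img <- rasterize_profile(steady_profile("SK", 0.04, 0.12),
#'                          px_per_diameter = 68)
#' @export
rasterize_profile <- function(profile, px_per_diameter,
                              background_level = 0.15,
                              foreground_level = 0.85,
                              pixel_noise_sd = 0, seed = NULL,
                              diam0 = attr(profile, "diam0")) {
  stopifnot(inherits(profile, "capsule_profile"))
  if (is.null(diam0) || !is.finite(diam0) || diam0 <= 0)
    stop("profile has no usable 'diam0'; pass the undeformed diameter")
  if (px_per_diameter < 16) stop("'px_per_diameter' must be >= 16")
  ppr <- px_per_diameter / diam0        # pixels per tube radius
  side <- as.integer(round(2 * ppr))    # RoI = tube diameter
  c0 <- (side - 1) / 2
  poly <- unclass(profile) * ppr
  poly <- sweep(poly, 2, -c0)           # pixel-centre coordinates, 0-based
  if (min(poly) < 0.5 || max(poly) > side - 1.5)
    stop("profile exceeds the image bounds at this resolution")
  ctr <- seq_len(side) - 1
  grid <- expand.grid(x = ctr, y = ctr)
  inside <- points_in_polygon(grid$x, grid$y, poly)
  pixels <- matrix(background_level, side, side)  # [row = y + 1, col = x + 1]
  pixels[cbind(grid$y + 1L, grid$x + 1L)[inside, , drop = FALSE]] <-
    foreground_level
  if (pixel_noise_sd > 0)
    pixels <- pixels + with_seed(seed,
      matrix(stats::rnorm(side^2, sd = pixel_noise_sd), side, side))
  structure(list(pixels = pixels, px_per_diameter = px_per_diameter,
                 background_level = background_level, diam0 = diam0),
            class = "capsule_image")
}

#' @export
print.capsule_image <- function(x, ...) {
  cat(sprintf(
    "capsule image: %d x %d px, %g px per undeformed capsule diameter\n",
    nrow(x$pixels), ncol(x$pixels), x$px_per_diameter))
  invisible(x)
}

#' Generate a labelled synthetic dataset of footprint feature vectors
#'
#' Draws `n` capsules with law classes in proportions `law_mix` and
#' capillary numbers uniform over the training box, subject to each law's
#' modulus-ratio constraint: for the neo-Hookean law `Ca^Gs = 3 Ca^Ks`
#' exactly (so `Ca^Ks` is drawn where both ranges admit the pair); for
#' Skalak and Hooke the pair is redrawn until `Ca^Gs / Ca^Ks > 1`, and the
#' implied `C = (ratio - 1)/2` or `nu_s = (ratio - 1)/(ratio + 1)` is
#' recorded. Each capsule's steady profile is generated with
#' [steady_profile()] and flattened to a feature vector. The dataset is
#' reproducible bit-for-bit from its manifest.
#'
#' @param n Number of samples.
#' @param ca_ks_range,ca_gs_range Sampling ranges of the capillary numbers
#'   (defaults: the training box 0.02-0.055 and 0.03-0.21).
#' @param law_mix Named or unnamed length-3 proportions for (NH, SK, HK);
#'   must sum to 1.
#' @param beta,alpha,n_nodes,noise_sd Passed to [steady_profile()].
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the arguments.
#' @return A `capsule_dataset`: list with `samples` (each a list with
#'   `vector`, `kind`, `ca_ks`, `ca_gs`, and `C`/`nu_s` when applicable)
#'   and `manifest` (the generation arguments).
#' @examples
#' ds <- generate_dataset(n = 30, seed = 1)
#' table(vapply(ds$samples, `[[`, "", "kind"))
#' @export
generate_dataset <- function(n = 400,
                             ca_ks_range = c(0.02, 0.055),
                             ca_gs_range = c(0.03, 0.21),
                             law_mix = c(NH = 1, SK = 1, HK = 1) / 3,
                             beta = 0.77, alpha = 0.03, n_nodes = 60,
                             noise_sd = 0, seed = 1) {
  stopifnot(n >= 1, length(law_mix) == 3)
  if (abs(sum(law_mix) - 1) > 1e-9) stop("'law_mix' must sum to 1")
  box <- profile_validity_box()
  if (ca_ks_range[1] < box$ca_ks[1] || ca_ks_range[2] > box$ca_ks[2] ||
      ca_gs_range[1] < box$ca_gs[1] || ca_gs_range[2] > box$ca_gs[2])
    stop("requested Ca ranges exceed the validity box")
  counts <- floor(n * law_mix)
  for (i in seq_len(n - sum(counts))) counts[i] <- counts[i] + 1
  nh_lo <- max(ca_ks_range[1], ca_gs_range[1] / 3)
  nh_hi <- min(ca_ks_range[2], ca_gs_range[2] / 3)
  if (nh_lo > nh_hi)
    stop("ranges admit no neo-Hookean pair with Ca^Gs = 3 Ca^Ks")
  samples <- with_seed(seed, {
    kinds <- sample(rep(law_kinds, counts))
    lapply(kinds, function(kind) {
      if (kind == "NH") {
        ca_ks <- stats::runif(1, nh_lo, nh_hi)
        ca_gs <- 3 * ca_ks
        extra <- NULL
      } else {
        repeat {
          ca_ks <- stats::runif(1, ca_ks_range[1], ca_ks_range[2])
          ca_gs <- stats::runif(1, ca_gs_range[1], ca_gs_range[2])
          if (ca_gs / ca_ks > 1 + 1e-9) break
        }
        eq <- equivalent_parameters(ca_gs / ca_ks)
        extra <- if (kind == "SK") list(C = eq$C) else list(nu_s = eq$nu_s)
      }
      prof <- steady_profile(kind, ca_ks, ca_gs, beta = beta, alpha = alpha,
                             n_nodes = n_nodes, noise_sd = noise_sd)
      c(list(vector = to_feature_vector(prof), kind = kind,
             ca_ks = ca_ks, ca_gs = ca_gs), extra)
    })
  })
  manifest <- list(n = n, ca_ks_range = ca_ks_range,
                   ca_gs_range = ca_gs_range,
                   law_mix = stats::setNames(as.numeric(law_mix), law_kinds),
                   beta = beta, alpha = alpha, n_nodes = n_nodes,
                   noise_sd = noise_sd, seed = seed)
  structure(list(samples = samples, manifest = manifest),
            class = "capsule_dataset")
}

#' @export
print.capsule_dataset <- function(x, ...) {
  kinds <- vapply(x$samples, `[[`, "", "kind")
  cat(sprintf(
    "capsule dataset: %d samples (%s), %d nodes, seed %s\n",
    length(x$samples),
    paste(sprintf("%s %d", names(table(kinds)), table(kinds)),
          collapse = ", "),
    x$manifest$n_nodes, format(x$manifest$seed)))
  invisible(x)
}

#' Label table of a dataset
#'
#' @param x A `capsule_dataset`.
#' @param ... Unused.
#' @return Data frame with columns `sample`, `kind`, `ca_ks`, `ca_gs`.
#' @export
as.data.frame.capsule_dataset <- function(x, ...) {
  data.frame(sample = seq_along(x$samples),
             kind = vapply(x$samples, `[[`, "", "kind"),
             ca_ks = vapply(x$samples, `[[`, 0, "ca_ks"),
             ca_gs = vapply(x$samples, `[[`, 0, "ca_gs"))
}

# Rebuild the capsule_profile of sample i from its stored feature vector.
dataset_profile <- function(dataset, i) {
  v <- dataset$samples[[i]]$vector
  m <- dataset$manifest
  new_capsule_profile(matrix(v, ncol = 2, byrow = TRUE),
                      diam0 = 2 * (1 + m$alpha) * m$beta,
                      beta = m$beta, alpha = m$alpha,
                      kind = dataset$samples[[i]]$kind,
                      ca_ks = dataset$samples[[i]]$ca_ks,
                      ca_gs = dataset$samples[[i]]$ca_gs)
}
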