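a0 <- 1.03 * 0.77  # inflated capsule radius in tube radii

test_that("the undeformed limit is a circle of the inflated radius", {
  for (kind in c("NH", "SK", "HK")) {
    p <- steady_profile(kind, ca_ks = 0, ca_gs = 0)
    r <- sqrt(rowSums(unclass(p)^2))
    expect_lt(max(abs(r - a0)), 1e-6)
  }
})

test_that("profiles enclose the inflated-sphere volume of revolution", {
  target <- 4 / 3 * pi * a0^3
  cases <- list(c(0.02, 0.03), c(0.055, 0.165), c(0.0375, 0.21),
                c(0.055, 0.055 * 3))
  for (kind in c("NH", "SK")) {
    for (ca in cases) {
      p <- steady_profile(kind, ca[1], ca[2])
      expect_equal(pappus_volume(p), target, tolerance = 5e-3)
    }
  }
  # renormalisation also holds for noisy profiles (implementation route)
  pn <- steady_profile("SK", 0.04, 0.12, noise_sd = 0.004, seed = 7)
  expect_equal(revolution_volume(pn), revolution_volume(
    steady_profile("SK", 0.04, 0.12)), tolerance = 5e-3)
})

test_that("profiles satisfy the node-polyline invariants", {
  # law-consistent pairs: the NH law only admits Ca^Gs = 3 Ca^Ks
  cases <- rbind(
    expand.grid(ck = c(0.02, 0.055), cg = c(0.03, 0.21), kind = "SK",
                stringsAsFactors = FALSE),
    data.frame(ck = c(0.02, 0.055), cg = 3 * c(0.02, 0.055), kind = "NH"))
  grid <- merge(cases, data.frame(n = c(10L, 60L)))
  for (i in seq_len(nrow(grid))) {
    p <- steady_profile(grid$kind[i], grid$ck[i], grid$cg[i],
                        n_nodes = grid$n[i])
    nodes <- unclass(p)
    expect_lt(max(abs(capmech:::polygon_centroid(nodes))), 1e-9)
    expect_gt(capmech:::polygon_area(nodes), 0)          # counter-clockwise
    sp <- node_spacings(p)
    expect_lt(stats::sd(sp) / mean(sp), 0.01)            # equal arc length
    expect_lt(max(abs(nodes[, 2])), 1)                   # inside the tube
    expect_equal(which.max(nodes[, 1]), 1L)              # tip-first ordering
  }
})

test_that("Skalak and Hooke profiles coincide while neo-Hookean separates", {
  sk <- steady_profile("SK", 0.055, 0.165)
  hk <- steady_profile("HK", 0.055, 0.165)
  nh <- steady_profile("NH", 0.055, 0.165)
  d_sk_hk <- mean_hausdorff(sk, hk)
  d_nh_sk <- mean_hausdorff(nh, sk)
  expect_lt(d_sk_hk, 0.01)
  expect_gt(d_nh_sk, 5 * max(d_sk_hk, 1e-4))
})

test_that("tip-to-tail length grows with the shear capillary number", {
  for (ck in seq(0.02, 0.055, length.out = 5)) {
    len <- vapply(seq(0.03, 0.21, length.out = 5), function(cg) {
      p <- steady_profile("SK", ck, cg)
      max(p[, 1]) - min(p[, 1])
    }, 0)
    expect_true(all(diff(len) >= 0))
  }
})

test_that("the rear cap flattens and dimples as the load grows", {
  # node 31 of 60 sits at the rear pole (equal arcs from the leading tip)
  curv <- vapply(c(0.005, 0.02, 0.0375, 0.055), function(ck)
    node_curvature(steady_profile("SK", ck, 0.12), 31L), 0)
  expect_true(all(diff(curv) < 0))
  expect_gt(curv[1], 0)   # convex near the undeformed limit
  expect_lt(curv[4], 0)   # concave (parachute) at high load
})

test_that("profile generation is seeded and validates its inputs", {
  p1 <- steady_profile("SK", 0.04, 0.12, noise_sd = 0.005, seed = 3)
  p2 <- steady_profile("SK", 0.04, 0.12, noise_sd = 0.005, seed = 3)
  p3 <- steady_profile("SK", 0.04, 0.12, noise_sd = 0.005, seed = 4)
  expect_identical(unclass(p1), unclass(p2))
  expect_false(identical(unclass(p1), unclass(p3)))
  expect_error(steady_profile("SK", 0.1, 0.1), "validity box")
  expect_error(steady_profile("SK", 0.04, 0.3), "validity box")
  expect_error(steady_profile("SK", 0.04, 0.12, beta = 0.99, alpha = 0.05),
               "larger than the tube")
  expect_error(steady_profile("SK", 0.04, 0.12, n_nodes = 6), "at least 10")
})

test_that("rasterisation reproduces areas, is binary and is seeded", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- capsule_profile(0.7 * cbind(cos(th), sin(th)), diam0 = 1.4)
  img <- rasterize_profile(circ, px_per_diameter = 138)
  # a circle of radius half the reference diameter covers pi * 69^2 px
  count <- sum(img$pixels == 0.85)
  expect_lt(abs(count - pi * 69^2) / (pi * 69^2), 0.02)
  expect_identical(sort(unique(as.vector(img$pixels))), c(0.15, 0.85))
  n1 <- rasterize_profile(circ, 64, pixel_noise_sd = 0.02, seed = 5)
  n2 <- rasterize_profile(circ, 64, pixel_noise_sd = 0.02, seed = 5)
  n3 <- rasterize_profile(circ, 64, pixel_noise_sd = 0.02, seed = 6)
  expect_identical(n1$pixels, n2$pixels)
  expect_false(identical(n1$pixels, n3$pixels))
  expect_error(rasterize_profile(circ, 8), ">= 16")
  big <- capsule_profile(1.2 * cbind(cos(th), sin(th)), diam0 = 1.4)
  expect_error(rasterize_profile(big, 64), "bounds")
})

test_that("dataset generation honours counts, constraints and ranges", {
  ds <- generate_dataset(n = 400, seed = 2)
  expect_length(ds$samples, 400)
  lab <- as.data.frame(ds)
  expect_equal(as.vector(table(lab$kind)[c("NH", "SK", "HK")]),
               c(134, 133, 133))
  nh <- lab[lab$kind == "NH", ]
  expect_equal(nh$ca_gs, 3 * nh$ca_ks, tolerance = 1e-12)
  expect_true(all(lab$ca_ks >= 0.02 & lab$ca_ks <= 0.055))
  expect_true(all(lab$ca_gs >= 0.03 & lab$ca_gs <= 0.21))
  expect_true(all(lab$ca_gs / lab$ca_ks > 1))
  expect_error(generate_dataset(10, law_mix = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(generate_dataset(10, ca_ks_range = c(0.02, 0.2)),
               "validity box")
})

test_that("datasets are reproducible bit-for-bit from their manifest", {
  ds <- generate_dataset(n = 25, seed = 42, noise_sd = 0.002)
  m <- ds$manifest
  re <- generate_dataset(m$n, m$ca_ks_range, m$ca_gs_range, m$law_mix,
                         m$beta, m$alpha, m$n_nodes, m$noise_sd, m$seed)
  expect_identical(ds$samples, re$samples)
})

test_that("datasets round-trip through the directory format", {
  ds <- generate_dataset(n = 8, n_nodes = 20, seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "sample_0008.csv")))
  back <- read_dataset(dir)
  expect_equal(lapply(back$samples, `[[`, "vector"),
               lapply(ds$samples, `[[`, "vector"), tolerance = 1e-12)
  expect_identical(vapply(back$samples, `[[`, "", "kind"),
                   vapply(ds$samples, `[[`, "", "kind"))
})
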