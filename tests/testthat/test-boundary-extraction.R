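test_that("preprocessing binarises, subtracts background and centres", {
  prof <- steady_profile("SK", 0.03, 0.09)
  img <- rasterize_profile(prof, px_per_diameter = 100)
  roi <- preprocess_image(img)
  # noise-free disk-like object: pixel count matches the polygon area
  area_px <- capmech:::polygon_area(unclass(prof)) *
    (100 / attr(prof, "diam0"))^2
  expect_lt(abs(sum(roi) - area_px) / area_px, 0.02)
  expect_identical(dim(roi), dim(img$pixels))
  # component centroid lands on the RoI centre to the nearest pixel
  comp <- which(roi, arr.ind = TRUE)
  ctr <- round(colMeans(comp))
  expect_true(all(abs(ctr - (dim(roi)[1] + 1) %/% 2) <= 1))
})

test_that("background subtraction removes static offsets exactly", {
  prof <- steady_profile("SK", 0.04, 0.12)
  img <- rasterize_profile(prof, px_per_diameter = 80)
  bg <- img$pixels * 0 + img$background_level
  r1 <- preprocess_image(img, background = bg)
  # shifting both frames by a constant gray level changes nothing
  r2 <- preprocess_image(img$pixels + 10 / 255, background = bg + 10 / 255,
                         tube_diameter_px = ncol(img$pixels))
  expect_identical(unname(r1), unname(r2))
  expect_error(preprocess_image(bg, background = bg,
                                tube_diameter_px = ncol(bg)),
               "no foreground")
  expect_error(preprocess_image(img, background = bg[1:10, 1:10]),
               "same shape")
})

test_that("preprocessing rejects capsules that cannot be centred", {
  b <- matrix(0.1, 40, 40)
  b[5:35, 5:35] <- 0.9
  expect_error(preprocess_image(b, tube_diameter_px = 20), "RoI border")
})

test_that("border following matches enumerated borders on small objects", {
  # 3 x 3 block: border = the block minus its centre, 8 pixels
  b <- matrix(FALSE, 7, 7); b[3:5, 3:5] <- TRUE
  tr <- trace_boundary(b)
  expect_identical(nrow(tr$points), 8L)
  want <- expand.grid(x = 2:4, y = 2:4)
  want <- want[!(want$x == 3 & want$y == 3), ]
  expect_setequal(paste(tr$points[, 1], tr$points[, 2]),
                  paste(want$x, want$y))
  # closed under 8-connectivity, counter-clockwise
  expect_true(max(abs(tr$points[1, ] - tr$points[8, ])) <= 1)
  expect_gt(capmech:::polygon_area(tr$points), 0)
})

test_that("border following covers degenerate one-pixel-thick objects", {
  b <- matrix(FALSE, 7, 9); b[4, 3:7] <- TRUE
  tr <- trace_boundary(b)
  got <- paste(tr$points[, 1], tr$points[, 2])
  expect_setequal(got, paste(2:6, 3))
})

test_that("border following stays within one pixel of a true circle", {
  b <- disk_binary(r = 20, cx = 30, cy = 30, side = 61)
  tr <- trace_boundary(b)
  dev <- abs(sqrt((tr$points[, 1] - 30)^2 + (tr$points[, 2] - 30)^2) - 20)
  expect_lt(max(dev), 1)
})

test_that("border following validates its input", {
  b <- matrix(FALSE, 9, 9); b[2:3, 2:3] <- TRUE; b[7:8, 7:8] <- TRUE
  expect_error(trace_boundary(b), "multiple")
  s <- matrix(FALSE, 5, 5); s[2, 2:3] <- TRUE
  expect_error(trace_boundary(s), "fewer than 4")
  expect_error(trace_boundary(matrix(FALSE, 4, 4)), "no foreground")
})

test_that("smoothing and resampling reproduce an exact circle", {
  tr <- make_trace(circle_trace(m = 200, r = 30))
  prof <- smooth_and_resample(tr, n_nodes = 60)
  r <- sqrt(rowSums(unclass(prof)^2))
  expect_lt(max(abs(r - 30)), 0.1)
  ang <- atan2(prof[, 2], prof[, 1])
  gaps <- (diff(c(ang, ang[1])) + 2 * pi) %% (2 * pi)
  expect_lt(max(abs(gaps - mean(gaps))) / mean(gaps), 0.01)
})

test_that("equal arc-length spacing holds even for four nodes on a square", {
  s <- seq(0, 0.99, 0.01)
  sq <- rbind(cbind(10 + 20 * s, 10), cbind(30, 10 + 20 * s),
              cbind(30 - 20 * s, 30), cbind(10, 30 - 20 * s))
  p4 <- smooth_and_resample(make_trace(sq), n_nodes = 4)
  seg <- node_spacings(p4)
  per <- sum(seg)
  expect_lt(max(abs(seg - per / 4)) / (per / 4), 0.01)
})

test_that("smoothing halves the staircase error of a corrupted circle", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  for (run in c(2, 3)) {
    stair <- rep(rep(c(1, -1), each = run), length.out = 180)
    jit <- cbind(40 + (30 + stair) * cos(th), 40 + (30 + stair) * sin(th))
    raw_max <- max(abs(sqrt((jit[, 1] - 40)^2 + (jit[, 2] - 40)^2) - 30))
    sm <- smooth_and_resample(make_trace(jit), n_nodes = 60)
    sm_max <- max(abs(sqrt(rowSums(unclass(sm)^2)) - 30))
    expect_lt(sm_max, 0.5 * raw_max)
  }
})

test_that("smoothing validates window and scale arguments", {
  tr <- make_trace(circle_trace(m = 50))
  expect_error(smooth_and_resample(tr, window_px = 3), "at least 5")
  expect_error(smooth_and_resample(tr, window_px = 60), "larger than")
  expect_error(
    smooth_and_resample(make_trace(circle_trace(m = 50), ppr = NA_real_)),
    "px_per_tube_radius")
})

test_that("feature vectors are canonical, centred and reconstructable", {
  prof <- steady_profile("NH", 0.03, 0.09, n_nodes = 40)
  v <- to_feature_vector(prof)
  expect_length(v, 80L)
  xs <- v[seq(1, 80, 2)]; ys <- v[seq(2, 80, 2)]
  nodes <- cbind(xs, ys)
  expect_lt(max(abs(capmech:::polygon_centroid(nodes))), 1e-9)
  # rotated node numbering and reversed orientation give the same vector
  rot <- unclass(prof)[c(17:40, 1:16), ]
  expect_equal(to_feature_vector(capsule_profile(rot)), v, tolerance = 1e-9)
  rev_ <- unclass(prof)[40:1, ]
  expect_equal(to_feature_vector(capsule_profile(rev_)), v, tolerance = 1e-9)
  back <- profile_from_vector(v)
  expect_equal(unclass(back), nodes, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(profile_from_vector(v[-1]), "even")
})

test_that("image to profile round trip stays below one pixel at 138 px", {
  errs <- vapply(1:5, function(i) {
    ck <- 0.019 + 0.007 * i; cg <- min(0.03 + 0.035 * i, 0.21)
    prof <- steady_profile("SK", ck, cg)
    img <- rasterize_profile(prof, px_per_diameter = 138)
    got <- extract_profile(img)
    profile_node_error(got, prof) * 138 / attr(prof, "diam0")
  }, 0)
  expect_lt(mean(errs), 1)
})

test_that("capsule images round-trip through PNG and TIFF files", {
  prof <- steady_profile("SK", 0.04, 0.12)
  img <- rasterize_profile(prof, px_per_diameter = 64)
  for (ext in c(".png", ".tiff")) {
    f <- withr::local_tempfile(fileext = ext)
    write_capsule_image(img, f)
    back <- read_capsule_image(f, px_per_diameter = 64)
    expect_equal(dim(back$pixels), dim(img$pixels))
    expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)
    # extraction from the re-read image matches the direct chain
    p1 <- extract_profile(back, tube_diameter_px = ncol(img$pixels))
    p2 <- extract_profile(img)
    expect_lt(mean_hausdorff(p1, p2), 1e-6)
  }
})
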