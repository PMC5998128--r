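test_that("eccentricity hits its analytic limits: circle 0, segment 1", {
  expect_lte(eccentricity(shape_disc(20)), 0.1)
  expect_gte(eccentricity(shape_line(50)), 0.99)
  # an off-centre disc (no exact symmetry) stays near 0
  m <- matrix(FALSE, 50, 50)
  rr <- row(m); cc <- col(m)
  m[(rr - 25.3)^2 + (cc - 24.6)^2 <= 15.2^2] <- TRUE
  expect_lte(eccentricity(m), 0.15)
  expect_equal(eccentricity(cbind(3, 4)), 0)  # single pixel by definition
  expect_error(eccentricity(matrix(FALSE, 3, 3)), "empty")
})

test_that("eccentricity of a rasterized ellipse matches the conic closed form", {
  for (th in c(0, pi / 7, pi / 3)) {
    e <- shape_ellipse(10, 6, th)
    expect_equal(eccentricity(e), sqrt(1 - 36 / 100), tolerance = 0.05)
  }
})

test_that("compactness follows 4*pi*A/P^2 with its analytic anchors", {
  r <- 10
  expect_equal(compactness(pi * r^2, 2 * pi * r), 1)
  s <- 7
  expect_equal(compactness(s^2, 4 * s), pi / 4)
  expect_equal(compactness(1, 2 * sqrt(pi), warn = FALSE), 1)
  expect_error(compactness(4, 0), "positive")
  expect_warning(compactness(10, 2), "compactness > 1")
})

test_that("perimeter of a rasterized disc is within 5% of the circumference", {
  for (r in c(12, 20, 35)) {
    p <- perimeter(shape_disc(r))
    expect_lt(abs(p - 2 * pi * r) / (2 * pi * r), 0.05)
  }
  expect_equal(perimeter(cbind(5, 5)), 1)   # single pixel by definition
})

test_that("convex area bounds the region and detects concavity", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  expect_equal(convex_area(sq), 9, tolerance = 1)

  tromino <- matrix(FALSE, 4, 4)
  tromino[2, 2] <- TRUE; tromino[3, 2] <- TRUE; tromino[3, 3] <- TRUE
  expect_gt(convex_area(tromino), 3)

  # C-shaped annulus sector: hull much larger than the region
  m <- matrix(FALSE, 61, 61)
  rr <- row(m) - 31; cc <- col(m) - 31
  rad <- sqrt(rr^2 + cc^2); ang <- atan2(rr, cc)
  m[rad >= 18 & rad <= 25 & abs(ang) >= pi / 3] <- TRUE
  expect_gte(convex_area(m) / sum(m), 1.3)
})

test_that("solidity and extent are ratios bounded by 1 on filled shapes", {
  rect <- matrix(TRUE, 6, 9)
  f <- component_features(rect, warn = FALSE)
  expect_equal(f$extent, 1)
  expect_gt(f$solidity, 0.97)
  expect_lte(f$solidity, 1)

  disc <- component_features(shape_disc(20))
  expect_equal(disc$extent, pi / 4, tolerance = 0.05)
  expect_error(solidity(5, 0), "positive")
  expect_error(extent(5, 0), "positive")
})

test_that("featurize returns one complete record per component in label order", {
  m <- matrix(FALSE, 40, 80)
  m[5:25, 5:25][shape_disc(8, pad = 2)] <- TRUE   # disc
  m[18, 40:75] <- TRUE                            # line
  lf <- connected_components(m, 8, min_area_px = 4)
  expect_equal(lf$n_components, 2L)
  f <- suppressWarnings(featurize(lf, um_per_pixel = 0.5))
  expect_equal(f$label, c(1L, 2L))
  expect_equal(f$area_um2, f$area_px * 0.25)
  expect_true(all(f$eccentricity >= 0 & f$eccentricity <= 1))
  expect_true(all(f$solidity <= 1 + 1e-9))
  expect_true(all(f$extent <= 1 + 1e-9))
  expect_true(all(f$convex_area_px >= f$area_px - 1e-9))
  # the disc is round and compact; the line is elongated
  disc_row <- which.max(f$compactness)
  line_row <- which.max(f$eccentricity)
  expect_false(disc_row == line_row)
  expect_lt(f$eccentricity[disc_row], 0.2)
  expect_gt(f$eccentricity[line_row], 0.99)
})

test_that("filament chains order as elongated/low-compactness vs discs", {
  spec <- scene_spec(image_size = c(500, 700),
                     counts = c(C_M = 8, C_A = 4),
                     filament = list(cells_mean = 12, cells_sd = 0,
                                     cell_length_um = 6.83, width_um = 5.0,
                                     curvature = 0.15, overlap_frac = 0.1),
                     seed = 9)
  sc <- generate_scene(spec)
  cfg <- test_config()
  a <- analyze_image(sc$image, cfg)
  f <- a$features
  truth_class <- sc$truth$per_object$class[
    vapply(seq_len(nrow(f)), function(i) {
      px <- which(a$field$labels == f$label[i])
      as.integer(names(which.max(table(sc$truth$mask[px]))))
    }, 0L)]
  fil <- truth_class == "C_A"
  expect_true(all(f$eccentricity[fil] >= 0.9))
  expect_true(all(f$compactness[fil] <= 0.65))
  expect_true(min(f$eccentricity[fil]) > max(f$eccentricity[!fil]))
  expect_true(max(f$compactness[fil]) < min(f$compactness[!fil]))
})

test_that("shape descriptors are scale-covariant and rotation-robust", {
  # adequately resolved shapes: chain-code discretization bias shrinks with
  # size, so invariance is asserted above ~20 px semi-axes
  f1 <- component_features(shape_ellipse(20, 12, pi / 5))
  f2 <- component_features(shape_ellipse(40, 24, pi / 5))
  expect_lt(abs(f2$area_px / f1$area_px - 4) / 4, 0.05)
  for (col in c("eccentricity", "compactness", "solidity", "extent")) {
    expect_lt(abs(f2[[col]] - f1[[col]]) / abs(f1[[col]]), 0.05)
  }
  eccs <- comps <- numeric(0)
  for (th in seq(0, pi * 0.9, length.out = 6)) {
    f <- component_features(shape_ellipse(25, 15, th))
    eccs <- c(eccs, f$eccentricity); comps <- c(comps, f$compactness)
  }
  expect_lte(diff(range(eccs)), 0.05)
  expect_lte(diff(range(comps)), 0.05)
})

test_that("boundary length agrees with an independent contour tracer", {
  set.seed(5)
  for (shape in list(shape_disc(15), shape_ellipse(18, 7, 0.4))) {
    ours <- perimeter(shape)
    oc <- EBImage::ocontour(EBImage::bwlabel(shape * 1L))[[1]]
    d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
    steps <- abs(d[, 1]) + abs(d[, 2])
    ref <- sum(steps == 1) + sqrt(2) * sum(steps == 2)
    expect_equal(ours, ref, tolerance = 0.02 * ref)
  }
})
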