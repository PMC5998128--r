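test_that("unit-cell calibration recovers the area of exact synthetic discs", {
  cfg <- test_config()
  imgs <- calibration_images("C_M", n_images = 2, seed = 40)
  cal <- calibrate_unit_area(imgs, "C_M", cfg)
  expect_equal(cal$species, "C_M")
  # generator discs target a 24.6 um^2 mean projected area
  expect_lt(abs(cal$unit_cell_area_um2 - 24.6) / 24.6, 0.05)
  expect_gte(cal$n_cells, 50)
})

test_that("calibration warns at low n and errors with nothing to retain", {
  cfg <- test_config()
  spec <- scene_spec(image_size = c(120, 120), counts = c(C_M = 1), seed = 3)
  sc <- generate_scene(spec)
  expect_warning(cal <- calibrate_unit_area(list(sc$image), "C_M", cfg),
                 "only 1 cells")
  expect_equal(cal$n_cells, 1L)
  # all components excluded by an impossible eccentricity gate
  expect_error(
    suppressMessages(calibrate_unit_area(list(sc$image), "C_M", cfg,
                                         max_eccentricity = -1)),
    "calibration failed")
})

test_that("unicellular enumeration counts target components exactly", {
  labs <- factor(c(rep("C_M", 12), rep("C_A", 3), "C_N"),
                 levels = class_labels())
  expect_equal(enumerate_unicellular(labs, "C_M"), 12L)
  expect_equal(enumerate_unicellular(labs, "C_K"), 0L)
  expect_equal(enumerate_unicellular(factor(character(0)), "C_M"), 0L)
})

test_that("filamentous enumeration divides class area by the unit-cell area", {
  cal <- calibration_model("C_A", 25, 2.5, 100)
  f <- data.frame(area_um2 = c(250, 100), label = 1:2)
  labs <- c("C_A", "C_M")
  est <- enumerate_filamentous(f, labs, "C_A", cal)
  expect_equal(est$estimated_cells, 10)
  expect_equal(est$total_area_um2, 250)
  # delta-method uncertainty: S * se(u) / u^2
  expect_equal(est$sd, 250 * (2.5 / sqrt(100)) / 25^2)
  none <- enumerate_filamentous(f, c("C_M", "C_M"), "C_A", cal)
  expect_equal(none$estimated_cells, 0)
  expect_error(enumerate_filamentous(f, labs, "C_A"), "calibration_model")
})

test_that("filament-chain scenes are enumerated within 10% by area division", {
  cfg <- test_config()
  cal <- suppressMessages(calibrate_unit_area(
    calibration_images("C_A", n_images = 2, seed = 60), "C_A", cfg,
    max_eccentricity = 0.85))
  spec <- scene_spec(image_size = c(1000, 1200), counts = c(C_A = 8),
                     filament = list(cells_mean = 12, cells_sd = 0,
                                     cell_length_um = 6.83, width_um = 5.0,
                                     curvature = 0.15, overlap_frac = 0.1),
                     seed = 13)
  sc <- generate_scene(spec)
  a <- analyze_image(sc$image, cfg)
  est <- enumerate_filamentous(a$features, a$classes, "C_A", cal)
  expect_lt(abs(est$estimated_cells - 96) / 96, 0.1)
})

test_that("concentration conversion follows the chamber geometry and dilution", {
  cfg <- test_config()     # 1 mm^2 grid x 0.1 mm depth = 1e-4 ml
  expect_equal(to_concentration(100, 1, cfg), 1e6)
  cfg10 <- test_config(dilution_factor = 10)
  expect_equal(to_concentration(100, 1, cfg10), 1e7)
  expect_equal(to_concentration(0, 5, cfg), 0)
  # averaging over images before scaling
  expect_equal(to_concentration(100, 4, cfg), 0.25e6)
})

test_that("mixture proportions normalize counted classes and flag all-zero input", {
  p <- mixture_proportions(c(C_A = 60, C_M = 40))
  expect_equal(unname(p), c(0.6, 0.4))
  expect_equal(sum(p), 1)
  one <- mixture_proportions(c(C_A = 0, C_M = 17, C_N = 5))
  expect_equal(unname(one["C_M"]), 1)
  expect_false("C_N" %in% names(one))
  expect_warning(z <- mixture_proportions(c(C_A = 0, C_M = 0)), "undefined")
  expect_true(all(is.na(z)))
})

test_that("enumeration is additive across images", {
  cfg <- test_config()
  cal <- suppressMessages(calibrate_unit_area(
    calibration_images("C_A", 1, seed = 70), "C_A", cfg,
    max_eccentricity = 0.85))
  mk <- function(seed) generate_scene(scene_spec(
    image_size = c(400, 500), counts = c(C_M = 10, C_A = 2),
    seed = seed))$image
  i1 <- mk(101); i2 <- mk(102)
  joint <- enumerate_images(list(i1, i2), cfg, calibration = cal)
  sep1 <- enumerate_images(list(i1), cfg, calibration = cal)
  sep2 <- enumerate_images(list(i2), cfg, calibration = cal)
  expect_equal(joint$per_class$estimated_cells,
               sep1$per_class$estimated_cells +
                 sep2$per_class$estimated_cells)
  expect_equal(joint$per_class$object_count,
               sep1$per_class$object_count + sep2$per_class$object_count)
})

test_that("total filament cell estimate is invariant to how area is split", {
  cal <- calibration_model("C_A", 26.8, 2.5, 100)
  f_many <- data.frame(area_um2 = rep(26.8 * 3, 4))
  f_one <- data.frame(area_um2 = 26.8 * 12)
  e_many <- enumerate_filamentous(f_many, rep("C_A", 4), "C_A", cal)
  e_one <- enumerate_filamentous(f_one, "C_A", "C_A", cal)
  expect_equal(e_many$estimated_cells, e_one$estimated_cells)
  expect_equal(e_many$estimated_cells, 12)
})
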