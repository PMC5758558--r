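test_that("derived shape parameters follow their definitions", {
  # ideal circle
  r <- 3.5
  s <- derive_shape(pi * r^2, 2 * pi * r, 2 * r, 2 * r)
  expect_equal(s$circularity, 1)
  expect_equal(s$elongation, 1)
  # direct evaluations
  expect_equal(derive_shape(30, 22, 10, 5)$circularity, 4 * pi * 30 / 484,
               tolerance = 1e-12)
  expect_equal(round(derive_shape(30, 22, 10, 5)$circularity, 4), 0.7789)
  expect_equal(round(derive_shape(50, 30, 10.45, 5.59)$elongation, 4),
               1.8694)
  # rasterization overshoot is clipped to 1
  expect_equal(derive_shape(100, 2 * sqrt(100 * pi) * 0.99, 11, 11)$circularity, 1)
  expect_error(derive_shape(-1, 22, 10, 5), "positive")
  expect_error(derive_shape(30, 22, 5, 10), "dmax")
})

test_that("blank and degenerate images segment to zero objects", {
  img <- matrix(0.5, 128, 128)
  m <- segment_image(img)
  expect_equal(max(m$labels), 0)
  expect_length(m$areas, 0)
  expect_equal(nrow(cell_records(img)), 0)
})

test_that("invalid threshold method is a configuration error", {
  expect_error(segmentation_params(threshold_method = "otsu"))
})

test_that("disjoint ellipses are recovered with areas near the analytic truth", {
  sc <- five_ellipse_scene()
  scene <- generate_scene(sc$spec)
  m <- segment_image(scene$image)
  expect_equal(max(m$labels), 5)
  meas <- measure_objects(m)
  for (k in seq_along(sc$objects)) {
    lab <- label_at_center(m, sc$objects[[k]])
    expect_gt(lab, 0)
    row <- meas[meas$label == lab, ]
    tr <- scene$truth[k, ]
    expect_lt(abs(row$area_um2 / tr$area_um2 - 1), 0.03)
    ar <- row$dmax_um / row$dmin_um
    expect_lt(abs(ar / (tr$dmax_um / tr$dmin_um) - 1), 0.03)
  }
})

test_that("touching similar-size ellipses are split into separate cells", {
  sc <- five_ellipse_scene()
  objs <- c(sc$objects, list(scene_object(362, 100, 33, 26, 0.1)))
  # object 6 overlaps object 2 slightly (centres 62 px apart, radii 35+33)
  scene <- generate_scene(scene_spec(objs, 512, 512, noise_sd = 0.01,
                                     seed = 7))
  m <- segment_image(scene$image)
  expect_equal(max(m$labels), 6)
  cb <- classify_budding(m)
  # similar-size lobes: processed as separate unbudded cells
  expect_equal(max(cb$labels), 6)
  expect_false(any(cb$budded, na.rm = TRUE))
})

test_that("calibrated measurements match analytic circles and ellipses", {
  ps <- 0.0975
  sc <- generate_scene(scene_spec(list(scene_object(128, 128, 40, 40)),
                                  256, 256, noise_sd = 0, seed = 1))
  meas <- measure_objects(segment_image(sc$image))
  expect_lt(abs(meas$area_um2 / (pi * (40 * ps)^2) - 1), 0.02)
  expect_lt(abs(meas$dmax_um / meas$dmin_um - 1), 0.02)
  # axis-aligned 2:1 ellipse
  sc2 <- generate_scene(scene_spec(list(scene_object(128, 128, 50, 25)),
                                   256, 256, noise_sd = 0, seed = 1))
  meas2 <- measure_objects(segment_image(sc2$image))
  expect_lt(abs(meas2$dmax_um / meas2$dmin_um / 2 - 1), 0.03)
  # perimeter estimator bias stays inside the tolerance band of the
  # chain-code corrections it uses
  expect_lt(abs(meas$perimeter_um / (2 * pi * 40 * ps) - 1), 0.02)
})

test_that("tiny labels are excluded from measurement with a warning", {
  lab <- matrix(0L, 32, 32)
  lab[10:20, 10:20] <- 1L
  lab[28, 28] <- 2L
  mask <- structure(list(labels = lab, components = lab,
                         areas = tabulate(lab[lab > 0])),
                    class = "labeled_mask")
  expect_warning(meas <- measure_objects(mask), "excluded")
  expect_equal(meas$label, 1L)
})

test_that("budding classification merges bud lobes and keeps pairs apart", {
  # small bud (area ratio 0.25): one budded record
  sc <- generate_scene(scene_spec(list(
    scene_object(150, 150, 30, 30, bud_r = 15),
    scene_object(350, 350, 35, 35)), 512, 512, noise_sd = 0.01, seed = 3))
  m <- segment_image(sc$image)
  expect_equal(max(m$labels), 3)       # watershed sees three lobes
  cb <- classify_budding(m)
  expect_equal(max(cb$labels), 2)
  moth <- cb$labels[150, 150]
  lone <- cb$labels[350, 350]
  expect_true(cb$budded[moth])
  expect_false(cb$budded[lone])
  # measured doublet dimensions near the tangent-circle ground truth
  meas <- measure_objects(cb)
  row <- meas[meas$label == moth, ]
  tr <- sc$truth[1, ]
  expect_lt(abs(row$area_um2 / tr$area_um2 - 1), 0.03)
  expect_lt(abs(row$dmax_um / tr$dmax_um - 1), 0.03)
})

test_that("budding classification is invariant to translation", {
  mk <- function(dx, dy) {
    sc <- generate_scene(scene_spec(list(
      scene_object(150 + dx, 150 + dy, 28, 28, bud_r = 14),
      scene_object(360 + dx, 360 + dy, 33, 33)),
      512, 512, noise_sd = 0.005, seed = 11))
    cb <- classify_budding(segment_image(sc$image))
    sort(cb$budded)
  }
  expect_equal(mk(0, 0), mk(17, -23))
})

test_that("scene generation is deterministic and fully ground-truthed", {
  sc <- five_ellipse_scene()
  a <- generate_scene(sc$spec)
  b <- generate_scene(sc$spec)
  expect_identical(a$image, b$image)
  expect_equal(nrow(a$truth), 5)
  # tangent-circle ground truth for a budded doublet
  ps <- 0.0975
  d <- generate_scene(scene_spec(list(
    scene_object(200, 200, 30, 30, bud_r = 20, bud_overlap = 0)),
    400, 400, noise_sd = 0, seed = 1))
  expect_equal(d$truth$dmax_um, 2 * (30 + 20) * ps)
  expect_equal(d$truth$area_um2, pi * (30^2 + 20^2) * ps^2)
  # invalid scenes are rejected
  expect_error(scene_spec(list(scene_object(5, 5, 40, 30))), "bounds")
  expect_error(scene_spec(list(scene_object(100, 100, 30, 30),
                               scene_object(104, 100, 30, 30))),
               "overlap")
  expect_error(scene_object(100, 100, 30, 30, bud_r = 31), "smaller")
})

test_that("the full pipeline is deterministic and schema-stable", {
  sc <- generate_scene(five_ellipse_scene()$spec)
  r1 <- cell_records(sc$image, condition = "aerobic", time_h = 12)
  r2 <- cell_records(sc$image, condition = "aerobic", time_h = 12)
  expect_identical(r1, r2)
  expect_named(r1, names(empty_cell_records()))
  expect_true(all(r1$circularity <= 1 & r1$circularity > 0))
  expect_true(all(r1$elongation >= 1))
  expect_true(all(r1$dmax_um >= r1$dmin_um))
})

test_that("outlier filtering drops records far from the sample median", {
  rec <- empty_cell_records()[rep(1, 0), ]
  base <- data.frame(id = 1:20, replicate = 1, condition = "aerobic",
                     time_h = 6, area_um2 = c(rnorm(19, 40, 2), 400),
                     perimeter_um = 20, dmax_um = 7, dmin_um = 6,
                     circularity = 0.9, elongation = 1.1,
                     budded = FALSE, phase = "unassigned")
  out <- filter_outliers(base, k = 3)
  expect_equal(nrow(out), 19)
  expect_false(400 %in% out$area_um2)
  expect_identical(filter_outliers(rec), rec)
})
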