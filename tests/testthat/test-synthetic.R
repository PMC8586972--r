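test_that("a harmonic-free scene rasterizes to the analytic disk area", {
  sc <- generate_scene(scene_spec(canvas_side = 128, radius = 50,
                                  n_harmonics = 0), seed = 4)
  expect_equal(sc$area_analytic, pi * 50^2)
  expect_lt(abs(sc$area_px - pi * 2500) / (pi * 2500), 0.02)
})

test_that("scene generation is deterministic for equal seeds", {
  spec <- scene_spec()
  expect_identical(generate_scene(spec, seed = 42),
                   generate_scene(spec, seed = 42))
  # and different for different seeds
  expect_false(identical(generate_scene(spec, seed = 42)$image,
                         generate_scene(spec, seed = 43)$image))
})

test_that("the mask is one connected component containing the centre", {
  for (seed in 1:4) {
    sc <- generate_scene(scene_spec(), seed = 200 + seed)
    lab <- EBImage::bwlabel(sc$mask)
    centre_lab <- lab[round(sc$center["y"]), round(sc$center["x"])]
    expect_gt(centre_lab, 0)
    expect_equal(sum(lab == centre_lab), sum(sc$mask))
    expect_equal(max(lab), 1)
  }
})

test_that("rasterized and analytic areas agree within 2% for radius >= 20", {
  for (r in c(20, 30, 45)) {
    sc <- generate_scene(scene_spec(canvas_side = 128, radius = r), seed = r)
    expect_lt(abs(sc$area_px - sc$area_analytic) / sc$area_analytic, 0.02)
  }
})

test_that("the generalized logistic behaves as an asymmetric sigmoid", {
  # symmetric case: area at t0 is half the asymptote
  expect_equal(growth_area(10, 3500, 0.1, 10, 1), 3500 / 2)
  # monotone non-decreasing for positive rate
  t <- seq(0, 63, by = 0.25)
  a <- growth_area(t, 3500, 0.1, 10, 1.5)
  expect_true(all(diff(a) >= 0))
  expect_lt(max(a), 3500)
})

test_that("a 63-day series has 504 frames with parseable timestamps", {
  spec <- growth_spec(canvas_side = 16, a_inf = 20, days = 63,
                      n_distractors = 0, noise_sd = 0, seed = 3)
  series <- generate_growth_series(spec)
  expect_length(series$frames, 8 * 63)
  expect_false(any(is.na(series$times)))
  expect_true(all(diff(as.numeric(series$times)) > 0))
  expect_setequal(unique(format(series$times, "%H:%M")), spec$times)
  # true areas track the sigmoid and never decrease
  expect_true(all(diff(series$truth$area_true) >= 0))
})

test_that("series written to disk round-trip through filename parsing", {
  dir <- withr::local_tempdir()
  spec <- growth_spec(canvas_side = 16, a_inf = 20, days = 2,
                      n_distractors = 0, seed = 9)
  series <- generate_growth_series(spec, out_dir = dir)
  pngs <- sort(list.files(dir, pattern = "^frame_.*png$", full.names = TRUE))
  expect_length(pngs, 16)
  parsed <- parse_frame_times(pngs)
  expect_equal(format(parsed, "%Y%m%d_%H%M"),
               format(series$times, "%Y%m%d_%H%M"))
})

test_that("polygon rasterization matches analytic areas and conventions", {
  # full-canvas rectangle
  expect_equal(sum(rasterize_polygon(rbind(c(0, 0), c(20, 0), c(20, 20),
                                           c(0, 20)), c(20, 20))), 400)
  # right triangle: half the square within one row
  tri <- rbind(c(0, 0), c(20, 0), c(0, 20))
  m <- rasterize_polygon(tri, c(20, 20))
  expect_lt(abs(sum(m) - 200), 20)
  # orientation invariance
  expect_identical(m, rasterize_polygon(tri[3:1, ], c(20, 20)))
  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1)), c(10, 10)),
               "3 vertices")
})

test_that("the oracle segmenter is exact at the generation grid", {
  spec <- growth_spec(canvas_side = 48, a_inf = 300, days = 1, drift_sd = 0,
                      n_distractors = 0, seed = 6)
  series <- generate_growth_series(spec)
  seg <- make_oracle_segmenter(series, input_side = 48)
  tr <- series$truth
  full <- seg(series$frames[[1]],
              list(frame = 1, x0 = 0, y0 = 0, side = 48, out = 48))
  truth_mask <- cropseg:::.star_mask(48, tr$cx[1], tr$cy[1], tr$r[1],
                                     series$params$a, series$params$phi)
  expect_equal(iou(full, truth_mask), 1)
  # a window fully outside the object support yields an empty mask
  empty <- seg(series$frames[[1]],
               list(frame = 1, x0 = 40, y0 = 40, side = 8, out = 16))
  expect_equal(sum(empty), 0)
})
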