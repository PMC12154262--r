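test_that("candidate extraction counts sufficiently large components only", {
  single <- rasterize_ellipse(ellipse_params(40, 40, 15, 10, 20), 96)
  expect_length(extract_candidates(single), 1)
  two <- single | rasterize_ellipse(ellipse_params(75, 75, 8, 6, 0), 96)
  expect_length(extract_candidates(two * 1L), 2)
  ## blob plus a 3-pixel speck: the speck is discarded before counting
  speck <- single
  speck[2, 2:4] <- 1L
  lab <- EBImage::bwlabel(speck > 0)
  areas <- tabulate(lab[lab > 0])
  expect_equal(sort(areas)[1], 3)            # oracle: component areas
  expect_length(extract_candidates(speck, min_area = 10), 1)
  expect_length(extract_candidates(matrix(0L, 32, 32)), 0)
})

test_that("direct least-squares ellipse fitting recovers rasterized parameters", {
  circ <- extract_candidates(rasterize_ellipse(ellipse_params(100, 100, 50, 50), 256))
  f <- fit_ellipse(circ[[1]])
  expect_lt(abs(f$a - 50), 1)
  expect_lt(abs(f$b - 50), 1)
  p <- ellipse_params(100, 100, 40, 25, 30)
  f2 <- fit_ellipse(extract_candidates(rasterize_ellipse(p, 256))[[1]])
  expect_lt(abs(f2$a - 40), 1)
  expect_lt(abs(f2$b - 25), 1)
  expect_lt(min(abs(f2$theta - 30), 180 - abs(f2$theta - 30)), 2)
  expect_lt(sqrt((f2$x0 - 100)^2 + (f2$y0 - 100)^2), 0.5)
})

test_that("contours that cannot define an ellipse raise a fit-failure signal", {
  expect_error(fit_ellipse(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               class = "fit_failed")
  collinear <- cbind(seq(0, 20, length.out = 12), seq(0, 40, length.out = 12))
  expect_error(fit_ellipse(collinear), class = "fit_failed")
})

test_that("diameter conversion follows the spacing x scale-ratio formula", {
  ## circle of diameter 60 working pixels, original 512 resized to 352
  mask <- rasterize_ellipse(ellipse_params(176, 176, 30, 30), 352)
  m <- measure_aod(mask, pixel_spacing = 0.7, scale_ratio = 512 / 352)
  expect_true(m$accepted)
  expect_equal(m$diameter_mm, m$diameter_px * (512 / 352) * 0.7,
               tolerance = 1e-12)
  expect_equal(m$diameter_mm, 60 * (512 / 352) * 0.7, tolerance = 0.01)
  expect_equal(m$diameter_px, 2 * m$ellipse$b, tolerance = 1e-12)
})

test_that("the rejection rule fires on empty, multi-candidate, and anisotropic inputs", {
  empty <- measure_aod(matrix(0L, 96, 96), 0.7)
  expect_false(empty$accepted)
  expect_equal(empty$rejection_reason, "empty_mask")
  expect_true(is.na(empty$diameter_mm))
  two <- (rasterize_ellipse(ellipse_params(30, 30, 12, 9, 0), 96) |
            rasterize_ellipse(ellipse_params(70, 70, 12, 9, 0), 96)) * 1L
  mc <- measure_aod(two, 0.7)
  expect_false(mc$accepted)
  expect_equal(mc$rejection_reason, "multiple_candidates")
  good <- rasterize_ellipse(ellipse_params(48, 48, 15, 11, 10), 96)
  expect_error(measure_aod(good, c(0.6, 0.9)), "anisotropic")
  expect_error(measure_aod(good, -0.7), "positive")
  ## mildly anisotropic spacing uses the mean
  m <- measure_aod(good, c(0.70, 0.72))
  expect_equal(m$diameter_mm, m$diameter_px * 0.71, tolerance = 1e-12)
})

test_that("adding a disjoint blob to any accepted mask flips it to multiple_candidates", {
  set.seed(10)
  for (i in 1:10) {
    p <- ellipse_params(runif(1, 25, 40), runif(1, 25, 40),
                        runif(1, 9, 14), runif(1, 8, 9), runif(1, 0, 180))
    mask <- rasterize_ellipse(p, 96)
    base <- measure_aod(mask, 0.7)
    expect_true(base$accepted)
    blob <- rasterize_ellipse(ellipse_params(78, 78, 7, 5, 0), 96)
    aug <- measure_aod(((mask | blob) * 1L), 0.7)
    expect_false(aug$accepted)
    expect_equal(aug$rejection_reason, "multiple_candidates")
  }
})

test_that("measured ellipse area stays consistent with the mask pixel count", {
  set.seed(20)
  for (i in 1:15) {
    a <- runif(1, 8, 30); b <- runif(1, 8, a)
    mask <- rasterize_ellipse(ellipse_params(60, 60, a, b, runif(1, 0, 180)), 128)
    f <- measure_aod(mask, 0.7)$ellipse   # boundary-compensated fit
    expect_lt(abs(pi * f$a * f$b - sum(mask)) / sum(mask), 0.03)
    expect_gte(f$a, f$b)
  }
})

test_that("batch measurement partitions inputs and reports the retained fraction", {
  good <- rasterize_ellipse(ellipse_params(48, 48, 14, 10, 0), 96)
  bad <- (good | rasterize_ellipse(ellipse_params(80, 80, 8, 6, 0), 96)) * 1L
  masks <- c(replicate(9, good, simplify = FALSE), list(bad))
  bm <- batch_measure(masks, pixel_spacings = 0.7)
  expect_equal(bm$report$n_processed, 10)
  expect_equal(bm$report$n_accepted, 9)
  expect_equal(bm$report$retained_fraction, 0.9)
  expect_length(bm$accepted, 9)
  expect_equal(as.integer(bm$report$by_reason[["multiple_candidates"]]), 1L)
  all_good <- batch_measure(replicate(4, good, simplify = FALSE), 0.7)
  expect_true(all(all_good$report$by_reason == 0))
  tab <- measurement_table(bm$measurements)
  expect_equal(nrow(tab), 10)
  expect_setequal(c("subject_id", "slice_index", "accepted", "rejection_reason",
                    "diameter_px", "diameter_mm", "x0", "y0", "a", "b", "theta"),
                  names(tab))
})

test_that("calibration from truth masks recovers phantom diameters to sub-pixel accuracy", {
  co <- generate_cohort(tiny_phantom_spec(n_subjects = 6, image_size = 128,
                                          distractor_fraction = 0, seed = 33))
  errs <- vapply(co, function(ph) {
    ws <- resize_pair(array(0.5, c(128, 128, 3)), ph$truth_mask, 96)
    m <- measure_aod(ws$mask, ph$slice$pixel_spacing, ws$scale_ratio)
    if (!m$accepted) return(NA_real_)
    abs(m$diameter_mm - ph$truth_aod_mm)
  }, 1)
  pxeq <- vapply(co, function(ph) ph$slice$pixel_spacing[1] * 128 / 96, 1)
  expect_true(all(!is.na(errs)))
  expect_lt(mean(errs), mean(pxeq))
})
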