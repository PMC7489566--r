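# analytic two-peak bone profile: background, two cortical plateaus, dimmer
# trabecular plateau between
make_profile <- function(n = 100, bg = 10, cort = 100, trab = 60,
                         cort_w = 8, trab_w = 24) {
  p <- rep(bg, n)
  c0 <- n / 2
  t1 <- round(c0 - trab_w / 2); t2 <- round(c0 + trab_w / 2)
  p[(t1 - cort_w):(t2 + cort_w)] <- cort
  p[t1:t2] <- trab
  p
}

test_that("constructed two-plateau profile segments to the analytic ratio", {
  p <- make_profile()
  fm <- segment_cortical_trabecular(p)
  expect_lt(abs(fm$trabecular_total_ratio - 24 / 40) / (24 / 40), 0.1)
  expect_lt(abs(fm$width_finger_px - 40), 4)
})

test_that("a symmetric profile centres between its edges", {
  p <- make_profile(n = 101)
  fm <- segment_cortical_trabecular(p)
  expect_lt(abs(fm$centre - mean(fm$edges)), 1.5)
  expect_lt(fm$edges[1], fm$cortical_peaks[1])
  expect_gt(fm$edges[2], fm$cortical_peaks[2])
})

test_that("profiles without a two-peak signature are rejected", {
  expect_error(segment_cortical_trabecular(seq(0, 100, length.out = 50)),
               "cortical peaks not found")
  expect_error(segment_cortical_trabecular(rep(5, 50)), "flat")
})

test_that("the ratio is invariant to affine intensity rescaling", {
  set.seed(3)
  p <- make_profile() + rnorm(100, sd = 1)
  f0 <- segment_cortical_trabecular(p)
  for (i in 1:5) {
    a <- runif(1, 0.2, 5); b <- runif(1, 0, 50)
    f1 <- segment_cortical_trabecular(a * p + b)
    expect_equal(f1$trabecular_total_ratio, f0$trabecular_total_ratio,
                 tolerance = 1e-10)
  }
})

test_that("projection averages rows and preserves column structure", {
  roi <- matrix(3, 40, 40)
  pr <- project_profile(roi)
  expect_equal(pr$intensity, rep(3, 40))

  roi[, 17] <- 50
  pr <- project_profile(roi)
  expect_equal(which.max(pr$intensity), 17)

  # synthetic two-band finger: maxima at the cortical band centres
  roi2 <- matrix(10, 60, 100)
  roi2[, 31:38] <- 100; roi2[, 63:70] <- 100; roi2[, 39:62] <- 60
  pr2 <- project_profile(roi2)
  fm <- segment_cortical_trabecular(pr2)
  expect_true(fm$cortical_peaks[1] %in% 31:38)
  expect_true(fm$cortical_peaks[2] %in% 63:70)
})

test_that("finger ROI local rotation is recovered on tilted phantoms", {
  ph20 <- generate_phantom(phantom_params(finger_angle_deg = 20, seed = 31))
  roi <- extract_finger_roi(ph20$radiograph, ph20$landmarks$finger)
  expect_lt(abs(roi$rotation_deg - 20), 2)

  ph0 <- cached_phantom()
  roi0 <- extract_finger_roi(ph0$radiograph, ph0$landmarks$finger)
  expect_lt(abs(roi0$rotation_deg), 1)
})

test_that("a featureless ROI warns and is used unrotated", {
  r <- radiograph(matrix(7, 400, 400), 0.2)
  expect_warning(roi <- extract_finger_roi(r, c(200, 200)), "unrotated")
  expect_equal(roi$rotation_deg, 0)
})

test_that("an ROI near the border is refused with margins stated", {
  ph <- cached_phantom()
  expect_error(extract_finger_roi(ph$radiograph, c(10, 10)), "bounds")
})

test_that("recovered ratio decreases with cortical thickness", {
  ratios <- vapply(c(4, 8, 12), function(cp) {
    ph <- generate_phantom(phantom_params(cortical_px = cp, seed = 32))
    roi <- extract_finger_roi(ph$radiograph, ph$landmarks$finger)
    fm <- segment_cortical_trabecular(project_profile(roi$roi))
    fm$trabecular_total_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("phantom finger ratio is recovered within 10%", {
  ph <- cached_phantom()
  roi <- extract_finger_roi(ph$radiograph, ph$landmarks$finger)
  fm <- segment_cortical_trabecular(project_profile(roi$roi))
  expect_lt(abs(fm$trabecular_total_ratio - ph$truth$finger_ratio) /
              ph$truth$finger_ratio, 0.1)
})
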