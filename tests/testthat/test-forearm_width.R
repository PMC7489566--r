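# build a bare synthetic forearm image: vertical band of given half-width
# profile on dark background, no bones (boundary logic only)
band_image <- function(nr = 400, nc = 400, half_fun, soft = 90, bg = 30) {
  px <- matrix(bg, nr, nc)
  c0 <- nc / 2
  for (r in 1:nr) {
    h <- half_fun(r)
    px[r, max(1, round(c0 - h)):min(nc, round(c0 + h))] <- soft
  }
  radiograph(px + 0.5, 0.2)
}

test_that("rectangular forearm yields parallel vertical boundaries", {
  r <- band_image(half_fun = function(r) 150)
  b <- trace_forearm_boundaries(r, lunate = c(20, 200))
  expect_true(all(abs((b$right - b$left) - 300) <= 2))
  expect_lt(diff(range(b$left)), 3)
})

test_that("trapezoid narrowing is recovered within tolerance", {
  # half-width shrinks by 0.25 px per row: width slope -0.5 px/row
  r <- band_image(nr = 500, half_fun = function(r) 160 - 0.25 * r)
  b <- trace_forearm_boundaries(r, lunate = c(20, 200))
  w <- b$right - b$left
  fit <- coef(lm(w ~ b$row))
  expect_lt(abs(fit[2] - (-0.5)) / 0.5, 0.1)
  # per-row widths match the analytic profile within 2%
  true_w <- 2 * (160 - 0.25 * b$row)
  keep <- b$row < 470  # smoothing window shortens support at the ends
  expect_lt(max(abs(w[keep] - true_w[keep]) / true_w[keep]), 0.02)
})

test_that("a featureless image has no traceable forearm", {
  r <- radiograph(matrix(10, 300, 300), 0.2)
  expect_error(trace_forearm_boundaries(r, lunate = c(20, 150)),
               "boundary not found")
})

test_that("width lines sit at exact 1 cm spacing in pixels", {
  r <- band_image(nr = 450, half_fun = function(r) 150)
  b <- trace_forearm_boundaries(r, lunate = c(10, 200))
  ws <- measure_widths(b, lunate = c(10, 200), spacing_mm = 0.2)
  expect_length(ws$widths_px, 8)
  expect_equal(unique(diff(ws$line_rows)), 50)  # 10 mm / 0.2 mm per px
  expect_true(all(abs(ws$widths_px - 300) <= 2))
})

test_that("widths on a trapezoid match analytic geometry within 2%", {
  r <- band_image(nr = 500, half_fun = function(r) 170 - 0.2 * r)
  lun <- c(15, 200)
  b <- trace_forearm_boundaries(r, lun)
  ws <- measure_widths(b, lun, spacing_mm = 0.2)
  true_w <- 2 * (170 - 0.2 * ws$line_rows)
  expect_true(all(abs(ws$widths_px - true_w) / true_w < 0.02))
})

test_that("too short a forearm raises an informative error", {
  r <- band_image(nr = 300, half_fun = function(r) 150)
  b <- trace_forearm_boundaries(r, lunate = c(10, 200))
  expect_error(measure_widths(b, lunate = c(10, 200), spacing_mm = 0.2),
               "insufficient forearm extent")
})

test_that("ratio definitions match their arithmetic", {
  expect_equal(unname(compute_ratios(rep(7, 8))), rep(1, 10))

  w <- c(12, 11, 10, 10, 10, 10, 11, 12)
  r <- compute_ratios(w)
  expect_equal(unname(r["W1 / W4"]), 1.2)
  expect_equal(unname(r["Min width / Max width"]), 10 / 12)
  expect_equal(unname(r["W1+W8 / W4+W5"]), 1.2)
  expect_equal(unname(r["W1+W2 / W7+W8"]), 1)
  expect_named(r, measurement_names()[1:10])
})

test_that("ratios agree with a naive re-computation on random widths", {
  set.seed(11)
  for (i in 1:10) {
    w <- runif(8, 50, 400)
    r <- compute_ratios(w)
    naive <- c(w[1]/w[4], w[2]/w[4], w[3]/w[4], w[5]/w[4], w[6]/w[4],
               w[7]/w[4], w[8]/w[4], min(w)/max(w),
               (w[1]+w[8])/(w[4]+w[5]), (w[1]+w[2])/(w[7]+w[8]))
    expect_equal(unname(r), naive)
  }
})

test_that("ratios are invariant to uniform scaling of all widths", {
  set.seed(12)
  for (i in 1:10) {
    w <- runif(8, 50, 400)
    s <- runif(1, 0.1, 10)
    expect_equal(compute_ratios(w), compute_ratios(s * w))
  }
})

test_that("zero or negative widths are rejected", {
  expect_error(compute_ratios(c(0, rep(1, 7))), "positive")
  expect_error(compute_ratios(rep(1, 7)), "8 widths")
})
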