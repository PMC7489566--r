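test_that("central region is the middle third with floor/ceil tiling", {
  r <- radiograph(matrix(1, 900, 600), 0.2)
  ctr <- extract_central_region(r)
  expect_equal(dim(ctr$pixels), c(300, 200))
  expect_equal(ctr$offset, c(300, 200))

  r64 <- radiograph(matrix(1, 64, 64), 0.2)
  expect_equal(dim(extract_central_region(r64)$pixels), c(22, 22))
})

test_that("central region stays inside the parent for arbitrary shapes", {
  set.seed(7)
  for (i in 1:20) {
    nr <- sample(64:500, 1); nc <- sample(64:500, 1)
    r <- radiograph(matrix(1, nr, nc), 0.2)
    ctr <- extract_central_region(r)
    expect_lte(ctr$offset[1] + nrow(ctr$pixels), nr)
    expect_lte(ctr$offset[2] + ncol(ctr$pixels), nc)
    expect_gte(min(dim(ctr$pixels)), 21)
  }
})

test_that("orientation is recovered on tilted and vertical phantoms", {
  ph10 <- generate_phantom(phantom_params(rotation_deg = 10, seed = 21))
  a10 <- detect_orientation(extract_central_region(ph10$radiograph)$pixels)
  expect_lt(abs(as.numeric(a10) - 10), 1)

  ph0 <- cached_phantom()
  a0 <- detect_orientation(extract_central_region(ph0$radiograph)$pixels)
  expect_lt(abs(as.numeric(a0)), 0.5)
})

test_that("flat images fall back to zero rotation with a warning", {
  flat <- matrix(5, 200, 200)
  expect_warning(a <- detect_orientation(flat), "no Hough line")
  expect_equal(as.numeric(a), 0)
})

test_that("rotation by zero is an exact identity", {
  ph <- cached_phantom()
  out <- rotate_to_vertical(ph$radiograph, 0)
  expect_identical(out$pixels, ph$radiograph$pixels)
})

test_that("rotate there-and-back reproduces a smooth image closely", {
  x <- seq(0, 1, length.out = 300)
  smooth <- 100 * outer(sin(pi * x), cos(pi * x / 2)) + 100
  r <- radiograph(smooth, 0.2)
  fwd <- rotate_to_vertical(r, 17)        # rotates content by -17
  back <- rotate_to_vertical(fwd, -17)
  # compare on a central region unaffected by canvas padding
  r_off <- (nrow(back$pixels) - 300) %/% 2
  c_off <- (ncol(back$pixels) - 300) %/% 2
  recovered <- back$pixels[r_off + (1:300), c_off + (1:300)]
  dyn <- diff(range(smooth))
  inner <- 30:270
  expect_lt(mean(abs(recovered[inner, inner] - smooth[inner, inner])) / dyn, 0.02)
})

test_that("orientation correction is idempotent within a degree", {
  ph <- generate_phantom(phantom_params(rotation_deg = 15, seed = 22))
  pre1 <- preprocess_radiograph(ph$radiograph, ph$landmarks)
  pre2 <- preprocess_radiograph(pre1$image)
  expect_lt(abs(pre2$rotation_deg), 1)
})

test_that("collimator mask covers the border frame plus dilation, not interior zeros", {
  px <- matrix(50, 200, 200)
  px[1:10, ] <- 0; px[191:200, ] <- 0; px[, 1:10] <- 0; px[, 191:200] <- 0
  px[100:104, 100:104] <- 0  # interior zero blob, not border-connected
  r <- radiograph(px, 0.2)
  m <- detect_collimator_mask(r, dilation_px = 5)
  expect_true(all(m[1:15, 100]))   # frame + 5 px dilation margin
  expect_false(m[100, 102])        # interior blob excluded
  expect_false(m[100, 100])

  # flood-fill oracle: border-connected zeros found independently via
  # iterative neighbour expansion from the border
  zero <- px == 0
  reach <- matrix(FALSE, 200, 200)
  reach[1, ] <- zero[1, ]; reach[200, ] <- zero[200, ]
  reach[, 1] <- zero[, 1] | reach[, 1]; reach[, 200] <- zero[, 200] | reach[, 200]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-200, ]
    grown[-200, ] <- grown[-200, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -200]
    grown[, -200] <- grown[, -200] | reach[, -1]
    grown <- grown & zero
    if (identical(grown, reach)) break
    reach <- grown
  }
  m0 <- detect_collimator_mask(r, dilation_px = 0)
  expect_identical(unname(m0), unname(reach))
})

test_that("strictly positive images yield an all-false mask", {
  r <- radiograph(matrix(runif(64 * 64) + 0.1, 64, 64), 0.2)
  expect_false(any(detect_collimator_mask(r)))
})

test_that("preprocess recovers rotation and zeroes the collimator frame", {
  ph <- generate_phantom(phantom_params(rotation_deg = 15, seed = 23))
  pre <- preprocess_radiograph(ph$radiograph, ph$landmarks)
  expect_lt(abs(pre$rotation_deg - 15), 1)
  # the detected mask (pre-rotation coordinates) covers the applied frame
  expect_true(all(pre$collimator_mask[ph$truth$collimator_mask]))
  expect_s3_class(pre$landmarks, "landmark_set")

  # collimator never eats the forearm
  expect_false(any(pre$collimator_mask & ph$truth$forearm_mask))
})

test_that("an already-vertical, frameless phantom needs no correction", {
  ph <- generate_phantom(phantom_params(collimator_border_px = 0, seed = 24))
  pre <- preprocess_radiograph(ph$radiograph, ph$landmarks)
  expect_lt(abs(pre$rotation_deg), 0.5)
  expect_false(any(pre$collimator_mask))
})
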