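test_that("radiograph constructor enforces its invariants", {
  expect_s3_class(radiograph(matrix(1, 64, 64), 0.2), "radiograph")
  expect_error(radiograph(matrix(1, 63, 64), 0.2), "64 x 64")
  expect_error(radiograph(matrix(-1, 64, 64), 0.2), ">= 0")
  expect_error(radiograph(matrix(1, 64, 64), 0), "positive")
})

test_that("landmark sets require distinct numeric points", {
  lm <- landmark_set(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(lm$styloid, c(3, 4))
  expect_error(landmark_set(c(1, 2), c(1, 2), c(5, 6)), "distinct")
  expect_error(landmark_set(c(1, NA), c(3, 4), c(5, 6)), "lunate")
})

test_that("DICOM pixel spacing and pixel values pass through bit-exactly", {
  px <- matrix(sample(0:4095, 96 * 80, replace = TRUE), 96, 80)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(f, px, spacing = "0.143\\0.143")
  rad <- read_radiograph(f)
  expect_equal(rad$spacing_mm, 0.143)
  expect_identical(rad$pixels, matrix(as.numeric(px), 96, 80))
})

test_that("MONOCHROME1 DICOM images are re-inverted so bone is bright", {
  px <- matrix(0:4095, 64, 64)[1:64, 1:64]
  px <- matrix(sample(0:1000, 64 * 64, replace = TRUE), 64, 64)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(f, px, photometric = "MONOCHROME1")
  rad <- read_radiograph(f)
  expect_equal(rad$pixels, max(px) - px, ignore_attr = TRUE)
})

test_that("detector spacing is used when calibrated spacing is absent", {
  px <- matrix(10, 64, 64)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(f, px, spacing = "0.2\\0.2", spacing_tag = c(0x0018, 0x1164))
  expect_equal(read_radiograph(f)$spacing_mm, 0.2)
})

test_that("anisotropic spacing beyond 1% is rejected", {
  px <- matrix(10, 64, 64)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(f, px, spacing = "0.10\\0.20")
  expect_error(read_radiograph(f), "anisotropic")
})

test_that("PNG needs a spacing override; override passes through", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(64 * 64), 64, 64), f)
  expect_error(read_radiograph(f), "pixel spacing unavailable")
  rad <- read_radiograph(f, spacing_override = 0.2)
  expect_equal(rad$spacing_mm, 0.2)
  expect_equal(dim(rad$pixels), c(64, 64))
})

test_that("DICOM without spacing demands the override flag", {
  px <- matrix(10, 64, 64)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(f, px, omit_spacing = TRUE)
  expect_error(read_radiograph(f), "spacing_override")
  expect_equal(read_radiograph(f, spacing_override = 0.3)$spacing_mm, 0.3)
})

test_that("landmark files read from CSV and JSON, rejecting duplicates", {
  df <- data.frame(case_id = sprintf("c%d", 1:5),
                   lunate_row = 390, lunate_col = 420,
                   styloid_row = 396, styloid_col = 486,
                   finger_row = 225, finger_col = 430 + 1:5)
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, fcsv, row.names = FALSE)
  lms <- read_landmarks(fcsv)
  expect_length(lms, 5)
  expect_s3_class(lms[["c3"]], "landmark_set")
  expect_equal(lms[["c2"]]$finger, c(225, 432))

  fjson <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(df, fjson, dataframe = "rows")
  expect_equal(read_landmarks(fjson)[["c4"]]$lunate, c(390, 420))

  dup <- rbind(df, df[1, ])
  write.csv(dup, fcsv, row.names = FALSE)
  expect_error(read_landmarks(fcsv), "duplicate")

  write.csv(df[, -2], fcsv, row.names = FALSE)
  expect_error(read_landmarks(fcsv), "missing column")
})

test_that("measurement tables round-trip through CSV", {
  set.seed(42)
  tab <- data.frame(case_id = c("a", "b", "c"),
                    group = c("control", "pre-successful", "post-successful"),
                    stringsAsFactors = FALSE)
  for (m in measurement_names()) tab[[m]] <- rnorm(3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, f)
  back <- read_measurements(f)
  expect_equal(ncol(back), 34)  # case_id + group + 32 measurements
  expect_equal(names(back)[-(1:2)], measurement_names())
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(tab[, -(1:2)]),
               tolerance = 1e-12)

  empty <- tab[0, ]
  write_measurements(empty, f)
  expect_equal(nrow(read.csv(f, check.names = FALSE)), 0)
  expect_equal(ncol(read.csv(f, check.names = FALSE)), 34)

  expect_error(write_measurements(tab[, -5], f), "missing column")
})
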