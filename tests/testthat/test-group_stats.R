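test_that("identical groups give p = 1", {
  expect_equal(two_sample_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(two_sample_test(rep(4, 5), rep(4, 3)), 1)  # zero variance
  expect_equal(two_sample_test(rep(4, 5), rep(5, 3)), 0)
})

test_that("welch p-values match the textbook formula", {
  set.seed(15)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    expect_equal(two_sample_test(a, b), oracle_welch_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("p-values are symmetric under group exchange", {
  set.seed(16)
  for (mode in c("welch", "student")) {
    a <- rnorm(12); b <- rnorm(8, 0.5)
    expect_equal(two_sample_test(a, b, mode), two_sample_test(b, a, mode))
  }
})

test_that("paired mode requires equal lengths and detects paired shifts", {
  expect_error(two_sample_test(1:5, 1:4, "paired"), "equal")
  set.seed(17)
  a <- rnorm(15)
  expect_lt(two_sample_test(a + 2, a + rnorm(15, sd = 0.1), "paired"), 1e-6)
})

test_that("tiny groups are refused", {
  expect_error(two_sample_test(1, c(2, 3)), "at least 2")
})

test_that("compare_groups produces the full 32 x 7 contrast table", {
  tab <- generate_cohort(5, seed = 18)
  cmp <- compare_groups(tab)
  expect_s3_class(cmp, "comparison_table")
  expect_equal(nrow(cmp), 32)
  expect_equal(names(cmp), c("measurement", "landmark",
                             "Control v Patient", "Pre- v Post-",
                             "Successful v Unsuccessful",
                             "Pre-Successful v Pre-Unsuccessful",
                             "Post-Successful v Post-Unsuccessful",
                             "Pre-Successful v Post-Successful",
                             "Pre-Unsuccessful v Post-Unsuccessful"))
  p <- as.matrix(cmp[, -(1:2)])
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
  expect_equal(dim(attr(cmp, "significant")), c(32, 7))
})

test_that("a planted 3-sd control/patient effect is strongly significant", {
  eff <- list("W1 / W4" = c("pre-successful" = 3, "pre-unsuccessful" = 3,
                            "post-successful" = 3, "post-unsuccessful" = 3))
  tab <- generate_cohort(10, effect_spec = eff, seed = 19)
  cmp <- compare_groups(tab)
  expect_lt(cmp[cmp$measurement == "W1 / W4", "Control v Patient"], 0.01)
})

test_that("constant measurements give p = 1 everywhere computable", {
  tab <- generate_cohort(3, seed = 20)
  for (m in measurement_names()) tab[[m]] <- 1
  cmp <- compare_groups(tab)
  p <- as.matrix(cmp[, -(1:2)])
  expect_true(all(p == 1))
})

test_that("unknown group labels are rejected", {
  tab <- generate_cohort(3, seed = 21)
  tab$group[1] <- "mystery"
  expect_error(compare_groups(tab), "unknown group")
})

test_that("non-finite values are dropped pairwise with a note", {
  tab <- generate_cohort(6, seed = 22)
  tab[["LBP 1"]][c(1, 7)] <- NA
  expect_message(cmp <- compare_groups(tab), "dropped 2")
  expect_true(is.finite(cmp[cmp$measurement == "LBP 1", "Control v Patient"]))
})

test_that("contrasts with too few cases flag NA instead of failing", {
  tab <- generate_cohort(3, seed = 23)
  tab <- tab[tab$group != "post-unsuccessful", ]
  cmp <- compare_groups(tab)
  expect_true(is.na(cmp[1, "Post-Successful v Post-Unsuccessful"]))
  expect_false(anyNA(cmp[["Control v Patient"]]))
})

test_that("benjamini-hochberg adjustment is attached on request", {
  tab <- generate_cohort(4, seed = 24)
  cmp <- compare_groups(tab, adjust = TRUE)
  padj <- attr(cmp, "p_adjusted")
  expect_equal(dim(padj), c(32, 7))
  expect_true(all(padj >= as.matrix(cmp[, -(1:2)]) - 1e-12, na.rm = TRUE))
})
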