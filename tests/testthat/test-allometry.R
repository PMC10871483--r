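tbl <- load_table1()

test_that("the packaged table holds 35 specimens with the documented
           missingness pattern", {
  expect_equal(nrow(tbl), 35L)
  fetal <- tbl[tbl$age_label == "13dpc", ]
  expect_equal(nrow(fetal), 4L)
  expect_true(all(is.na(fetal$bw_g)))
  expect_true(all(is.na(fetal$va_mm3)))
  expect_true(all(is.na(fetal$sa_mm2)))
  expect_true(all(!is.na(fetal$vl_mm3)))
  postnatal <- tbl[tbl$age_label != "13dpc", ]
  expect_equal(nrow(postnatal), 31L)
  expect_true(all(!is.na(postnatal$bw_g)))
  expect_equal(sum(tbl$age_label == "neonate"), 3L)
})

test_that("a tampered specimen table is refused", {
  path <- tempfile(fileext = ".csv")
  d <- read.csv(system.file("extdata", "table1_individuals.csv",
                            package = "lungmorph"))
  d$vl_mm3[5] <- d$vl_mm3[5] + 1
  write.csv(d, path, row.names = FALSE)
  expect_error(load_table1(path, verify_checksum = TRUE), "md5")
  expect_silent(load_table1(path, verify_checksum = FALSE))
})

test_that("group summaries reproduce the published per-stage statistics", {
  expect_equal(unname(group_summary(tbl, "VL", "neonate", rounded = TRUE)[1:2]),
               c(2.15, 0.53))
  expect_equal(unname(group_summary(tbl, "VL", "13dpc", rounded = TRUE)[1:2]),
               c(0.53, 0.14))
  expect_equal(unname(group_summary(tbl, "diameter", "7dpn",
                                    rounded = TRUE)[["mean"]]), 192)
  expect_equal(unname(group_summary(tbl, "septum", "21dpn",
                                    rounded = TRUE)[["mean"]]), 18)
  expect_equal(unname(group_summary(tbl, "VL", "adult",
                                    rounded = TRUE)[["mean"]]), 2629.33)
  expect_error(group_summary(tbl, "VA", "13dpc"), "no values")
})

test_that("correlation recovers exact synthetic relationships", {
  syn <- data.frame(age_label = "adult", bw_g = 1:10, vl_mm3 = 3 * (1:10))
  r <- correlation(syn, "VL", "none")
  expect_equal(r$r, 1)
  expect_equal(r$slope, 3)
  expect_equal(r$n, 10L)

  pow <- data.frame(age_label = "adult", bw_g = seq(0.5, 20, length.out = 12))
  pow$sa_mm2 <- 2 * pow$bw_g^0.9
  fit <- loglog_fit(pow, "SA")
  expect_equal(fit$slope, 0.9, tolerance = 1e-10)
  expect_equal(fit$intercept, log10(2), tolerance = 1e-10)
  expect_equal(fit$r, 1)

  expect_error(correlation(head(syn, 2), "VL"), "fewer than 3")
})

test_that("allometric fits on the packaged data are positive and order
           invariant", {
  fit <- loglog_fit(tbl, "VL")
  expect_gt(fit$slope, 0)
  expect_equal(fit$n, 31L)
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(loglog_fit(shuffled, "VL")[c("slope", "intercept", "r")],
               fit[c("slope", "intercept", "r")])
})

test_that("both correlation conventions are computed and neither matches
           the published r values (the documented ambiguity)", {
  val <- validate_against_table1(tbl)
  corr <- val$correlations
  expect_equal(nrow(corr), 3L)
  expect_true(all(is.finite(corr$r_raw)))
  expect_true(all(is.finite(corr$r_log10)))
  expect_true(all(corr$n == 31L))
  # published 0.987 / 0.915 / 0.971 are not reproducible from the table;
  # the report must say so rather than silently switching conventions
  expect_false(any(corr$raw_matches))
  expect_false(any(corr$log10_matches))
})

test_that("fold changes reproduce the published narrative ratios", {
  expect_equal(fold_change(tbl, "bw", "neonate", "adult"), 74.38 / 0.13,
               tolerance = 1e-3)
  # "around 550 times" body weight; "~10-fold" surface area by 14 dpn
  expect_gt(fold_change(tbl, "bw", "neonate", "adult"), 500)
  expect_lt(fold_change(tbl, "bw", "neonate", "adult"), 600)
  expect_equal(fold_change(tbl, "SA", "neonate", "14dpn"), 11.38,
               tolerance = 0.01)
  expect_equal(fold_change(tbl, "VL", "neonate", "neonate"), 1.0)
})

test_that("allometry plots are written and non-empty", {
  path <- tempfile(fileext = ".png")
  plot_allometry(tbl, "VL", path)
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
})
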