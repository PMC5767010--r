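test_that("cohort CSV round trip preserves values and missingness", {
  co <- tiny_cohort(n = 12)
  co$pil6[3] <- NA
  co$death_1y[5] <- NA
  co <- akibma:::as_cohort(as.data.frame(co))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
  expect_true(is.na(back$pil6[3]))
  expect_true(is.na(back$death_1y[5]))
  # writing again yields byte-identical files
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed cohort files are rejected with informative errors", {
  co <- tiny_cohort(n = 5)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- as.data.frame(co)
  bad$subject_id[2] <- bad$subject_id[1]
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), bad$subject_id[1])

  bad <- as.data.frame(co)
  bad$pil6 <- as.character(bad$pil6)
  bad$pil6[4] <- "oops"
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "row 4")

  bad <- as.data.frame(co)
  bad$not_a_marker <- 1
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "not_a_marker")

  bad <- as.data.frame(co)
  bad$phfabp <- NULL
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "phfabp")
})

test_that("complete-case filter counts, preserves order, and is idempotent", {
  co <- tiny_cohort(n = 10)
  full <- complete_case_filter(co)
  expect_equal(attr(full, "counts")$removed, 0)
  expect_equal(attr(full, "counts")$retained, 10)

  co$pil6[2] <- NA
  co$ucr[5] <- NA
  co$cpb_time[9] <- NA
  co <- akibma:::as_cohort(as.data.frame(co))
  filt <- complete_case_filter(co)
  expect_equal(attr(filt, "counts")$removed, 3)
  expect_equal(attr(filt, "counts")$retained, 7)
  expect_equal(filt$subject_id, setdiff(co$subject_id,
                                        co$subject_id[c(2, 5, 9)]))
  again <- complete_case_filter(filt)
  expect_equal(as.data.frame(again), as.data.frame(filt),
               ignore_attr = TRUE)
  expect_identical(again$subject_id, filt$subject_id)

  # filtering on a predictor subset ignores other missingness
  sub <- complete_case_filter(co, c("phfabp", "pntprobnp"))
  expect_equal(attr(sub, "counts")$retained, 10)

  for (v in aki_predictors()$name) co[[v]][1:10] <- NA
  co <- akibma:::as_cohort(as.data.frame(co))
  expect_error(complete_case_filter(co), "every subject")
})

test_that("analysis matrix applies schema transforms and center encoding", {
  co <- tiny_cohort(n = 30, seed = 3)
  co$pil6[1] <- 1.0        # log(1) = 0
  co$delta_cr[2] <- -0.10  # signed variable passes through
  co <- akibma:::as_cohort(as.data.frame(co))
  m <- build_analysis_matrix(co)
  expect_equal(unname(m$x[1, "pil6"]), 0)
  expect_equal(unname(m$x[2, "delta_cr"]), -0.10)
  expect_equal(colnames(m$x), aki_predictors()$name)
  expect_false(anyNA(m$x))

  # six centers -> five indicators against the sorted-first reference
  co6 <- generate_cohort(cohort_config(n = 400, seed = 9,
                                       miss_rate = 0))$cohort
  m6 <- build_analysis_matrix(co6)
  expect_equal(ncol(m6$z), 5)
  expect_equal(m6$reference_center, "1")
  expect_true(all(rowSums(m6$z) <= 1))
  expect_equal(colnames(m6$z), paste0("center", 2:6))

  # deterministic: identical input -> bit-identical matrix
  m6b <- build_analysis_matrix(co6)
  expect_identical(m6$x, m6b$x)
  expect_identical(m6$z, m6b$z)
})

test_that("analysis matrix rejects bad inputs", {
  co <- tiny_cohort(n = 8)
  bad <- as.data.frame(co)
  bad$pil6[3] <- -2
  bad <- akibma:::as_cohort(bad)
  expect_error(build_analysis_matrix(bad), "pil6")
  expect_error(build_analysis_matrix(bad), bad$subject_id[3])
  expect_error(build_analysis_matrix(co, outcome = "no_such"), "no_such")
  co$phfabp[4] <- NA
  co <- akibma:::as_cohort(as.data.frame(co))
  expect_error(build_analysis_matrix(co), "complete_case_filter")
})

test_that("rows missing an outcome are dropped only for that outcome", {
  co <- tiny_cohort(n = 20, seed = 6)
  co$death_1y[1:4] <- NA
  co <- akibma:::as_cohort(as.data.frame(co))
  m_mild <- build_analysis_matrix(co, outcome = "mild_aki")
  m_death <- build_analysis_matrix(co, outcome = "death_1y")
  expect_equal(m_mild$n, 20)
  expect_equal(m_death$n, 16)
})
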