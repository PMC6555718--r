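test_that("write then read is the identity, including missingness", {
  co <- make_cohort(
    make_case("A", gcs = NA_integer_, avpu = "V", shivering = "present"),
    make_case("B", systolic_bp = 0, heart_rate = NA_real_,
              shivering = "absent", confounders = "",
              survived = "unknown", cpc = NA_integer_),
    make_case("C", source = "literature", core_temp_c = 13.7,
              temp_at_device_floor = TRUE, cpc = 2L)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_length(attr(back, "row_errors"), 0)
  for (col in setdiff(names(co), NULL)) {
    expect_equal(back[[col]], co[[col]], info = col)
  }
  # missing gcs stays missing (empty cell), sbp = 0 stays a measured zero
  expect_true(is.na(back$gcs[1]))
  expect_identical(back$systolic_bp[2], 0)
  expect_identical(back$shivering, c("present", "absent", "undocumented"))
})

test_that("empty cohort round-trips as a header-only file", {
  co <- make_cohort(make_case())[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_length(readLines(path), 2)  # schema comment + header
  back <- read_cohort(path)
  expect_equal(nrow(back), 0)
})

test_that("schema and row errors are reported precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- make_cohort(make_case())
  df <- as.data.frame(co)
  df$core_temp_c <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "missing mandatory column.*core_temp_c")

  # row with gcs = 16 rejected with a range violation; valid rows kept
  co2 <- make_cohort(make_case("OK"), make_case("BAD"), make_case("OK2"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co2, path2)
  lines <- readLines(path2)  # line 1 schema comment, line 2 header
  lines[4] <- sub("BAD,50,male,hospital,15", "BAD,50,male,hospital,16", lines[4])
  writeLines(lines, path2)
  back <- read_cohort(path2)
  expect_equal(nrow(back), 2)
  expect_match(attr(back, "row_errors"), "row 2: gcs out of range")

  # unparseable temperature: row skipped and logged
  lines[5] <- sub("OK2,(.*),33,FALSE", "OK2,\\1,warm,FALSE", lines[5])
  writeLines(lines, path2)
  back2 <- read_cohort(path2)
  expect_equal(nrow(back2), 1)
  expect_true(any(grepl("unparseable", attr(back2, "row_errors"))))
})

test_that("physically implausible temperatures are data errors", {
  co <- make_cohort(make_case("X", core_temp_c = 9.9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 0)
  expect_match(attr(back, "row_errors"), "plausibility")
})

test_that("eligibility applies the first-failing criterion in funnel order", {
  co <- make_cohort(
    make_case("ok"),
    make_case("minor", age = 17L),
    # a minor who is also warm still counts under "age" (first criterion)
    make_case("minor_warm", age = 16L, core_temp_c = 36.0),
    make_case("warm", core_temp_c = 35.0),
    make_case("hypo", confounders = "hypoglycemia_lt_3mmol"),
    make_case("alc", confounders = "alcohol_over_150mg_dl"),
    make_case("nostage", gcs = NA_integer_, avpu = NA_character_)
  )
  res <- apply_eligibility(co)
  expect_equal(res$cohort$case_id, "ok")
  expect_equal(unname(res$report),
               c(1L, 2L, 1L, 2L, 1L))
  expect_equal(res$excluded$reason[res$excluded$case_id == "minor"], "age")
  expect_equal(res$excluded$reason[res$excluded$case_id == "minor_warm"], "age")
  expect_equal(res$excluded$reason[res$excluded$case_id == "warm"], "temperature")
  expect_equal(res$excluded$reason[res$excluded$case_id == "hypo"], "confounder")
  expect_equal(res$excluded$reason[res$excluded$case_id == "nostage"], "unstageable")
})

test_that("eligibility is idempotent, conserves cases, ignores outcomes", {
  set.seed(11)
  co <- generate_cohort(default_config(n_total = 60, seed = 11))
  co$age[1:5] <- 15L
  co$confounders[6:8] <- "traumatic_brain_injury"
  res <- apply_eligibility(co)
  expect_equal(nrow(res$cohort) + nrow(res$excluded), nrow(co))
  res2 <- apply_eligibility(res$cohort)
  expect_equal(nrow(res2$cohort), nrow(res$cohort))
  expect_equal(nrow(res2$excluded), 0)

  # flipping the outcome fields never changes eligibility
  co2 <- co
  co2$survived <- "no"
  co2$cpc <- NA_integer_
  expect_equal(apply_eligibility(co2)$report, res$report)
})
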