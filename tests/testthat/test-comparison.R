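test_that("chi-square matches the closed 2x2 form and hand arithmetic", {
  res <- chi_square_test(matrix(c(90, 95, 32, 88), 2))
  manual <- 305 * (90 * 88 - 32 * 95)^2 / (122 * 183 * 185 * 120)
  expect_equal(res$statistic, manual)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)

  # identical row distributions: statistic 0, p 1
  flat <- chi_square_test(matrix(c(10, 20, 5, 10, 15, 30), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # 2x3 against a direct sum((O-E)^2/E)
  tab <- matrix(c(8, 2, 5, 9, 3, 7), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_test(tab)$statistic, sum((tab - e)^2 / e))

  expect_error(chi_square_test(matrix(c(0, 0, 5, 3), 2)), "zero row or column")
})

test_that("fisher exact equals hypergeometric enumeration, exhaustively to n = 10", {
  expect_equal(fisher_exact_test(matrix(c(0, 5, 5, 0), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_test(matrix(0L, 2, 2)), 1)

  for (n in 0:10) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      got <- fisher_exact_test(matrix(c(a, c, b, d), 2))
      expect_equal(got, fisher_oracle(a, b, c, d), tolerance = 1e-9,
                   info = sprintf("table %d %d / %d %d", a, b, c, d))
    }
  }
})

test_that("student t matches hand calculation and handles degenerate input", {
  res <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)

  same <- student_t_test(c(5, 7, 9), c(9, 5, 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  const_eq <- student_t_test(c(2, 2), c(2, 2))
  expect_true(const_eq$degenerate)
  expect_equal(const_eq$p_value, 1)
  const_ne <- student_t_test(c(2, 2), c(3, 3))
  expect_true(const_ne$degenerate)
  expect_equal(const_ne$p_value, 0)
})

test_that("wilcoxon exact p matches enumeration, with and without ties", {
  res <- wilcoxon_rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$method, "exact")

  same <- wilcoxon_rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # no ties: must agree with R's exact distribution for every assignment
  for (n1 in 2:4) {
    for (n2 in n1:(10 - n1)) {
      idx <- utils::combn(n1 + n2, n1)
      for (j in seq_len(ncol(idx))) {
        vals <- seq_len(n1 + n2)
        x <- vals[idx[, j]]
        y <- vals[-idx[, j]]
        got <- wilcoxon_rank_sum_test(x, y)
        ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
        expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
        expect_equal(got$statistic, unname(ref$statistic))
      }
    }
  }

  # ties: exhaustive over small value alphabets against the enumeration oracle
  set.seed(2)
  for (shape in list(c(2, 2), c(2, 3), c(3, 3))) {
    vals <- expand.grid(rep(list(1:3), sum(shape)))
    for (j in seq_len(nrow(vals))) {
      v <- as.numeric(vals[j, ])
      x <- v[seq_len(shape[1])]
      y <- v[-seq_len(shape[1])]
      expect_equal(wilcoxon_rank_sum_test(x, y)$p_value, ranksum_oracle(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("each test keeps its nominal type-I error under the null", {
  set.seed(20260923)
  nrep <- 10000
  alpha <- 0.05

  p_t <- replicate(nrep, student_t_test(rnorm(25), rnorm(25))$p_value)
  expect_gt(mean(p_t < alpha), 0.03)
  expect_lt(mean(p_t < alpha), 0.07)

  p_w <- replicate(nrep, wilcoxon_rank_sum_test(rnorm(20), rnorm(20))$p_value)
  expect_gt(mean(p_w < alpha), 0.03)
  expect_lt(mean(p_w < alpha), 0.07)

  p_c <- replicate(nrep, {
    tab <- rbind(table(factor(rbinom(100, 1, 0.5), 0:1)),
                 table(factor(rbinom(100, 1, 0.5), 0:1)))
    if (any(colSums(tab) == 0)) 1 else chi_square_test(tab)$p_value
  })
  expect_gt(mean(p_c < alpha), 0.03)
  expect_lt(mean(p_c < alpha), 0.07)

  p_f <- replicate(nrep, {
    a <- rbinom(1, 50, 0.5)
    c_ <- rbinom(1, 50, 0.5)
    fisher_exact_test(matrix(c(a, c_, 50 - a, 50 - c_), 2))
  })
  expect_gt(mean(p_f < alpha), 0.03)
  expect_lt(mean(p_f < alpha), 0.07)
})

test_that("table2 report covers the expected variables and is deterministic", {
  co <- stage_cohort(generate_cohort(default_config(n_total = 120, seed = 4)))
  rep1 <- build_table2_report(co)
  rep2 <- build_table2_report(co)
  expect_identical(rep1, rep2)
  expect_setequal(
    unique(rep1$variable),
    c("age", "sex", "core_temp_c", "gcs", "heart_rate", "systolic_bp",
      "respiration_rate", "clinical_stage", "cause", "survived", "cpc")
  )
  expect_true(all(rep1$p_value >= 0 & rep1$p_value <= 1, na.rm = TRUE))
  # heart rate appears with both summaries and a single flagged p
  hr <- rep1[rep1$variable == "heart_rate", ]
  expect_equal(nrow(hr), 2)
  expect_equal(length(unique(hr$p_value)), 1)
})

test_that("mirrored groups give p = 1 everywhere computable", {
  half <- generate_cohort(default_config(n_total = 40, seed = 9))
  half$source <- "hospital"
  twin <- half
  twin$source <- "literature"
  twin$case_id <- paste0(twin$case_id, "_L")
  co <- rbind(half, twin)
  class(co) <- class(half)
  rep <- build_table2_report(stage_cohort(co))
  computable <- !is.na(rep$p_value)
  expect_true(any(computable))
  expect_true(all(rep$p_value[computable] == 1))
})

test_that("stage mixes as different as the defaults are detected", {
  set.seed(60)
  hits <- replicate(20, {
    co <- stage_cohort(generate_cohort(default_config(n_total = 305,
                                                      seed = sample(1e6, 1))))
    rep <- build_table2_report(co)
    rep$p_value[rep$variable == "clinical_stage"] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a two-case cohort yields flagged rows, not a crash", {
  co <- make_cohort(
    make_case("h", source = "hospital"),
    make_case("l", source = "literature")
  )
  rep <- build_table2_report(stage_cohort(co))
  expect_true(any(rep$test == "not_computable"))
  expect_s3_class(rep, "tbl_df")
})
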