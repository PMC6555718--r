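test_that("fixture counts reproduce the published concordance figures", {
  cs <- concordance_summary(table3_counts("overall"))
  expect_equal(cs$n_total, 305L)
  expect_equal(cs$n_correct, 185L)
  expect_equal(cs$n_overestimated, 55L)
  expect_equal(cs$n_underestimated, 65L)
  expect_equal(round(cs$proportion_correct, 3), 0.607)

  hosp <- concordance_summary(table3_counts("hospital"))
  expect_equal(c(hosp$n_correct, hosp$n_total), c(90L, 122L))
  lit <- concordance_summary(table3_counts("literature"))
  expect_equal(c(lit$n_correct, lit$n_total), c(95L, 183L))

  # strata sum elementwise to the overall table
  expect_equal(
    unclass(table3_counts("hospital")) + unclass(table3_counts("literature")),
    unclass(table3_counts("overall")),
    ignore_attr = TRUE
  )
})

test_that("Wald CI matches the closed form and Wilson rounds the same", {
  # 50 of 100 by hand: 0.5 +/- 1.96 * 0.05
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 50L
  m[1, 2] <- 50L
  cs <- concordance_summary(as_correspondence_table(m), "wald")
  z <- qnorm(0.975)
  expect_equal(cs$ci_lower, 0.5 - z * 0.05)
  expect_equal(cs$ci_upper, 0.5 + z * 0.05)

  wald <- concordance_summary(table3_counts("overall"), "wald")
  wilson <- concordance_summary(table3_counts("overall"), "wilson")
  expect_equal(round(100 * c(wald$ci_lower, wald$ci_upper)), c(55, 66))
  expect_equal(round(100 * c(wilson$ci_lower, wilson$ci_upper)), c(55, 66))
})

test_that("direction convention: over/underestimation per the binning", {
  expect_equal(classify_concordance(1, 33.4), "correct")
  expect_equal(classify_concordance(1, 28.5), "overestimated")
  expect_equal(classify_concordance(4, 31.8), "underestimated")
  # stage 1 can never be underestimated, stage 4 never overestimated
  temps <- seq(10.05, 34.95, by = 0.1)
  expect_false(any(classify_concordance(rep(1, length(temps)), temps) ==
                     "underestimated"))
  expect_false(any(classify_concordance(rep(4, length(temps)), temps) ==
                     "overestimated"))
})

test_that("correct classification means the temperature is in the stage range", {
  grid <- seq(10, 34.9, by = 0.01)
  ranges <- theoretical_range(1:4)
  for (s in 1:4) {
    verdict <- classify_concordance(rep(s, length(grid)), grid)
    lo <- ranges$lower[s]
    inside <- (if (is.finite(lo)) grid >= lo else TRUE) & grid < ranges$upper[s]
    expect_equal(verdict == "correct", inside)
  }
})

test_that("table aggregation equals case-by-case classification", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    co <- generate_cohort(default_config(n_total = n, seed = sample(1e6, 1)))
    staged <- stage_cohort(co)
    tab <- correspondence_table(staged)
    cs <- concordance_summary(tab)
    verdicts <- classify_concordance(staged$clinical_stage, staged$core_temp_c)
    expect_equal(cs$n_correct, sum(verdicts == "correct"))
    expect_equal(cs$n_overestimated, sum(verdicts == "overestimated"))
    expect_equal(cs$n_underestimated, sum(verdicts == "underestimated"))
    expect_equal(cs$n_total, cs$n_correct + cs$n_overestimated + cs$n_underestimated)
  }
})

test_that("conservation holds on random count tables", {
  set.seed(7)
  for (rep in 1:20) {
    m <- matrix(rpois(16, 5), 4, 4)
    cs <- concordance_summary(as_correspondence_table(m))
    expect_equal(cs$n_correct + cs$n_overestimated + cs$n_underestimated,
                 sum(m))
  }
  expect_error(concordance_summary(as_correspondence_table(matrix(0L, 4, 4))),
               "undefined")
})

test_that("empty and diagonal cohorts give the degenerate tables", {
  staged <- toy_staged_cohort()
  empty <- staged[0, ]
  expect_equal(sum(correspondence_table(empty)), 0)
  # the toy cohort is built with one case per diagonal cell and stratum
  tab <- correspondence_table(staged, "hospital")
  expect_equal(unclass(tab), diag(1L, 4),
               ignore_attr = TRUE)
  all_diag <- concordance_summary(tab)
  expect_equal(all_diag$proportion_correct, 1)
  expect_equal(all_diag$n_overestimated + all_diag$n_underestimated, 0L)
})

test_that("stage_summary matches hand-computed interval examples", {
  s <- stage_summary(c(20, 22, 24, 26, 28), 2)
  expect_equal(s$mean_temp, 24)
  expect_equal(c(s$pi_lower, s$pi_upper), c(20.4, 27.6))

  s2 <- stage_summary(c(10, 12, 14, 16), 4)
  expect_equal(s2$mean_temp, 13)
  expect_equal(s2$sd_temp, sqrt(20 / 3))
  tmult <- qt(0.975, 3)
  expect_equal(s2$ci_lower, 13 - tmult * sqrt(20 / 3) / 2)
  expect_equal(round(c(s2$ci_lower, s2$ci_upper), 2), c(8.89, 17.11))

  s3 <- stage_summary(rep(30, 6), 2)
  expect_equal(s3$sd_temp, 0)
  expect_equal(c(s3$pi_lower, s3$pi_upper), c(30, 30))

  s4 <- stage_summary(25.5, 3)
  expect_true(is.na(s4$sd_temp) && is.na(s4$ci_lower))
  expect_error(stage_summary(numeric(0), 1), "empty")
})

test_that("summary invariants hold on random samples", {
  set.seed(3)
  for (rep in 1:20) {
    temps <- round(runif(sample(2:60, 1), 15, 34.5), 1)
    s <- stage_summary(temps, 1)
    expect_true(s$min <= s$pi_lower)
    expect_true(s$pi_lower <= s$pi_upper)
    expect_true(s$pi_upper <= s$max)
    expect_true(s$ci_lower <= s$mean_temp && s$mean_temp <= s$ci_upper)
  }
})

test_that("90% prediction interval covers about 90% of fresh draws", {
  set.seed(99)
  p <- moment_matched_truncnorm(26.0, 3.4, 19.3, 33.5)
  train <- hypostage:::truncnorm_inv(runif(5000), p)
  s <- stage_summary(train, 3)
  fresh <- hypostage:::truncnorm_inv(runif(20000), p)
  coverage <- mean(fresh >= s$pi_lower & fresh <= s$pi_upper)
  expect_gt(coverage, 0.88)
  expect_lt(coverage, 0.92)
})

test_that("shivering summary tallies the tri-state and summarises present cases", {
  co <- make_cohort(
    make_case("a", shivering = "present", core_temp_c = 29),
    make_case("b", shivering = "present", core_temp_c = 30.5),
    make_case("c", shivering = "present", core_temp_c = 32.2),
    make_case("d", shivering = "absent"),
    make_case("e", shivering = "undocumented")
  )
  s <- shivering_summary(co)
  expect_equal(sum(s$counts), nrow(co))
  expect_equal(unname(s$counts), c(3L, 1L, 1L))
  expect_equal(s$temperature$median, 30.5)
  expect_equal(c(s$temperature$min, s$temperature$max), c(29, 32.2))

  none <- shivering_summary(make_cohort(make_case("x")))
  expect_null(none$temperature)
  expect_equal(unname(none$counts), c(0L, 0L, 1L))
})
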