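#' Pearson chi-square test of independence
#'
#' Pearson's chi-square without continuity correction: statistic
#' sum((O - E)^2 / E), df = (r-1)(c-1), upper-tail p-value.
#'
#' @param table An r x c matrix of non-negative counts.
#' @return A list with `statistic`, `df`, `p_value` and `expected`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: expected counts undefined; ",
         "use fisher_exact_test()", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by the probability-mass method: the sum of
#' hypergeometric probabilities, margins fixed, of all tables at most as
#' probable as the one observed.
#'
#' @param table A 2 x 2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("`table` must be 2 x 2", call. = FALSE)
  if (sum(table) == 0) return(1)
  stats::fisher.test(table)$p.value
}

#' Two-sample Student t-test
#'
#' Pooled-variance Student t by default; Welch available. Two-sided. The
#' degenerate case where both groups have zero variance is handled without
#' error: p = 1 for equal means, p = 0 (flagged) for unequal means.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with `statistic`, `df`, `p_value` and logical `degenerate`.
#' @export
student_t_test <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    }
    return(list(statistic = Inf * sign(mean(x) - mean(y)), df = NA_real_,
                p_value = 0, degenerate = TRUE))
  }
  res <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, degenerate = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Reports the Mann-Whitney statistic for the first group (rank sum minus its
#' minimum), with midranks for ties. The p-value is exact — by complete
#' enumeration of all assignments of the pooled values to the two groups,
#' ties included — whenever the smaller group has at most 8 values and the
#' enumeration is tractable; otherwise the tie-corrected normal approximation
#' (without continuity correction) is used. The two-sided exact p is twice
#' the smaller tail, capped at 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A list with `statistic`, `p_value` and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
wilcoxon_rank_sum_test <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  k <- min(n1, n2)
  n <- n1 + n2
  exact_ok <- k <= 8 && choose(n, k) <= 2e5
  if (exact_ok) {
    # Null distribution of the rank-sum of the first group over all
    # assignments; midranks make this valid under ties as well.
    sets <- utils::combn(n, n1)
    stats_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(stats_all <= w + 1e-9)
    p_hi <- mean(stats_all >= w - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = w, p_value = p, method = "exact")
  } else {
    res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    list(statistic = w, p_value = res$p.value, method = "normal_approx")
  }
}

fmt_mean_sd <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2) return(NA_character_)
  sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
}

fmt_median_iqr <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_character_)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
  sprintf("%g (%g-%g)", q[2], q[1], q[3])
}

fmt_counts <- function(v, levels) {
  tab <- table(factor(v, levels = levels))
  paste(sprintf("%s %d (%.0f%%)", names(tab), as.integer(tab),
                100 * as.integer(tab) / max(1, sum(tab))), collapse = "; ")
}

## Chi-square when all expected counts >= 5, Fisher otherwise.
categorical_test <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2)) {
    return(list(test = "not_computable", statistic = NA_real_, p_value = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab, workspace = 2e6)$p.value
    list(test = "fisher_exact", statistic = NA_real_, p_value = p)
  } else {
    res <- chi_square_test(tab)
    list(test = "chi_square", statistic = res$statistic, p_value = res$p_value)
  }
}

continuous_test <- function(x, y, kind) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (kind == "student_t") {
    if (length(x) < 2 || length(y) < 2) {
      return(list(test = "not_computable", statistic = NA_real_, p_value = NA_real_))
    }
    res <- student_t_test(x, y)
    list(test = if (res$degenerate) "student_t (degenerate)" else "student_t",
         statistic = res$statistic, p_value = res$p_value)
  } else {
    if (length(x) == 0 || length(y) == 0) {
      return(list(test = "not_computable", statistic = NA_real_, p_value = NA_real_))
    }
    if (length(unique(c(x, y))) == 1) {
      return(list(test = "wilcoxon_rank_sum (degenerate)", statistic = NA_real_,
                  p_value = 1))
    }
    res <- wilcoxon_rank_sum_test(x, y)
    list(test = "wilcoxon_rank_sum", statistic = res$statistic,
         p_value = res$p_value)
  }
}

#' Hospital-versus-literature baseline comparison report
#'
#' Compares baseline characteristics between the hospital-sampled and
#' literature-sampled cases: age, core temperature and systolic blood
#' pressure by Student's t-test; GCS, heart rate and respiration rate by the
#' Wilcoxon rank-sum test (heart rate is summarised both as mean +/- SD and
#' median (IQR), with a single rank-sum p, flagged as ambiguous); sex,
#' clinical stage, cause, survival and neurological outcome (CPC collapsed to
#' 1 / 2-3 / unknown among survivors) by chi-square, switching to Fisher's
#' exact test when any expected count is below 5. All p-values are two-sided.
#'
#' @param cohort A cohort containing both sources; staged (if the
#'   `clinical_stage` column is absent it is added via [stage_cohort()] with
#'   `on_error = "skip"`).
#' @return A tibble of class `table2_report`: one row per variable summary
#'   with columns `variable`, `summary_type`, `hospital`, `literature`,
#'   `test`, `statistic`, `p_value`, `note`.
#' @export
build_table2_report <- function(cohort) {
  if (!all(c("hospital", "literature") %in% cohort$source)) {
    stop("cohort must contain both hospital and literature cases", call. = FALSE)
  }
  if (!"clinical_stage" %in% names(cohort)) {
    cohort <- stage_cohort(cohort, on_error = "skip")
  }
  h <- cohort[cohort$source == "hospital", ]
  l <- cohort[cohort$source == "literature", ]

  rows <- list()
  add <- function(variable, summary_type, hv, lv, tst, note = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = variable, summary_type = summary_type,
      hospital = hv, literature = lv,
      test = tst$test, statistic = tst$statistic, p_value = tst$p_value,
      note = note
    )
  }

  add("age", "mean_sd", fmt_mean_sd(h$age), fmt_mean_sd(l$age),
      continuous_test(h$age, l$age, "student_t"))

  sex_tab <- rbind(table(factor(h$sex, c("male", "female"))),
                   table(factor(l$sex, c("male", "female"))))
  add("sex", "counts",
      sprintf("male %d (%.0f%%)", sum(h$sex == "male"), 100 * mean(h$sex == "male")),
      sprintf("male %d (%.0f%%)", sum(l$sex == "male"), 100 * mean(l$sex == "male")),
      categorical_test(sex_tab))

  add("core_temp_c", "mean_sd", fmt_mean_sd(h$core_temp_c),
      fmt_mean_sd(l$core_temp_c),
      continuous_test(h$core_temp_c, l$core_temp_c, "student_t"))

  add("gcs", "median_iqr", fmt_median_iqr(h$gcs), fmt_median_iqr(l$gcs),
      continuous_test(h$gcs, l$gcs, "wilcoxon"))

  hr_test <- continuous_test(h$heart_rate, l$heart_rate, "wilcoxon")
  add("heart_rate", "mean_sd", fmt_mean_sd(h$heart_rate),
      fmt_mean_sd(l$heart_rate), hr_test,
      "single rank-sum p reported against both summaries")
  add("heart_rate", "median_iqr", fmt_median_iqr(h$heart_rate),
      fmt_median_iqr(l$heart_rate), hr_test,
      "single rank-sum p reported against both summaries")

  add("systolic_bp", "mean_sd", fmt_mean_sd(h$systolic_bp),
      fmt_mean_sd(l$systolic_bp),
      continuous_test(h$systolic_bp, l$systolic_bp, "student_t"))

  add("respiration_rate", "median_iqr", fmt_median_iqr(h$respiration_rate),
      fmt_median_iqr(l$respiration_rate),
      continuous_test(h$respiration_rate, l$respiration_rate, "wilcoxon"))

  stage_tab <- rbind(table(factor(h$clinical_stage, 1:4)),
                     table(factor(l$clinical_stage, 1:4)))
  add("clinical_stage", "counts", fmt_counts(h$clinical_stage, 1:4),
      fmt_counts(l$clinical_stage, 1:4), categorical_test(stage_tab))

  cause_levels <- c("water", "avalanche", "environmental_other_unknown")
  cause_tab <- rbind(table(factor(h$cause, cause_levels)),
                     table(factor(l$cause, cause_levels)))
  add("cause", "counts", fmt_counts(h$cause, cause_levels),
      fmt_counts(l$cause, cause_levels), categorical_test(cause_tab))

  surv_tab <- rbind(table(factor(h$survived[h$survived != "unknown"], c("yes", "no"))),
                    table(factor(l$survived[l$survived != "unknown"], c("yes", "no"))))
  add("survived", "counts",
      fmt_counts(h$survived[h$survived != "unknown"], c("yes", "no")),
      fmt_counts(l$survived[l$survived != "unknown"], c("yes", "no")),
      categorical_test(surv_tab), "unknown survival excluded from the test")

  cpc_group <- function(d) {
    s <- d[d$survived %in% c("yes", "unknown"), ]
    ifelse(is.na(s$cpc), "unknown", ifelse(s$cpc == 1, "CPC 1", "CPC 2-3"))
  }
  hc <- cpc_group(h)
  lc <- cpc_group(l)
  cpc_levels <- c("CPC 1", "CPC 2-3", "unknown")
  cpc_tab <- rbind(table(factor(hc, cpc_levels)), table(factor(lc, cpc_levels)))
  add("cpc", "counts", fmt_counts(hc, cpc_levels), fmt_counts(lc, cpc_levels),
      categorical_test(cpc_tab), "survivors only; categories collapsed to 1 / 2-3 / unknown")

  out <- do.call(rbind, rows)
  class(out) <- c("table2_report", class(out))
  out
}
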