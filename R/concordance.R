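#' Classify stage-vs-temperature concordance for one case
#'
#' A case is correctly classified when its measured temperature falls in the
#' range its clinical stage predicts. "Overestimated" means the clinical stage
#' predicts a warmer range than measured (the temperature bin is deeper than
#' the stage); "underestimated" means the measured temperature is warmer than
#' predicted.
#'
#' @param stage Integer vector of clinical stages (1-4).
#' @param core_temp_c Numeric vector of measured core temperatures, below 35.
#' @return Character vector with values `"correct"`, `"overestimated"` or
#'   `"underestimated"`.
#' @examples
#' classify_concordance(1, 33.4)   # correct
#' classify_concordance(1, 28.5)   # overestimated: colder than stage 1 predicts
#' classify_concordance(4, 31.8)   # underestimated
#' @export
classify_concordance <- function(stage, core_temp_c) {
  if (!all(stage %in% 1:4)) stop("`stage` must be in 1:4", call. = FALSE)
  bin <- bin_temperature(core_temp_c)
  ifelse(bin == stage, "correct",
         ifelse(bin > stage, "overestimated", "underestimated"))
}

#' Cross-tabulate clinical stage against temperature bin
#'
#' Builds the 4 x 4 correspondence matrix (rows: clinical stage 1-4; columns:
#' temperature bin 1-4) for a staged cohort, optionally restricted to one
#' sampling source.
#'
#' @param cohort A staged cohort (see [stage_cohort()]), with columns
#'   `clinical_stage` and `temp_bin`.
#' @param stratum `"overall"` (default), `"hospital"` or `"literature"`.
#' @return An integer matrix of class `correspondence_table` with `stratum`
#'   attribute and dimnames `stage1..4` x `bin1..4`.
#' @export
correspondence_table <- function(cohort, stratum = c("overall", "hospital", "literature")) {
  stratum <- match.arg(stratum)
  if (!all(c("clinical_stage", "temp_bin") %in% names(cohort))) {
    stop("cohort is not staged; run stage_cohort() first", call. = FALSE)
  }
  if (stratum != "overall") cohort <- cohort[cohort$source == stratum, , drop = FALSE]
  counts <- table(factor(cohort$clinical_stage, levels = 1:4),
                  factor(cohort$temp_bin, levels = 1:4))
  as_correspondence_table(matrix(as.integer(counts), 4, 4), stratum)
}

#' Build a correspondence table from a count matrix
#'
#' @param counts A 4 x 4 matrix of non-negative integer counts (rows: clinical
#'   stage; columns: temperature bin).
#' @param stratum Label: `"overall"`, `"hospital"` or `"literature"`.
#' @return An object of class `correspondence_table`.
#' @export
as_correspondence_table <- function(counts, stratum = "overall") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 4))) stop("`counts` must be 4 x 4", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("stage", 1:4), paste0("bin", 1:4))
  structure(counts, stratum = stratum, class = c("correspondence_table", "matrix", "array"))
}

#' @export
print.correspondence_table <- function(x, ...) {
  cat(sprintf("Stage x temperature-bin correspondence (%s, n = %d)\n",
              attr(x, "stratum"), sum(x)))
  m <- unclass(x)
  attr(m, "stratum") <- NULL
  m <- cbind(m, total = rowSums(m))
  m <- rbind(m, total = colSums(m))
  print(m)
  invisible(x)
}

#' Summarise classification concordance
#'
#' From a correspondence table, counts correctly classified cases (diagonal),
#' cases whose temperature the stage overestimates (above the diagonal:
#' measured temperature colder than predicted) and underestimates (below the
#' diagonal), with a binomial confidence interval for the proportion correct.
#'
#' @param table A `correspondence_table`.
#' @param ci_method `"wald"` (normal approximation, the default) or
#'   `"wilson"` (score interval, via [stats::prop.test()] without continuity
#'   correction).
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `concordance_summary`: `n_total`, `n_correct`,
#'   `n_overestimated`, `n_underestimated`, `proportion_correct`, `ci_lower`,
#'   `ci_upper`, `ci_method`, `conf_level`, `stratum`.
#' @export
concordance_summary <- function(table, ci_method = c("wald", "wilson"),
                                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(table, "correspondence_table"))
  n <- sum(table)
  if (n == 0) stop("empty table: proportion correct is undefined", call. = FALSE)
  m <- unclass(table)
  k <- sum(diag(m))
  over <- sum(m[upper.tri(m)])
  under <- sum(m[lower.tri(m)])
  p <- k / n
  ci <- binom_ci(k, n, ci_method, conf_level)
  structure(
    list(
      n_total = n, n_correct = k, n_overestimated = over,
      n_underestimated = under, proportion_correct = p,
      ci_lower = ci[1], ci_upper = ci[2], ci_method = ci_method,
      conf_level = conf_level, stratum = attr(table, "stratum")
    ),
    class = "concordance_summary"
  )
}

binom_ci <- function(k, n, method, conf_level) {
  if (method == "wald") {
    p <- k / n
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  } else {
    as.numeric(stats::prop.test(k, n, conf.level = conf_level,
                                correct = FALSE)$conf.int)
  }
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "Concordance (%s): %d/%d correct (%.0f%%, %.0f%% CI %.0f-%.0f%%); temperature overestimated %d (%.0f%%), underestimated %d (%.0f%%)\n",
    x$stratum, x$n_correct, x$n_total, 100 * x$proportion_correct,
    100 * x$conf_level, 100 * x$ci_lower, 100 * x$ci_upper,
    x$n_overestimated, 100 * x$n_overestimated / x$n_total,
    x$n_underestimated, 100 * x$n_underestimated / x$n_total
  ))
  invisible(x)
}

#' Per-stage temperature summary with confidence and prediction intervals
#'
#' Computes n, mean, sample SD, range, the 95% confidence interval for the
#' mean (Student-t multiplier with n-1 degrees of freedom), and the 90%
#' prediction interval as the empirical 5% and 95% quantiles, computed by
#' linear interpolation between order statistics (plotting position
#' (k-1)/(n-1), i.e. [stats::quantile()] type 7), so that 5% of individuals
#' are expected below and 5% above the interval.
#'
#' @param temps Numeric vector of core temperatures for one stage group.
#' @param stage The stage label (1-4).
#' @param conf_level Confidence level for the mean CI, default 0.95.
#' @param pi_level Prediction interval coverage, default 0.90.
#' @param quantile_type Quantile estimator type passed to [stats::quantile()];
#'   default 7 (linear interpolation of order statistics).
#' @return A one-row tibble: `stage`, `n`, `mean_temp`, `sd_temp`, `min`,
#'   `max`, `ci_lower`, `ci_upper`, `pi_lower`, `pi_upper`. With n = 1 the SD
#'   and CI are `NA`.
#' @export
stage_summary <- function(temps, stage, conf_level = 0.95, pi_level = 0.90,
                          quantile_type = 7) {
  if (length(temps) == 0) stop("empty stage group", call. = FALSE)
  n <- length(temps)
  m <- mean(temps)
  s <- if (n >= 2) stats::sd(temps) else NA_real_
  ci <- if (n >= 2) {
    tmult <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    c(m - tmult * s / sqrt(n), m + tmult * s / sqrt(n))
  } else {
    c(NA_real_, NA_real_)
  }
  alpha <- (1 - pi_level) / 2
  pi <- unname(stats::quantile(temps, c(alpha, 1 - alpha), type = quantile_type))
  tibble::tibble(
    stage = as.integer(stage), n = n, mean_temp = m, sd_temp = s,
    min = min(temps), max = max(temps),
    ci_lower = ci[1], ci_upper = ci[2],
    pi_lower = pi[1], pi_upper = pi[2]
  )
}

#' Per-stage summaries for a staged cohort
#'
#' @param cohort A staged cohort.
#' @inheritParams stage_summary
#' @return A tibble with one row per stage present in the cohort.
#' @export
stage_summaries <- function(cohort, conf_level = 0.95, pi_level = 0.90,
                            quantile_type = 7) {
  stages <- sort(unique(cohort$clinical_stage))
  do.call(rbind, lapply(stages, function(s) {
    stage_summary(cohort$core_temp_c[cohort$clinical_stage == s], s,
                  conf_level, pi_level, quantile_type)
  }))
}

#' Summarise shivering documentation and temperatures
#'
#' Shivering is rarely documented in charts; this tallies the tri-state
#' (present / absent / undocumented) and summarises temperature (median, IQR,
#' range) among the cases where shivering was present.
#'
#' @param cohort A cohort tibble.
#' @return A list with `counts` (named integer vector over the tri-state) and
#'   `temperature` (a list with `n`, `median`, `iqr_lower`, `iqr_upper`,
#'   `min`, `max`, or `NULL` when no shivering-present case exists).
#' @export
shivering_summary <- function(cohort) {
  counts <- c(
    present = sum(cohort$shivering == "present"),
    absent = sum(cohort$shivering == "absent"),
    undocumented = sum(cohort$shivering == "undocumented")
  )
  temps <- cohort$core_temp_c[cohort$shivering == "present"]
  temperature <- if (length(temps) == 0) {
    NULL
  } else {
    q <- unname(stats::quantile(temps, c(0.25, 0.5, 0.75), type = 7))
    list(n = length(temps), median = q[2], iqr_lower = q[1], iqr_upper = q[3],
         min = min(temps), max = max(temps))
  }
  list(counts = counts, temperature = temperature)
}

#' Published stage-by-temperature correspondence counts
#'
#' Loads the packaged fixture of published correspondence counts between the
#' clinical stage and the measured temperature bin for 305 hypothermia cases
#' (122 from hospital sampling, 183 from a literature review), stratified by
#' sampling source.
#'
#' @param stratum `"overall"`, `"hospital"` or `"literature"`.
#' @return A `correspondence_table` for the requested stratum.
#' @examples
#' table3_counts("overall")
#' @export
table3_counts <- function(stratum = c("overall", "hospital", "literature")) {
  stratum <- match.arg(stratum)
  path <- system.file("extdata", "table3_counts.csv", package = "hypostage",
                      mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  df <- df[df$stratum == stratum, ]
  m <- matrix(0L, 4, 4)
  m[cbind(df$stage, df$bin)] <- df$count
  as_correspondence_table(m, stratum)
}
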