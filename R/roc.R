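#' ROC coordinates for discriminating two adjacent stage groups by temperature
#'
#' For a candidate threshold t, sensitivity is the proportion of the
#' higher-stage (colder) group with a temperature strictly below t, and
#' specificity the proportion of the lower-stage (warmer) group with a
#' temperature equal to or above t.
#'
#' @param lower_temps Temperatures of the lower (warmer) stage group.
#' @param higher_temps Temperatures of the higher (colder) stage group.
#' @param candidates Candidate thresholds; by default all distinct observed
#'   temperatures across both groups plus one value 0.1 above the maximum (so
#'   the specificity-zero end of the curve is reachable).
#' @return A tibble with columns `threshold`, `sensitivity`, `specificity`,
#'   ordered by threshold.
#' @export
roc_points <- function(lower_temps, higher_temps, candidates = NULL) {
  if (length(lower_temps) == 0 || length(higher_temps) == 0) {
    stop("both stage groups must be non-empty", call. = FALSE)
  }
  if (is.null(candidates)) {
    candidates <- sort(unique(c(lower_temps, higher_temps)))
    candidates <- c(candidates, max(candidates) + 0.1)
  } else {
    candidates <- sort(unique(candidates))
  }
  tibble::tibble(
    threshold = candidates,
    sensitivity = vapply(candidates, function(t) mean(higher_temps < t), 0),
    specificity = vapply(candidates, function(t) mean(lower_temps >= t), 0)
  )
}

#' Area under the ROC curve for two temperature groups
#'
#' AUC is the probability that a randomly chosen higher-stage case is colder
#' than a randomly chosen lower-stage case, with ties credited one half.
#' Computed from the rank (Mann-Whitney) statistic with midranks, so it is
#' independent of any threshold grid.
#'
#' @inheritParams roc_points
#' @return A number in \[0, 1\].
#' @export
roc_auc <- function(lower_temps, higher_temps) {
  n_l <- length(lower_temps)
  n_h <- length(higher_temps)
  if (n_l == 0 || n_h == 0) stop("both stage groups must be non-empty", call. = FALSE)
  r <- rank(c(lower_temps, higher_temps))
  (sum(r[seq_len(n_l)]) - n_l * (n_l + 1) / 2) / (n_l * n_h)
}

#' Youden-optimal temperature threshold between two stage groups
#'
#' Scans the candidate thresholds (all distinct observed temperatures plus one
#' value above the maximum) and returns the threshold maximising
#' sensitivity + specificity, which is equivalent to maximising the Youden
#' index J = sensitivity + specificity - 1. When several thresholds tie, the
#' full tied set is reported and the largest tied candidate is selected (the
#' clinically conservative direction: it maximises sensitivity for detecting
#' the colder stage); `tie_rule = "smallest"` selects the other end.
#'
#' @inheritParams roc_points
#' @param tie_rule `"largest"` (default) or `"smallest"`.
#' @return A list with `threshold`, `sensitivity`, `specificity`, `youden_j`,
#'   and `tied` (all thresholds achieving the maximum).
#' @export
youden_optimal <- function(lower_temps, higher_temps, candidates = NULL,
                           tie_rule = c("largest", "smallest")) {
  tie_rule <- match.arg(tie_rule)
  pts <- roc_points(lower_temps, higher_temps, candidates)
  j <- pts$sensitivity + pts$specificity - 1
  tied <- pts$threshold[j >= max(j) - 1e-12]
  t_star <- if (tie_rule == "largest") max(tied) else min(tied)
  i <- match(t_star, pts$threshold)
  list(
    threshold = t_star,
    sensitivity = pts$sensitivity[i],
    specificity = pts$specificity[i],
    youden_j = j[i],
    tied = tied
  )
}

historical_cutoffs <- c(`1|2` = 32, `2|3` = 28, `3|4` = 24)

#' Adjacent-stage ROC analyses for a staged cohort
#'
#' Runs the three adjacent-stage analyses (stages 1 vs 2, 2 vs 3, 3 vs 4):
#' ROC coordinates, AUC, the Youden-optimal threshold, and the comparison of
#' sensitivity + specificity (percent scale) at the optimal versus the
#' historical cutoff (32, 28 and 24 degrees C).
#'
#' @param cohort A staged cohort (see [stage_cohort()]).
#' @param tie_rule Passed to [youden_optimal()].
#' @return A named list (`"1|2"`, `"2|3"`, `"3|4"`) of `roc_result` objects;
#'   pairs with an empty stage group are dropped with a warning. Each result
#'   holds `pair`, `points`, `auc`, `optimal` (threshold, sensitivity,
#'   specificity, youden_j, tied), `historical` (cutoff plus its sensitivity
#'   and specificity), and `sum_sens_spec_pct` at both thresholds.
#' @export
adjacent_thresholds <- function(cohort, tie_rule = c("largest", "smallest")) {
  tie_rule <- match.arg(tie_rule)
  temps <- split(cohort$core_temp_c, factor(cohort$clinical_stage, levels = 1:4))
  out <- list()
  for (s in 1:3) {
    lab <- sprintf("%d|%d", s, s + 1)
    lower <- temps[[s]]
    higher <- temps[[s + 1]]
    if (length(lower) == 0 || length(higher) == 0) {
      warning(sprintf("stage pair %s skipped: empty stage group", lab), call. = FALSE)
      next
    }
    pts <- roc_points(lower, higher)
    opt <- youden_optimal(lower, higher, tie_rule = tie_rule)
    cut <- historical_cutoffs[[lab]]
    hist_sens <- mean(higher < cut)
    hist_spec <- mean(lower >= cut)
    out[[lab]] <- structure(
      list(
        pair = c(lower_stage = s, higher_stage = s + 1),
        points = pts,
        auc = roc_auc(lower, higher),
        optimal = opt,
        historical = list(cutoff = cut, sensitivity = hist_sens,
                          specificity = hist_spec),
        sum_sens_spec_pct = c(
          optimal = 100 * (opt$sensitivity + opt$specificity),
          historical = 100 * (hist_sens + hist_spec)
        )
      ),
      class = "roc_result"
    )
  }
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "Stages %d vs %d: AUC %.3f; optimal threshold %.1f C (sens %.0f%%, spec %.0f%%, sens+spec %.0f); historical cutoff %.0f C (sens+spec %.0f)\n",
    x$pair[1], x$pair[2], x$auc, x$optimal$threshold,
    100 * x$optimal$sensitivity, 100 * x$optimal$specificity,
    x$sum_sens_spec_pct["optimal"], x$historical$cutoff,
    x$sum_sens_spec_pct["historical"]
  ))
  invisible(x)
}
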