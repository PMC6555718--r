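#' Theoretical core-temperature range of a clinical stage
#'
#' The Swiss staging model links each clinical stage to a typical core
#' temperature range: stage 1 is 32 to <35 degrees C, stage 2 is 28 to <32,
#' stage 3 is 24 to <28, and stage 4 is below 24. Ranges are half-open
#' (lower bound inclusive, upper bound exclusive) so that the four ranges
#' partition all temperatures below 35 degrees C without overlap or gap.
#'
#' @param stage Integer vector of clinical stages in 1:4.
#' @return A tibble with one row per input stage and columns `stage`, `lower`,
#'   `upper`, `lower_inclusive`, `upper_inclusive`. Stage 4 has `lower = -Inf`
#'   (unbounded below).
#' @examples
#' theoretical_range(1:4)
#' @export
theoretical_range <- function(stage) {
  if (!all(stage %in% 1:4)) {
    stop("`stage` must contain only values 1, 2, 3 or 4", call. = FALSE)
  }
  lowers <- c(32, 28, 24, -Inf)
  uppers <- c(35, 32, 28, 24)
  tibble::tibble(
    stage = as.integer(stage),
    lower = lowers[stage],
    upper = uppers[stage],
    lower_inclusive = is.finite(lowers[stage]),
    upper_inclusive = FALSE
  )
}

#' Bin a measured core temperature into the staging model's ranges
#'
#' Maps a measured temperature below 35 degrees C to the stage range it falls
#' in: bin 1 for \[32, 35), bin 2 for \[28, 32), bin 3 for \[24, 28), bin 4
#' for anything below 24.
#'
#' @param core_temp_c Numeric vector of core temperatures in degrees C, all
#'   below 35 (hypothermia by definition).
#' @return Integer vector of bins in 1:4.
#' @examples
#' bin_temperature(c(33.4, 28.0, 24.0, 13.7))
#' @export
bin_temperature <- function(core_temp_c) {
  if (any(!is.finite(core_temp_c))) {
    stop("`core_temp_c` must be finite", call. = FALSE)
  }
  if (any(core_temp_c >= 35)) {
    stop("temperature >= 35 degrees C is outside the hypothermia staging model",
         call. = FALSE)
  }
  as.integer(4L - findInterval(core_temp_c, c(24, 28, 32)))
}

#' Assign the Swiss clinical hypothermia stage
#'
#' Applies the clinical staging rules: stage 4 requires the absence of vital
#' signs (respiratory rate of 0, no measurable blood pressure, no palpable
#' pulse) together with GCS 3 or AVPU 'U'; otherwise the stage follows the
#' level of consciousness — GCS 15 (AVPU 'A') is stage 1, GCS 9-14 (AVPU 'V')
#' stage 2, GCS 3-8 (AVPU 'P' or 'U') stage 3. GCS takes precedence over AVPU
#' when both are recorded. Shivering is never an input: staging uses the state
#' of consciousness and vital signs only.
#'
#' "No measurable blood pressure" is encoded as `systolic_bp = 0`; a missing
#' blood pressure never counts as absent, so stage 4 is only reached on
#' positive evidence that all three vital signs are absent.
#'
#' @param gcs Glasgow Coma Scale score, integer 3-15, or `NA`.
#' @param avpu One of `"A"`, `"V"`, `"P"`, `"U"`, or `NA`.
#' @param respiration_rate Breaths per minute, or `NA`.
#' @param systolic_bp Systolic blood pressure in mmHg; `0` means measured but
#'   not measurable; `NA` means not recorded.
#' @param pulse_palpable One of `"yes"`, `"no"`, `"unknown"`.
#' @return A list of class `stage_assignment` with elements `stage` (integer
#'   1-4), `basis` (`"gcs"`, `"avpu"` or `"vitals_absent"`), and
#'   `predicted_range` (one-row tibble, see [theoretical_range()]).
#' @examples
#' assign_clinical_stage(gcs = 15, avpu = NA, pulse_palpable = "yes")
#' assign_clinical_stage(gcs = 3, avpu = "U", respiration_rate = 0,
#'                       systolic_bp = 0, pulse_palpable = "no")
#' @export
assign_clinical_stage <- function(gcs = NA, avpu = NA, respiration_rate = NA,
                                  systolic_bp = NA, pulse_palpable = "unknown") {
  if (!is.na(gcs) && (gcs < 3 || gcs > 15 || gcs != round(gcs))) {
    stop("`gcs` must be an integer between 3 and 15", call. = FALSE)
  }
  if (!is.na(avpu) && !avpu %in% c("A", "V", "P", "U")) {
    stop("`avpu` must be one of 'A', 'V', 'P', 'U'", call. = FALSE)
  }
  if (is.na(gcs) && is.na(avpu)) {
    stop("unstageable: both GCS and AVPU are missing", call. = FALSE)
  }

  vitals_absent <- !is.na(respiration_rate) && respiration_rate == 0 &&
    !is.na(systolic_bp) && systolic_bp == 0 &&
    !is.na(pulse_palpable) && pulse_palpable == "no"

  if (vitals_absent) {
    deepest <- (!is.na(gcs) && gcs == 3) ||
      (is.na(gcs) && !is.na(avpu) && avpu == "U")
    if (!deepest) {
      stop("inconsistent record: vital signs absent but consciousness is not ",
           "GCS 3 / AVPU 'U'", call. = FALSE)
    }
    return(new_stage_assignment(4L, "vitals_absent"))
  }

  if (!is.na(gcs)) {
    stage <- if (gcs == 15) 1L else if (gcs >= 9) 2L else 3L
    return(new_stage_assignment(stage, "gcs"))
  }
  stage <- switch(avpu, A = 1L, V = 2L, P = 3L, U = 3L)
  new_stage_assignment(stage, "avpu")
}

new_stage_assignment <- function(stage, basis) {
  structure(
    list(stage = stage, basis = basis, predicted_range = theoretical_range(stage)),
    class = "stage_assignment"
  )
}

#' @export
print.stage_assignment <- function(x, ...) {
  r <- x$predicted_range
  rng <- if (is.finite(r$lower)) {
    sprintf("[%g, %g)", r$lower, r$upper)
  } else {
    sprintf("< %g", r$upper)
  }
  cat(sprintf("Clinical stage %d (basis: %s; predicted temperature %s degrees C)\n",
              x$stage, x$basis, rng))
  invisible(x)
}

#' Stage every case of a cohort
#'
#' Vectorised application of [assign_clinical_stage()] and
#' [bin_temperature()] over a cohort, appending the columns `clinical_stage`,
#' `stage_basis` and `temp_bin`.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param on_error `"strict"` stops at the first unstageable or inconsistent
#'   case; `"skip"` drops such cases and records them in the
#'   `staging_errors` attribute of the result (row label and reason).
#' @return The cohort with three added columns; cases dropped under
#'   `on_error = "skip"` are listed in `attr(, "staging_errors")`.
#' @export
stage_cohort <- function(cohort, on_error = c("strict", "skip")) {
  on_error <- match.arg(on_error)
  n <- nrow(cohort)
  stage <- integer(n)
  basis <- character(n)
  bad <- logical(n)
  reasons <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(
      assign_clinical_stage(
        gcs = cohort$gcs[i], avpu = cohort$avpu[i],
        respiration_rate = cohort$respiration_rate[i],
        systolic_bp = cohort$systolic_bp[i],
        pulse_palpable = cohort$pulse_palpable[i]
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (on_error == "strict") {
        stop(sprintf("case %s: %s", cohort$case_id[i], conditionMessage(res)),
             call. = FALSE)
      }
      bad[i] <- TRUE
      reasons <- c(reasons, sprintf("case %s: %s", cohort$case_id[i],
                                    conditionMessage(res)))
    } else {
      stage[i] <- res$stage
      basis[i] <- res$basis
    }
  }
  out <- cohort[!bad, , drop = FALSE]
  out$clinical_stage <- stage[!bad]
  out$stage_basis <- basis[!bad]
  out$temp_bin <- bin_temperature(out$core_temp_c)
  attr(out, "staging_errors") <- reasons
  attr(out, "provenance") <- attr(cohort, "provenance")
  out
}
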