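#' @keywords internal
"_PACKAGE"

## Cohort CSV schema v1. Columns, in order; empty cell = missing throughout.
## systolic_bp distinguishes "0" (measured, not measurable -- a stage-4 signal)
## from an empty cell (not recorded).
cohort_columns <- c(
  "case_id", "age", "sex", "source", "gcs", "avpu", "heart_rate",
  "systolic_bp", "respiration_rate", "pulse_palpable", "core_temp_c",
  "temp_at_device_floor", "shivering", "cause", "confounders", "survived",
  "cpc"
)

cohort_schema_comment <- "# hypostage cohort schema v1"

confounder_tokens <- c(
  "alcohol_over_150mg_dl", "other_intoxication", "drug_overdose",
  "hypoglycemia_lt_3mmol", "traumatic_brain_injury", "medical_condition",
  "therapeutic", "neonatal"
)

## Physical plausibility bounds for a recorded core temperature (degrees C).
## Outside these bounds is a data error, not an eligibility exclusion.
temp_plausible <- c(10.0, 42.0)

new_cohort <- function(cases, provenance = "unspecified") {
  stopifnot(!anyDuplicated(cases$case_id))
  out <- tibble::as_tibble(cases)
  attr(out, "provenance") <- provenance
  class(out) <- c("hypo_cohort", class(out))
  out
}

#' Read a hypothermia case cohort from CSV
#'
#' Reads the versioned cohort CSV schema (17 fixed columns, documented in the
#' package README). Every row is either parsed into a validated case or
#' rejected with its row number and reason; rejected rows are reported in the
#' `row_errors` attribute of the result.
#'
#' @param path Path to a cohort CSV file. Lines starting with `#` (the schema
#'   version comment) are ignored.
#' @param schema_version Schema identifier; only `"v1"` exists.
#' @return A cohort tibble (class `hypo_cohort`) with attributes `provenance`
#'   (the file path) and `row_errors` (character vector, empty when all rows
#'   parsed).
#' @seealso [write_cohort()], [apply_eligibility()]
#' @export
read_cohort <- function(path, schema_version = "v1") {
  if (!identical(schema_version, "v1")) {
    stop("unknown schema_version: ", schema_version, call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         na.strings = character(0), check.names = FALSE)
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[cohort_columns]

  errors <- character(0)
  keep <- logical(nrow(raw))
  parsed <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    res <- parse_case_row(raw[i, ])
    if (is.character(res)) {
      errors <- c(errors, sprintf("row %d: %s", i, res))
    } else {
      keep[i] <- TRUE
      parsed[[i]] <- res
    }
  }
  cases <- if (any(keep)) {
    do.call(rbind, parsed[keep])
  } else {
    empty_case_frame()
  }
  if (anyDuplicated(cases$case_id)) {
    stop("schema error: duplicate case_id values", call. = FALSE)
  }
  out <- new_cohort(cases, provenance = path)
  attr(out, "row_errors") <- errors
  out
}

empty_case_frame <- function() {
  data.frame(
    case_id = character(0), age = integer(0), sex = character(0),
    source = character(0), gcs = integer(0), avpu = character(0),
    heart_rate = numeric(0), systolic_bp = numeric(0),
    respiration_rate = numeric(0), pulse_palpable = character(0),
    core_temp_c = numeric(0), temp_at_device_floor = logical(0),
    shivering = character(0), cause = character(0), confounders = character(0),
    survived = character(0), cpc = integer(0),
    stringsAsFactors = FALSE
  )
}

num_or_na <- function(x) {
  if (is.na(x) || x == "") return(NA_real_)
  suppressWarnings(as.numeric(x))
}

## Returns a one-row data.frame, or a character reason for rejection.
parse_case_row <- function(row) {
  row <- lapply(row, as.character)
  blank <- function(x) is.na(x) || x == ""

  if (blank(row$case_id)) return("case_id missing")

  temp <- num_or_na(row$core_temp_c)
  if (blank(row$core_temp_c)) return("core_temp_c missing")
  if (is.na(temp)) return(sprintf("core_temp_c unparseable: '%s'", row$core_temp_c))
  if (temp < temp_plausible[1] || temp > temp_plausible[2]) {
    return(sprintf("core_temp_c %.1f outside physical plausibility bounds [%.1f, %.1f]",
                   temp, temp_plausible[1], temp_plausible[2]))
  }

  age <- num_or_na(row$age)
  if (blank(row$age) || is.na(age) || age < 0 || age != round(age)) {
    return(sprintf("age invalid: '%s'", row$age))
  }

  sex <- if (blank(row$sex)) "unknown" else row$sex
  if (!sex %in% c("male", "female", "unknown")) {
    return(sprintf("sex invalid: '%s'", row$sex))
  }
  if (!row$source %in% c("hospital", "literature")) {
    return(sprintf("source invalid: '%s'", row$source))
  }

  gcs <- num_or_na(row$gcs)
  if (!blank(row$gcs) && (is.na(gcs) || gcs < 3 || gcs > 15 || gcs != round(gcs))) {
    return(sprintf("gcs out of range 3-15: '%s'", row$gcs))
  }
  avpu <- if (blank(row$avpu)) NA_character_ else row$avpu
  if (!is.na(avpu) && !avpu %in% c("A", "V", "P", "U")) {
    return(sprintf("avpu invalid: '%s'", row$avpu))
  }

  hr <- num_or_na(row$heart_rate)
  if (!blank(row$heart_rate) && (is.na(hr) || hr < 0)) {
    return(sprintf("heart_rate invalid: '%s'", row$heart_rate))
  }
  sbp <- num_or_na(row$systolic_bp)
  if (!blank(row$systolic_bp) && (is.na(sbp) || sbp < 0)) {
    return(sprintf("systolic_bp invalid: '%s'", row$systolic_bp))
  }
  rr <- num_or_na(row$respiration_rate)
  if (!blank(row$respiration_rate) && (is.na(rr) || rr < 0)) {
    return(sprintf("respiration_rate invalid: '%s'", row$respiration_rate))
  }

  pulse <- if (blank(row$pulse_palpable)) "unknown" else row$pulse_palpable
  if (!pulse %in% c("yes", "no", "unknown")) {
    return(sprintf("pulse_palpable invalid: '%s'", row$pulse_palpable))
  }

  floor_flag <- if (blank(row$temp_at_device_floor)) FALSE else
    toupper(row$temp_at_device_floor) %in% c("TRUE", "T", "1", "YES")

  shiver <- if (blank(row$shivering)) "undocumented" else row$shivering
  if (!shiver %in% c("present", "absent", "undocumented")) {
    return(sprintf("shivering invalid: '%s'", row$shivering))
  }

  cause <- if (blank(row$cause)) "environmental_other_unknown" else row$cause
  if (!cause %in% c("water", "avalanche", "environmental_other_unknown")) {
    return(sprintf("cause invalid: '%s'", row$cause))
  }

  conf <- if (blank(row$confounders)) "" else row$confounders
  if (conf != "") {
    tokens <- strsplit(conf, ";", fixed = TRUE)[[1]]
    bad <- setdiff(tokens, confounder_tokens)
    if (length(bad) > 0) {
      return(sprintf("unknown confounder token(s): %s", paste(bad, collapse = ", ")))
    }
    conf <- paste(sort(unique(tokens)), collapse = ";")
  }

  survived <- if (blank(row$survived)) "unknown" else row$survived
  if (!survived %in% c("yes", "no", "unknown")) {
    return(sprintf("survived invalid: '%s'", row$survived))
  }
  cpc <- num_or_na(row$cpc)
  if (!blank(row$cpc) && (is.na(cpc) || cpc < 1 || cpc > 5 || cpc != round(cpc))) {
    return(sprintf("cpc invalid: '%s'", row$cpc))
  }
  if (!is.na(cpc) && survived == "no") {
    return("cpc recorded for a non-survivor")
  }

  data.frame(
    case_id = row$case_id, age = as.integer(age), sex = sex,
    source = row$source, gcs = if (blank(row$gcs)) NA_integer_ else as.integer(gcs),
    avpu = avpu, heart_rate = hr, systolic_bp = sbp, respiration_rate = rr,
    pulse_palpable = pulse, core_temp_c = temp,
    temp_at_device_floor = floor_flag, shivering = shiver, cause = cause,
    confounders = conf, survived = survived,
    cpc = if (blank(row$cpc)) NA_integer_ else as.integer(cpc),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to CSV
#'
#' Writes the versioned cohort CSV schema. Missing values become empty cells
#' (never `"0"`, which for `systolic_bp` means "measured, not measurable");
#' `write_cohort()` followed by [read_cohort()] reproduces the cohort
#' field-for-field.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns, drop = FALSE]
  df$temp_at_device_floor <- ifelse(df$temp_at_device_floor, "TRUE", "FALSE")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(cohort_schema_comment, con)
  utils::write.csv(df, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Apply the study eligibility criteria
#'
#' Keeps adult cases (age >= 18) with hypothermia (core temperature strictly
#' below 35 degrees C), no confounding factor that could itself impair
#' consciousness (acute intoxication, drug overdose, hypoglycemia below
#' 3 mmol/L, traumatic brain injury, causal medical condition, therapeutic or
#' neonatal hypothermia; blood alcohol is only a confounder above 150 mg/dL
#' and is encoded as such), and enough consciousness data (GCS or AVPU) to be
#' staged. Cases failing several criteria are counted under the first failing
#' one, in the screening-funnel order age, temperature, confounder,
#' stageability. Eligibility never looks at outcome fields.
#'
#' @param cohort A cohort tibble.
#' @param min_age Minimum age in years (inclusive); default 18.
#' @param max_temp Exclusive upper temperature bound in degrees C; default 35.
#' @return A list with elements `cohort` (the eligible cases, same class and
#'   provenance), `excluded` (tibble of case_id and reason), and `report`
#'   (named integer vector of exclusion counts per criterion, plus
#'   `included`).
#' @export
apply_eligibility <- function(cohort, min_age = 18, max_temp = 35) {
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(reason) & cohort$age < min_age] <- "age"
  reason[is.na(reason) & cohort$core_temp_c >= max_temp] <- "temperature"
  reason[is.na(reason) & cohort$confounders != ""] <- "confounder"
  reason[is.na(reason) & is.na(cohort$gcs) & is.na(cohort$avpu)] <- "unstageable"

  keep <- is.na(reason)
  out <- cohort[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(cohort, "provenance")
  excluded <- tibble::tibble(
    case_id = cohort$case_id[!keep],
    reason = reason[!keep]
  )
  report <- c(
    included = sum(keep),
    age = sum(reason == "age", na.rm = TRUE),
    temperature = sum(reason == "temperature", na.rm = TRUE),
    confounder = sum(reason == "confounder", na.rm = TRUE),
    unstageable = sum(reason == "unstageable", na.rm = TRUE)
  )
  list(cohort = out, excluded = excluded, report = report)
}
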