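# Builders for in-code fixtures: a fully specified single case with sensible
# defaults, and a cohort assembled from such cases.

make_case <- function(case_id = "C1", age = 50L, sex = "male",
                      source = "hospital", gcs = 15L, avpu = NA_character_,
                      heart_rate = 80, systolic_bp = 120,
                      respiration_rate = 16, pulse_palpable = "yes",
                      core_temp_c = 33.0, temp_at_device_floor = FALSE,
                      shivering = "undocumented",
                      cause = "environmental_other_unknown",
                      confounders = "", survived = "yes", cpc = 1L) {
  tibble::tibble(
    case_id = case_id, age = age, sex = sex, source = source, gcs = gcs,
    avpu = avpu, heart_rate = heart_rate, systolic_bp = systolic_bp,
    respiration_rate = respiration_rate, pulse_palpable = pulse_palpable,
    core_temp_c = core_temp_c, temp_at_device_floor = temp_at_device_floor,
    shivering = shivering, cause = cause, confounders = confounders,
    survived = survived, cpc = cpc
  )
}

make_cohort <- function(...) {
  cases <- do.call(rbind, list(...))
  attr(cases, "provenance") <- "test"
  class(cases) <- c("hypo_cohort", class(cases))
  cases
}

# A small mixed-source staged cohort used by several suites.
toy_staged_cohort <- function() {
  co <- make_cohort(
    make_case("H1", core_temp_c = 33.5, gcs = 15L),
    make_case("H2", core_temp_c = 30.2, gcs = 12L),
    make_case("H3", core_temp_c = 26.4, gcs = 5L),
    make_case("H4", core_temp_c = 21.0, gcs = 3L, heart_rate = 0,
              systolic_bp = 0, respiration_rate = 0, pulse_palpable = "no",
              survived = "no", cpc = NA_integer_),
    make_case("L1", source = "literature", core_temp_c = 34.0, gcs = 15L),
    make_case("L2", source = "literature", core_temp_c = 27.5, gcs = 10L),
    make_case("L3", source = "literature", core_temp_c = 25.0, gcs = 4L),
    make_case("L4", source = "literature", core_temp_c = 18.3, gcs = 3L,
              heart_rate = 0, systolic_bp = 0, respiration_rate = 0,
              pulse_palpable = "no", survived = "no", cpc = NA_integer_)
  )
  stage_cohort(co)
}
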