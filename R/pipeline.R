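#' Run the full staging-evaluation pipeline
#'
#' Sequences eligibility filtering, stage assignment, concordance analysis
#' (correspondence tables, summaries and per-stage statistics by stratum),
#' adjacent-stage ROC threshold analysis, shivering tally and the
#' hospital-versus-literature comparison, and returns one report object.
#' Stages whose preconditions are unmet (an empty stage group, a single
#' sampling source) are skipped with a warning, not a crash.
#'
#' The input may be patient-level (a cohort or a generator configuration) or
#' a bare correspondence count matrix — the published-counts mode, in which
#' only the concordance block is computable and the other blocks are `NULL`.
#'
#' @param input A cohort tibble, a `generator_config` (a cohort is generated
#'   from it), a `correspondence_table`, or the fixture name `"table3"`.
#' @param ci_method Proportion CI method, `"wald"` or `"wilson"`.
#' @param quantile_type Quantile estimator for prediction intervals.
#' @param tie_rule ROC tie rule, see [youden_optimal()].
#' @param seed Seed recorded in provenance; defaults to the config seed when
#'   generating, `NA` otherwise.
#' @return A list of class `hypostage_report` with blocks `provenance`,
#'   `eligibility`, `correspondence`, `concordance`, `stage_summaries`,
#'   `shivering`, `thresholds`, `comparison`, and `skipped` (character vector
#'   of skipped stages with reasons).
#' @export
run_pipeline <- function(input, ci_method = c("wald", "wilson"),
                         quantile_type = 7,
                         tie_rule = c("largest", "smallest"), seed = NA) {
  ci_method <- match.arg(ci_method)
  tie_rule <- match.arg(tie_rule)
  skipped <- character(0)

  if (identical(input, "table3")) {
    input <- table3_counts("overall")
  }

  if (inherits(input, "correspondence_table")) {
    report <- list(
      provenance = provenance_block(seed, list(mode = "counts", ci_method = ci_method)),
      eligibility = NULL,
      correspondence = stats::setNames(list(input), attr(input, "stratum")),
      concordance = stats::setNames(list(concordance_summary(input, ci_method)),
                                    attr(input, "stratum")),
      stage_summaries = NULL, shivering = NULL, thresholds = NULL,
      comparison = NULL,
      skipped = c("stage_summaries: patient-level temperatures unavailable in counts mode",
                  "thresholds: patient-level temperatures unavailable in counts mode",
                  "comparison: patient-level data unavailable in counts mode",
                  "shivering: patient-level data unavailable in counts mode")
    )
    class(report) <- "hypostage_report"
    return(report)
  }

  if (inherits(input, "generator_config")) {
    if (is.na(seed)) seed <- input$seed
    cohort <- generate_cohort(input, seed = seed)
    config_opts <- list(mode = "generator", config = unclass(input),
                        ci_method = ci_method, quantile_type = quantile_type,
                        tie_rule = tie_rule)
  } else {
    cohort <- input
    config_opts <- list(mode = "cohort", provenance = attr(input, "provenance"),
                        ci_method = ci_method, quantile_type = quantile_type,
                        tie_rule = tie_rule)
  }

  elig <- apply_eligibility(cohort)
  staged <- stage_cohort(elig$cohort, on_error = "skip")
  if (length(attr(staged, "staging_errors")) > 0) {
    skipped <- c(skipped, paste0("staging: ", attr(staged, "staging_errors")))
  }

  strata <- c("overall", intersect(c("hospital", "literature"), unique(staged$source)))
  if (length(strata) < 3) strata <- "overall"
  correspondence <- lapply(stats::setNames(strata, strata), function(st) {
    correspondence_table(staged, st)
  })
  concordance <- lapply(correspondence, concordance_summary, ci_method = ci_method)
  summaries <- stage_summaries(staged, quantile_type = quantile_type)
  shiver <- shivering_summary(staged)

  thresholds <- withCallingHandlers(
    adjacent_thresholds(staged, tie_rule = tie_rule),
    warning = function(w) {
      skipped <<- c(skipped, paste0("thresholds: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )

  comparison <- if (all(c("hospital", "literature") %in% staged$source)) {
    build_table2_report(staged)
  } else {
    skipped <- c(skipped, "comparison: cohort does not contain both sampling sources")
    NULL
  }

  report <- list(
    provenance = provenance_block(seed, config_opts),
    eligibility = elig$report,
    correspondence = correspondence,
    concordance = concordance,
    stage_summaries = summaries,
    shivering = shiver,
    thresholds = thresholds,
    comparison = comparison,
    skipped = skipped
  )
  class(report) <- "hypostage_report"
  report
}

provenance_block <- function(seed, config_opts) {
  list(
    package = "hypostage",
    version = as.character(utils::packageVersion("hypostage")),
    seed = seed,
    config_hash = rlang::hash(config_opts)
  )
}

#' @export
print.hypostage_report <- function(x, ...) {
  cat("hypostage analysis report\n")
  cat(sprintf("  provenance: v%s, seed %s, config %s\n", x$provenance$version,
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8)))
  for (cs in x$concordance) print(cs)
  if (!is.null(x$thresholds)) for (r in x$thresholds) print(r)
  if (length(x$skipped) > 0) {
    cat("  skipped:\n")
    for (s in x$skipped) cat("   -", s, "\n")
  }
  invisible(x)
}

#' Render an analysis report to files
#'
#' Writes a report in one or more formats. `json` is lossless (full numeric
#' precision); `csv` writes one file per tabular block (correspondence
#' tables, stage summaries, comparison report); `markdown` writes a single
#' human-readable summary with temperatures rounded to 0.1 degrees C and
#' percentages to whole percent.
#'
#' @param report A `hypostage_report`.
#' @param dir Output directory (created if needed).
#' @param format Character vector from `c("json", "csv", "markdown")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, format = c("json", "csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  if ("json" %in% format) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    written <- c(written, path)
  }
  if ("csv" %in% format) {
    for (st in names(report$correspondence)) {
      path <- file.path(dir, sprintf("correspondence_%s.csv", st))
      m <- unclass(report$correspondence[[st]])
      utils::write.csv(as.data.frame(m), path)
      written <- c(written, path)
    }
    if (!is.null(report$stage_summaries)) {
      path <- file.path(dir, "stage_summaries.csv")
      utils::write.csv(report$stage_summaries, path, row.names = FALSE)
      written <- c(written, path)
    }
    if (!is.null(report$comparison)) {
      path <- file.path(dir, "comparison.csv")
      utils::write.csv(report$comparison, path, row.names = FALSE)
      written <- c(written, path)
    }
  }
  if ("markdown" %in% format) {
    path <- file.path(dir, "report.md")
    writeLines(report_markdown(report), path)
    written <- c(written, path)
  }
  invisible(written)
}

report_to_list <- function(report) {
  x <- unclass(report)
  x$correspondence <- lapply(x$correspondence, function(m) {
    list(stratum = attr(m, "stratum"), counts = unclass(m))
  })
  x$concordance <- lapply(x$concordance, unclass)
  if (!is.null(x$thresholds)) {
    x$thresholds <- lapply(x$thresholds, function(r) {
      r <- unclass(r)
      r$points <- as.data.frame(r$points)
      r
    })
  }
  if (!is.null(x$stage_summaries)) x$stage_summaries <- as.data.frame(x$stage_summaries)
  if (!is.null(x$comparison)) x$comparison <- as.data.frame(x$comparison)
  if (!is.null(x$eligibility)) x$eligibility <- as.list(x$eligibility)
  x
}

report_markdown <- function(report) {
  lines <- c("# Swiss staging evaluation report", "",
             sprintf("Package hypostage v%s; seed %s; config hash %s.",
                     report$provenance$version, report$provenance$seed,
                     report$provenance$config_hash), "")
  if (length(report$concordance) == 0) {
    lines <- c(lines, "_Empty report: no concordance block._")
    return(lines)
  }
  for (st in names(report$correspondence)) {
    m <- unclass(report$correspondence[[st]])
    lines <- c(lines, sprintf("## Correspondence (%s)", st), "",
               paste("| |", paste(colnames(m), collapse = " | "), "| total |"),
               paste(rep("|---", 6), collapse = ""))
    for (i in 1:4) {
      lines <- c(lines, paste0("| ", rownames(m)[i], " | ",
                               paste(m[i, ], collapse = " | "), " | ",
                               sum(m[i, ]), " |"))
    }
    lines <- c(lines, paste0("| total | ", paste(colSums(m), collapse = " | "),
                             " | ", sum(m), " |"), "")
    cs <- report$concordance[[st]]
    lines <- c(lines, sprintf(
      "Correct %d/%d (%.0f%%, 95%% CI %.0f-%.0f%%); overestimated %d (%.0f%%); underestimated %d (%.0f%%).",
      cs$n_correct, cs$n_total, 100 * cs$proportion_correct,
      100 * cs$ci_lower, 100 * cs$ci_upper,
      cs$n_overestimated, 100 * cs$n_overestimated / cs$n_total,
      cs$n_underestimated, 100 * cs$n_underestimated / cs$n_total), "")
  }
  if (!is.null(report$stage_summaries)) {
    s <- report$stage_summaries
    lines <- c(lines, "## Per-stage temperatures", "",
               "| stage | n | mean ± SD | range | 95% CI | 90% PI |",
               paste(rep("|---", 6), collapse = ""))
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf("| %d | %d | %.1f ± %.1f | %.1f-%.1f | %.1f-%.1f | %.1f-%.1f |",
                                s$stage[i], s$n[i], s$mean_temp[i], s$sd_temp[i],
                                s$min[i], s$max[i], s$ci_lower[i], s$ci_upper[i],
                                s$pi_lower[i], s$pi_upper[i]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$thresholds)) {
    lines <- c(lines, "## Adjacent-stage thresholds", "")
    for (lab in names(report$thresholds)) {
      r <- report$thresholds[[lab]]
      lines <- c(lines, sprintf(
        "- Stages %s: AUC %.3f; optimal threshold %.1f C (sens+spec %.0f) vs historical %.0f C (sens+spec %.0f).",
        lab, r$auc, r$optimal$threshold, r$sum_sens_spec_pct["optimal"],
        r$historical$cutoff, r$sum_sens_spec_pct["historical"]))
    }
    lines <- c(lines, "")
  }
  if (length(report$skipped) > 0) {
    lines <- c(lines, "## Skipped stages", "", paste0("- ", report$skipped))
  }
  lines
}
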