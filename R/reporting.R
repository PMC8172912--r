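#' Render one laboratory's performance report
#'
#' Builds the per-laboratory session report: the verdict, one row per
#' scored quantity (reported value, consensus mean and SD, signed SDI to
#' two decimals, within-limit flag) and any corrective-action categories
#' attached by the coordinator.  Rendering is pure — the same inputs give
#' byte-identical output; a timestamp appears only if injected via
#' `generated_at`.
#'
#' @param verdict One verdict row (as emitted by [score_session()]).
#' @param scores Score tibble for the verdict's session (filtered to the
#'   laboratory internally).
#' @param errors Optional error-record tibble (`session_id`, `lab_id`,
#'   `category`, ...); rows for this laboratory become corrective-action
#'   notes.
#' @param generated_at Optional character timestamp to embed verbatim.
#' @return A list of class `"eqa_lab_report"`.
#' @export
render_lab_report <- function(verdict, scores, errors = NULL,
                              generated_at = NULL) {
  stopifnot(nrow(verdict) == 1)
  lab_scores <- scores[scores$lab_id == verdict$lab_id &
                         scores$session_id == verdict$session_id, , drop = FALSE]
  if (verdict$outcome != "unable_to_report" && nrow(lab_scores) == 0) {
    stop_eqa(sprintf("verdict for lab %s has outcome %s but no scores",
                     verdict$lab_id, verdict$outcome),
             "cd4eqa_consistency_error")
  }
  results <- NULL
  if (nrow(lab_scores) > 0) {
    results <- lab_scores |>
      dplyr::arrange(.data$level, .data$marker, .data$value_kind) |>
      dplyr::transmute(
        quantity = quantity_label(.data$level, .data$marker, .data$value_kind),
        reported_value = .data$reported_value,
        trimmed_mean = .data$trimmed_mean,
        trimmed_sd = .data$trimmed_sd,
        sdi = format_sdi(.data$sdi),
        within_limit = .data$within_limit,
        scoreable = .data$scoreable
      )
  }
  actions <- character(0)
  if (!is.null(errors) && nrow(errors) > 0) {
    e <- errors[errors$lab_id == verdict$lab_id &
                  errors$session_id == verdict$session_id, , drop = FALSE]
    if (nrow(e) > 0) {
      actions <- sort(unique(paste0(e$category, " (",
                                    classify_error(e$category), ")")))
    }
  }
  structure(
    list(
      lab_id = verdict$lab_id,
      session_id = verdict$session_id,
      instrument = verdict$instrument,
      outcome = toupper(verdict$outcome),
      unable_reason = if (verdict$outcome == "unable_to_report")
        verdict$notes else NULL,
      notes = if (verdict$outcome != "unable_to_report" &&
                  !is.na(verdict$notes) && nzchar(verdict$notes))
        verdict$notes else NULL,
      failing_quantities = if (nzchar(verdict$failing_quantities))
        strsplit(verdict$failing_quantities, ";")[[1]] else character(0),
      results = results,
      corrective_actions = actions,
      generated_at = generated_at
    ),
    class = "eqa_lab_report"
  )
}

#' @export
format.eqa_lab_report <- function(x, ...) {
  lines <- c(
    "CD4 EQA LABORATORY PERFORMANCE REPORT",
    sprintf("Laboratory: %s    Session: %s    Instrument: %s",
            x$lab_id, x$session_id, x$instrument),
    sprintf("Outcome: %s", x$outcome)
  )
  if (!is.null(x$unable_reason)) {
    lines <- c(lines, sprintf("Reason unable to report: %s", x$unable_reason),
               "No results were submitted for this session.")
  }
  if (!is.null(x$notes)) lines <- c(lines, sprintf("Note: %s", x$notes))
  if (!is.null(x$results)) {
    r <- x$results
    lines <- c(lines, "",
               sprintf("%-18s %10s %10s %9s %7s %s", "Quantity", "Reported",
                       "Mean", "SD", "SDI", "Within +/-2"),
               sprintf("%-18s %10.2f %10.2f %9.2f %7s %s", r$quantity,
                       r$reported_value,
                       ifelse(is.na(r$trimmed_mean), NA, r$trimmed_mean),
                       r$trimmed_sd, r$sdi,
                       ifelse(!r$scoreable, "unscored",
                              ifelse(r$within_limit, "yes", "NO"))))
  }
  if (length(x$failing_quantities) > 0) {
    lines <- c(lines, "", paste("Failing quantities:",
                                paste(x$failing_quantities, collapse = ", ")))
  }
  if (length(x$corrective_actions) > 0) {
    lines <- c(lines, "", "Recommended corrective action review:",
               paste0("  - ", x$corrective_actions))
  }
  if (!is.null(x$generated_at)) {
    lines <- c(lines, "", paste("Generated:", x$generated_at))
  }
  lines
}

#' @export
print.eqa_lab_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Render the coordinator's session report
#'
#' Aggregates a scored session for the country coordinator: the session
#' summary, the instrument breakdown, failing laboratories with their
#' attached corrective-action categories, the phase distribution of the
#' session's error records, and any quantities left unscored because fewer
#' than the minimum number of laboratories reported them.  Pure rendering:
#' identical inputs give byte-identical output.
#'
#' @param session_result An `"eqa_session_result"` from [score_session()].
#' @param errors Optional error-record tibble for the session.
#' @param generated_at Optional character timestamp to embed verbatim.
#' @return A list of class `"eqa_coordinator_report"`.
#' @export
render_coordinator_report <- function(session_result, errors = NULL,
                                      generated_at = NULL) {
  stopifnot(inherits(session_result, "eqa_session_result"))
  v <- session_result$verdicts
  s <- session_result$scores
  sid <- session_result$session_id
  e <- if (is.null(errors)) {
    tibble::tibble(session_id = character(), lab_id = character(),
                   category = character())
  } else {
    errors[errors$session_id == sid, , drop = FALSE]
  }

  failing <- v[v$outcome == "fail", , drop = FALSE]
  failing_labs <- purrr::pmap(
    failing[c("lab_id", "instrument", "failing_quantities")],
    function(lab_id, instrument, failing_quantities) {
      cats <- sort(unique(e$category[e$lab_id == lab_id]))
      list(lab_id = lab_id, instrument = instrument,
           failing_quantities = if (nzchar(failing_quantities))
             strsplit(failing_quantities, ";")[[1]] else character(0),
           recommended_actions = cats)
    })

  unscored <- s[!s$scoreable, , drop = FALSE]
  unscored_q <- sort(unique(quantity_label(unscored$level, unscored$marker,
                                           unscored$value_kind)))
  structure(
    list(
      session_id = sid,
      summary = summarize_session(v),
      instrument_breakdown = instrument_table(v),
      failing_labs = failing_labs,
      phase_distribution = phase_distribution(e),
      unscored_quantities = unscored_q,
      generated_at = generated_at
    ),
    class = "eqa_coordinator_report"
  )
}

#' @export
format.eqa_coordinator_report <- function(x, ...) {
  sm <- x$summary
  lines <- c(
    "CD4 EQA COORDINATOR SESSION REPORT",
    sprintf("Session: %s", x$session_id),
    sprintf("Registered: %d    Reported: %d    Unable to report: %d",
            sm$n_registered, sm$n_reported, sm$n_unable),
    sprintf("Pass: %s    Fail: %s  (percent of reporting laboratories)",
            format_count_pct(sm$n_pass, sm$pct_pass),
            format_count_pct(sm$n_fail, sm$pct_fail)),
    "",
    "Breakdown by instrument:",
    sprintf("  %-10s %9s %10s %10s", "Instrument", "Reported", "Pass", "Fail")
  )
  b <- x$instrument_breakdown
  lines <- c(lines, sprintf("  %-10s %9d %10s %10s", b$instrument,
                            b$n_reported,
                            format_count_pct(b$n_pass, b$pct_pass),
                            format_count_pct(b$n_fail, b$pct_fail)))
  lines <- c(lines, "", "Sites recommended for corrective action:")
  if (length(x$failing_labs) == 0) {
    lines <- c(lines, "  (none - all reporting sites passed)")
  } else {
    for (fl in x$failing_labs) {
      acts <- if (length(fl$recommended_actions) > 0) {
        paste(fl$recommended_actions, collapse = ", ")
      } else "review pending"
      lines <- c(lines, sprintf("  %s [%s]: %s; actions: %s", fl$lab_id,
                                fl$instrument,
                                paste(fl$failing_quantities, collapse = ", "),
                                acts))
    }
  }
  pd <- x$phase_distribution
  if (nrow(pd) > 0) {
    lines <- c(lines, "", "Error phase distribution:",
               sprintf("  %-16s %4d (%.1f%%)", pd$phase, pd$n, pd$pct))
  }
  if (length(x$unscored_quantities) > 0) {
    lines <- c(lines, "",
               paste("Unscored quantities (fewer than the minimum number of",
                     "reporting laboratories):"),
               paste0("  ", x$unscored_quantities))
  }
  if (!is.null(x$generated_at)) {
    lines <- c(lines, "", paste("Generated:", x$generated_at))
  }
  lines
}

#' @export
print.eqa_coordinator_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a report as structured JSON plus plain text
#'
#' Every report is written twice: a machine-readable JSON document and the
#' human-readable plain-text rendering.  Output is deterministic.
#'
#' @param report An `"eqa_lab_report"` or `"eqa_coordinator_report"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- if (inherits(report, "eqa_lab_report")) {
    sprintf("lab_%s_%s", report$lab_id, report$session_id)
  } else {
    sprintf("coordinator_%s", report$session_id)
  }
  json_path <- file.path(dir, paste0(stem, ".json"))
  txt_path <- file.path(dir, paste0(stem, ".txt"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  writeLines(format(report), txt_path)
  invisible(c(json_path, txt_path))
}
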