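#' Per-session participation and outcome summary
#'
#' Counts verdicts by outcome for each session.  Pass/fail percentages are
#' computed over laboratories that reported (the pass rate among those able
#' to report); the unable-to-report percentage is computed over all
#' registered laboratories.  Percentages are kept at full precision — apply
#' [round_half_up()] for display, which is the convention the program's
#' printed tables use.
#'
#' @param verdicts Verdict tibble (any number of sessions) with columns
#'   `session_id`, `lab_id`, `outcome`.
#' @param session_levels Optional character vector giving session display
#'   order; defaults to sorted unique session ids.
#' @return Tibble with one row per session: `session_id`, `n_registered`,
#'   `n_reported`, `n_pass`, `n_fail`, `n_unable`, `pct_pass`, `pct_fail`,
#'   `pct_unable`.
#' @export
summarize_session <- function(verdicts, session_levels = NULL) {
  stopifnot(nrow(verdicts) >= 1)
  lv <- session_levels %||% sort(unique(verdicts$session_id))
  verdicts |>
    dplyr::mutate(session_id = factor(.data$session_id, levels = lv)) |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      n_registered = dplyr::n(),
      n_pass = sum(.data$outcome == "pass"),
      n_fail = sum(.data$outcome == "fail"),
      n_unable = sum(.data$outcome == "unable_to_report"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_reported = .data$n_pass + .data$n_fail,
      pct_pass = pct_of(.data$n_pass, .data$n_reported),
      pct_fail = pct_of(.data$n_fail, .data$n_reported),
      pct_unable = pct_of(.data$n_unable, .data$n_registered),
      session_id = as.character(.data$session_id)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "session_id", "n_registered", "n_reported", "n_pass", "n_fail",
      "n_unable", "pct_pass", "pct_fail", "pct_unable")))
}

#' Pass/fail breakdown by instrument class
#'
#' One row per (session, instrument) among reporting laboratories, with
#' within-instrument pass/fail percentages, plus an all-instruments row per
#' session.  Instrument rows partition the all-instruments row exactly;
#' instruments absent from a session get no row.
#'
#' @inheritParams summarize_session
#' @param verdicts Verdict tibble; every row must carry an `instrument`.
#' @return Tibble `session_id`, `instrument` (`"All"` for the combined
#'   row), `n_reported`, `n_pass`, `n_fail`, `pct_pass`, `pct_fail`.
#' @export
instrument_table <- function(verdicts, session_levels = NULL) {
  stopifnot(!anyNA(verdicts$instrument))
  lv <- session_levels %||% sort(unique(verdicts$session_id))
  reported <- dplyr::filter(verdicts, .data$outcome != "unable_to_report")
  per_instr <- reported |>
    dplyr::group_by(.data$session_id, .data$instrument) |>
    dplyr::summarise(
      n_reported = dplyr::n(),
      n_pass = sum(.data$outcome == "pass"),
      n_fail = sum(.data$outcome == "fail"),
      .groups = "drop"
    )
  all_instr <- reported |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      instrument = "All",
      n_reported = dplyr::n(),
      n_pass = sum(.data$outcome == "pass"),
      n_fail = sum(.data$outcome == "fail"),
      .groups = "drop"
    )
  dplyr::bind_rows(all_instr, per_instr) |>
    dplyr::mutate(
      pct_pass = pct_of(.data$n_pass, .data$n_reported),
      pct_fail = pct_of(.data$n_fail, .data$n_reported),
      instrument = factor(.data$instrument,
                          levels = c("All", instrument_levels())),
      session_id = factor(.data$session_id, levels = lv)
    ) |>
    dplyr::arrange(.data$session_id, .data$instrument) |>
    dplyr::mutate(session_id = as.character(.data$session_id),
                  instrument = as.character(.data$instrument))
}

#' Per-instrument failure-rate series
#'
#' The failure percentage of each instrument class across sessions, with
#' the all-instruments series as the baseline.
#'
#' @inheritParams instrument_table
#' @return Tibble `session_id`, `instrument`, `pct_fail` ordered by session
#'   then instrument (`"All"` first).
#' @export
failure_rate_series <- function(verdicts, session_levels = NULL) {
  instrument_table(verdicts, session_levels)[
    , c("session_id", "instrument", "pct_fail")]
}

#' Participation series
#'
#' Number of registered laboratories (reported + unable to report) per
#' session, in session order.
#'
#' @inheritParams summarize_session
#' @return Tibble `session_id`, `n_registered`.
#' @export
participation_series <- function(verdicts, session_levels = NULL) {
  if (nrow(verdicts) == 0) {
    return(tibble::tibble(session_id = character(), n_registered = integer()))
  }
  summarize_session(verdicts, session_levels)[, c("session_id", "n_registered")]
}

#' Format a count with its display percentage
#'
#' Renders `"n (pct)"` cells in the style of the program's session tables,
#' with the percentage rounded half-up to the nearest integer.
#'
#' @param n Integer counts.
#' @param pct Percentages at full precision.
#' @return Character vector like `"29 (58)"`.
#' @export
format_count_pct <- function(n, pct) {
  ifelse(is.na(pct), sprintf("%d (-)", n),
         sprintf("%d (%d)", n, as.integer(round_half_up(pct))))
}
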