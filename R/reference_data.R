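#' Published session counts of the Cameroon national CD4 EQA program
#'
#' Reported/pass/fail counts per session and instrument class for the
#' eleven sessions (2014–2018) of the Cameroon national CD4 enumeration
#' EQA program, as published in the program's evaluation summary.  Counts
#' only are stored; percentages are always recomputed from the counts, so
#' the occasional rounding slips of the printed table do not propagate.
#'
#' @return Tibble `session_id` (`"S01"`–`"S11"`), `instrument`,
#'   `n_reported`, `n_pass`, `n_fail`.
#' @export
cameroon_session_counts <- function() {
  path <- system.file("extdata", "cameroon_session_counts.csv",
                      package = "cd4eqa", mustWork = TRUE)
  readr::read_csv(path, col_types = "cciii", progress = FALSE)
}

#' Expand session counts into a verdict fixture
#'
#' Turns a counts table (as from [cameroon_session_counts()]) into an
#' equivalent per-laboratory verdict tibble — `n_pass` passing and `n_fail`
#' failing synthetic laboratories per (session, instrument), plus
#' `n_unable` unable-to-report ones when that column is present.  The
#' trends functions applied to this fixture reproduce the published
#' percentages.
#'
#' @param counts Tibble with columns `session_id`, `instrument`, `n_pass`,
#'   `n_fail` and optionally `n_unable`.
#' @return Verdict tibble (`session_id`, `lab_id`, `instrument`, `outcome`)
#'   with synthetic laboratory ids.
#' @export
counts_to_verdicts <- function(counts) {
  if (!"n_unable" %in% names(counts)) counts$n_unable <- 0L
  rows <- purrr::pmap(
    counts[c("session_id", "instrument", "n_pass", "n_fail", "n_unable")],
    function(session_id, instrument, n_pass, n_fail, n_unable) {
      outcome <- rep(c("pass", "fail", "unable_to_report"),
                     c(n_pass, n_fail, n_unable))
      tibble::tibble(session_id = session_id, instrument = instrument,
                     outcome = outcome)
    })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(lab_id = sprintf("FIX%03d", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("session_id", "lab_id", "instrument",
                                  "outcome")))
}
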