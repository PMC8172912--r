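#' The program's error taxonomy
#'
#' Fixed mapping from failure category to testing phase.  Pre-analytical
#' errors occur before the specimen is tested (transport and preservation,
#' identification, request procedure, mix-ups); analytical errors occur
#' during testing (reagents, pipetting and pipette calibration, gating,
#' instrument error codes, sample handling/processing); post-analytical
#' errors occur after testing (data entry on the paper form or the website,
#' transcription, reporting omissions).
#'
#' @return Tibble with columns `category` and `phase`; every category maps
#'   to exactly one phase.
#' @export
error_taxonomy <- function() {
  tibble::tibble(
    category = c(
      "delayed_transport_preservation", "sample_integrity",
      "incorrect_sample_identification", "request_procedure_error",
      "sample_mixup",
      "expired_reagents", "pipetting_error", "pipette_calibration",
      "gating_technique", "instrument_error_code",
      "sample_handling_processing",
      "data_entry_paper_form", "data_entry_website", "transcription_error",
      "reporting_omission"
    ),
    phase = c(
      rep("pre_analytical", 5),
      rep("analytical", 6),
      rep("post_analytical", 4)
    )
  )
}

phase_levels <- function() c("pre_analytical", "analytical", "post_analytical")

#' Classify an error category into its testing phase
#'
#' @param category Character vector of categories from [error_taxonomy()].
#' @return Character vector of phases (`pre_analytical`, `analytical`,
#'   `post_analytical`).
#' @examples
#' classify_error(c("gating_technique", "transcription_error"))
#' @export
classify_error <- function(category) {
  tax <- error_taxonomy()
  unknown <- setdiff(unique(category), tax$category)
  if (length(unknown) > 0) {
    stop_eqa(sprintf("unknown error categor%s: %s",
                     if (length(unknown) > 1) "ies" else "y",
                     paste(unknown, collapse = ", ")), "cd4eqa_taxonomy_error")
  }
  setNames(tax$phase, tax$category)[category]
}

#' Phase distribution of recorded failures
#'
#' Shares each of the three testing phases contributes to a set of error
#' records.  Distributions count records, not laboratories: a failing
#' laboratory may carry several records.
#'
#' @param errors Tibble of error records with a `category` column (phase is
#'   derived) or an explicit `phase` column.
#' @return Tibble with one row per phase (`phase`, `n`, `pct`); `pct` is
#'   `100 * n / total` rounded half-up to one decimal and sums to 100
#'   within rounding.  An empty input yields an empty tibble.
#' @examples
#' recs <- tibble::tibble(category = rep(c("sample_integrity",
#'   "pipetting_error", "transcription_error"), c(35, 154, 11)))
#' phase_distribution(recs)
#' @export
phase_distribution <- function(errors) {
  if (nrow(errors) == 0) {
    return(tibble::tibble(phase = character(), n = integer(), pct = double()))
  }
  phase <- if ("phase" %in% names(errors)) {
    errors$phase
  } else {
    classify_error(errors$category)
  }
  n <- vapply(phase_levels(), function(p) sum(phase == p), integer(1))
  tibble::tibble(
    phase = phase_levels(),
    n = unname(n),
    pct = round_half_up(100 * unname(n) / sum(n), 1)
  )
}

#' Category distribution of recorded failures
#'
#' Counts error records per category across all sessions (the error-type
#' profile a coordinator reviews when planning corrective actions).
#'
#' @inheritParams phase_distribution
#' @return Tibble `category`, `phase`, `n`, `pct` sorted by decreasing `n`.
#' @export
category_distribution <- function(errors) {
  if (nrow(errors) == 0) {
    return(tibble::tibble(category = character(), phase = character(),
                          n = integer(), pct = double()))
  }
  classify_error(errors$category)  # validate
  errors |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(phase = unname(classify_error(.data$category)),
                  pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::select(dplyr::all_of(c("category", "phase", "n", "pct"))) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
}
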