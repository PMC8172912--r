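#' Read per-laboratory panel submissions
#'
#' Reads the comma-delimited submissions file used by the program
#' (one row per laboratory, session and specimen) and validates every row
#' against the domain invariants.  Rows that violate an invariant are
#' dropped with a row-addressed diagnostic; valid rows are kept
#' (partial-load contract), so a single bad laboratory entry never blocks a
#' session.
#'
#' The required header is
#' `session_id,lab_id,instrument,specimen_id,status,unable_reason,receipt_date,analysis_date,cd3_pct,cd3_abs,cd4_pct,cd4_abs,cd8_pct,cd8_abs`.
#' Missing numeric cells are encoded as the empty string (0 is a legal
#' count).  Dates must be ISO-8601 (`YYYY-MM-DD`).  Unknown instrument
#' strings are mapped to `"Other"` with a warning.
#'
#' Row-level invariants:
#' * percent values in \[0, 100\]; absolute counts >= 0;
#' * `status = "reported"` requires at least one value,
#'   `status = "unable_to_report"` requires no values and an
#'   `unable_reason`;
#' * `analysis_date >= receipt_date` when both are present.
#'
#' @param path Path to the submissions file.
#' @return A tibble of validated submissions with typed columns (dates as
#'   `Date`, values as `double`).  The attribute `"rejected"` holds a tibble
#'   (`row`, `lab_id`, `session_id`, `reason`) describing dropped rows; a
#'   message reports the rejected-row count when it is nonzero.
#' @seealso [write_submissions()], [validate_submissions()]
#' @export
parse_submissions <- function(path) {
  raw <- read_schema_file(path, submission_cols(), what = "submissions")
  out <- validate_submissions(raw)
  if (nrow(out$rejected) > 0) {
    inform(sprintf("parse_submissions: rejected %d of %d row(s); see attr(., \"rejected\")",
                   nrow(out$rejected), nrow(raw)))
  }
  structure(out$valid, rejected = out$rejected)
}

# read a delimited file as character columns, enforcing an exact header
read_schema_file <- function(path, expected, what) {
  if (!file.exists(path)) {
    stop_eqa(sprintf("%s file not found: %s", what, path), "cd4eqa_schema_error")
  }
  if (file.size(path) == 0) {
    warn(sprintf("%s file is empty: %s", what, path))
    return(tibble::as_tibble(setNames(rep(list(character()), length(expected)), expected)))
  }
  d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(expected, names(d))
  extra <- setdiff(names(d), expected)
  if (length(missing) > 0) {
    stop_eqa(sprintf("%s file is missing column(s): %s", what,
                     paste(missing, collapse = ", ")), "cd4eqa_schema_error")
  }
  if (length(extra) > 0) {
    stop_eqa(sprintf("%s file has unknown column(s): %s", what,
                     paste(extra, collapse = ", ")), "cd4eqa_schema_error")
  }
  d[expected]
}

#' Validate raw submission rows
#'
#' Applies the row-level invariants of the submission model to a tibble of
#' character (or already-typed) columns.  Used by [parse_submissions()] and
#' directly by tests on in-memory fixtures.
#'
#' @param raw Tibble with the submission schema columns.
#' @return List with `valid` (typed tibble of accepted rows) and `rejected`
#'   (diagnostics tibble: `row`, `lab_id`, `session_id`, `reason`).
#' @export
validate_submissions <- function(raw) {
  n <- nrow(raw)
  empty_rej <- tibble::tibble(row = integer(), lab_id = character(),
                              session_id = character(), reason = character())
  if (n == 0) {
    return(list(valid = type_submissions(raw), rejected = empty_rej))
  }
  raw <- dplyr::mutate(raw, dplyr::across(dplyr::everything(), as.character))
  reasons <- vector("list", n)
  add <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }

  # duplicate keys are a file-level error, not a row rejection
  key <- paste(raw$lab_id, raw$session_id, raw$specimen_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- unique(key[duplicated(key)])
    stop_eqa(sprintf("duplicate (lab_id, session_id, specimen_id) key(s): %s",
                     paste(gsub("\r", "/", head(dup, 5)), collapse = "; ")),
             "cd4eqa_duplicate_key_error")
  }

  for (col in c("session_id", "lab_id", "specimen_id")) {
    add(is.na(raw[[col]]) | raw[[col]] == "", sprintf("missing %s", col))
  }

  status <- raw$status
  add(!status %in% c("reported", "unable_to_report"), "invalid status")

  # instruments: unknown strings fold into Other with a warning
  instr <- raw$instrument
  instr[is.na(instr)] <- ""
  unknown <- !instr %in% instrument_levels() & instr != ""
  if (any(unknown)) {
    warn(sprintf("unknown instrument string(s) mapped to Other: %s",
                 paste(unique(instr[unknown]), collapse = ", ")))
    instr[unknown] <- "Other"
  }
  add(instr == "", "missing instrument")
  raw$instrument <- instr

  # numeric cells: empty string is NA, anything non-numeric is a rejection
  vals <- matrix(NA_real_, n, length(value_cols()),
                 dimnames = list(NULL, value_cols()))
  for (col in value_cols()) {
    x <- raw[[col]]
    blank <- is.na(x) | trimws(x) == ""
    v <- suppressWarnings(as.numeric(x))
    add(!blank & is.na(v), sprintf("%s is not numeric", col))
    vals[, col] <- ifelse(blank, NA_real_, v)
  }
  for (col in c("cd3_pct", "cd4_pct", "cd8_pct")) {
    bad <- !is.na(vals[, col]) & (vals[, col] < 0 | vals[, col] > 100)
    add(bad, sprintf("%s out of [0,100]", col))
  }
  for (col in c("cd3_abs", "cd4_abs", "cd8_abs")) {
    bad <- !is.na(vals[, col]) & vals[, col] < 0
    add(bad, sprintf("%s negative", col))
  }

  any_value <- rowSums(!is.na(vals)) > 0
  reason_given <- !is.na(raw$unable_reason) & raw$unable_reason != ""
  add(status == "reported" & !any_value, "reported with no values")
  add(status == "unable_to_report" & any_value, "unable_to_report with values present")
  add(status == "unable_to_report" & !reason_given, "unable_to_report without unable_reason")
  add(reason_given & !raw$unable_reason %in% unable_reasons(), "unknown unable_reason")

  rd <- parse_iso_date(raw$receipt_date)
  ad <- parse_iso_date(raw$analysis_date)
  add(!rd$ok, "receipt_date is not ISO-8601")
  add(!ad$ok, "analysis_date is not ISO-8601")
  both <- !is.na(rd$date) & !is.na(ad$date)
  add(both & ad$date < rd$date, "analysis_date before receipt_date")

  bad <- !vapply(reasons, is.null, logical(1))
  rejected <- tibble::tibble(
    row = which(bad),
    lab_id = raw$lab_id[bad],
    session_id = raw$session_id[bad],
    reason = vapply(reasons[bad], paste, character(1), collapse = "; ")
  )

  typed <- raw
  for (col in value_cols()) typed[[col]] <- vals[, col]
  typed$receipt_date <- rd$date
  typed$analysis_date <- ad$date
  typed$unable_reason <- ifelse(reason_given, raw$unable_reason, NA_character_)
  list(valid = tibble::as_tibble(typed[!bad, ]), rejected = rejected)
}

# coerce an empty raw frame to the typed submission schema
type_submissions <- function(raw) {
  out <- tibble::as_tibble(raw)
  for (col in value_cols()) out[[col]] <- as.numeric(out[[col]])
  out$receipt_date <- as.Date(out$receipt_date)
  out$analysis_date <- as.Date(out$analysis_date)
  out
}

#' Write submissions back to the delimited schema
#'
#' Inverse of [parse_submissions()]: dates are written as ISO-8601 and
#' missing cells as empty strings, so a parse/write cycle reproduces the
#' file content field for field.
#'
#' @param submissions Tibble of validated submissions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_submissions <- function(submissions, path) {
  readr::write_csv(submissions[submission_cols()], path, na = "")
  invisible(path)
}

#' Read a panel manifest
#'
#' The manifest lists the specimens shipped in each session
#' (`session_id,specimen_id,level`).  Every session must contain exactly two
#' specimens, one `low` and one `mid` CD4 level.
#'
#' @param path Path to the manifest file.
#' @return Tibble with columns `session_id`, `specimen_id`, `level`.
#' @export
parse_panel_manifest <- function(path) {
  d <- read_schema_file(path, c("session_id", "specimen_id", "level"),
                        what = "manifest")
  if (nrow(d) == 0) {
    return(d)
  }
  bad_level <- !d$level %in% specimen_levels()
  if (any(bad_level)) {
    stop_eqa(sprintf("manifest has invalid level value(s): %s",
                     paste(unique(d$level[bad_level]), collapse = ", ")),
             "cd4eqa_manifest_error")
  }
  if (anyDuplicated(paste(d$session_id, d$specimen_id)) > 0) {
    stop_eqa("manifest has duplicate specimen_id within a session",
             "cd4eqa_manifest_error")
  }
  chk <- dplyr::summarise(
    dplyr::group_by(d, .data$session_id),
    n = dplyr::n(),
    n_low = sum(.data$level == "low"),
    n_mid = sum(.data$level == "mid"),
    .groups = "drop"
  )
  bad <- chk$n != 2 | chk$n_low != 1 | chk$n_mid != 1
  if (any(bad)) {
    stop_eqa(sprintf(
      "manifest session(s) without exactly one low and one mid specimen: %s",
      paste(chk$session_id[bad], collapse = ", ")), "cd4eqa_manifest_error")
  }
  d
}

#' @rdname parse_panel_manifest
#' @param manifest Tibble of specimens.
#' @export
write_panel_manifest <- function(manifest, path) {
  readr::write_csv(manifest[c("session_id", "specimen_id", "level")], path, na = "")
  invisible(path)
}

#' Read a coordinator error log
#'
#' Error records are coordinator-entered annotations attached to failing
#' laboratories (`session_id,lab_id,category,note`).  The analysis phase of
#' each record is always derived from its category via [classify_error()],
#' never stored.
#'
#' @param path Path to the error-log file.
#' @return Tibble with columns `session_id`, `lab_id`, `category`, `note`
#'   plus a derived `phase` column.
#' @export
parse_error_log <- function(path) {
  d <- read_schema_file(path, c("session_id", "lab_id", "category", "note"),
                        what = "error log")
  if (nrow(d) > 0) {
    d$phase <- classify_error(d$category)  # errors on unknown categories
  } else {
    d$phase <- character()
  }
  d
}

#' @rdname parse_error_log
#' @param errors Tibble of error records.
#' @export
write_error_log <- function(errors, path) {
  readr::write_csv(errors[c("session_id", "lab_id", "category", "note")], path, na = "")
  invisible(path)
}

#' Pivot submissions to one row per measured quantity
#'
#' Reshapes reported submissions from the wide file schema to a long table
#' with one row per (lab, specimen, marker, value kind) measurement,
#' dropping cells the laboratory did not report.
#'
#' @param submissions Tibble of validated submissions.
#' @param manifest Optional manifest tibble; when given, the specimen CD4
#'   `level` is joined on.
#' @return Long tibble with columns `session_id`, `lab_id`, `instrument`,
#'   `specimen_id`, (`level`,) `marker`, `value_kind`, `reported_value`.
#' @export
submissions_long <- function(submissions, manifest = NULL) {
  long <- submissions |>
    dplyr::filter(.data$status == "reported") |>
    dplyr::select(dplyr::all_of(c("session_id", "lab_id", "instrument",
                                  "specimen_id", value_cols()))) |>
    tidyr::pivot_longer(dplyr::all_of(value_cols()),
                        names_to = c("marker", "value_kind"), names_sep = "_",
                        values_to = "reported_value") |>
    dplyr::mutate(
      marker = toupper(.data$marker),
      value_kind = c(pct = "percent", abs = "absolute")[.data$value_kind]
    ) |>
    dplyr::filter(!is.na(.data$reported_value))
  if (!is.null(manifest)) {
    long <- dplyr::left_join(long, manifest[c("specimen_id", "level")],
                             by = "specimen_id")
  }
  long
}
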