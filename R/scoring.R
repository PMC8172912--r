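#' Scoring configuration
#'
#' Parameters of the consensus/SDI scoring rule.
#'
#' @param outlier_k Trimming threshold in SD units: values deviating from
#'   the group mean by strictly more than `outlier_k` SD are excluded from
#'   the consensus (default 2; the boundary value exactly at `k` SD is
#'   retained).
#' @param pass_limit Pass criterion in SDI units: a score is within limit
#'   when `|SDI| <= pass_limit` (default 2; the boundary passes).
#' @param min_group_n Minimum number of reported values for a quantity to be
#'   scoreable (default 3).
#' @param trim_passes Number of compute/exclude/recompute trimming passes
#'   (default 1: the consensus is recalculated once after exclusion).
#' @param by_instrument Logical; if `TRUE`, consensus groups are stratified
#'   by instrument class (peer-group scoring) instead of pooling all
#'   technologies (default `FALSE`, the program's pooled rule).
#' @return A list of class `"scoring_config"`.
#' @export
scoring_config <- function(outlier_k = 2, pass_limit = 2, min_group_n = 3,
                           trim_passes = 1, by_instrument = FALSE) {
  stopifnot(
    is.numeric(outlier_k), length(outlier_k) == 1, outlier_k > 0,
    is.numeric(pass_limit), length(pass_limit) == 1, pass_limit > 0,
    is.numeric(min_group_n), length(min_group_n) == 1, min_group_n >= 2,
    min_group_n == as.integer(min_group_n),
    is.numeric(trim_passes), length(trim_passes) == 1, trim_passes >= 1,
    is.logical(by_instrument), length(by_instrument) == 1
  )
  structure(
    list(outlier_k = outlier_k, pass_limit = pass_limit,
         min_group_n = as.integer(min_group_n),
         trim_passes = as.integer(trim_passes),
         by_instrument = by_instrument),
    class = "scoring_config"
  )
}

#' Trimmed consensus statistics for one quantity
#'
#' Computes the consensus (aggregate) mean and SD for one measured quantity
#' across laboratories: the mean and sample SD of all values are computed,
#' values deviating from that mean by more than `outlier_k` SD are marked as
#' outliers and excluded, and the mean and SD are recalculated on the
#' remainder (`trim_passes` times; once by default).  The sample SD
#' (n − 1 denominator) is used throughout.  A trimming pass that would
#' leave fewer than `min_group_n` values is not applied.
#'
#' @param values Numeric vector of reported values for one
#'   (session, specimen, marker, value-kind) group.
#' @param lab_ids Optional character vector of laboratory ids parallel to
#'   `values` (used to report which laboratories were trimmed).
#' @param config A [scoring_config()].
#' @return A list of class `"eqa_aggregate"` with `n_initial`, `n_outliers`,
#'   `trimmed_mean`, `trimmed_sd`, `outlier_lab_ids`, `retained_lab_ids`
#'   and the logical vector `retained` parallel to the input.
#' @examples
#' compute_trimmed_aggregate(c(500, 510, 490, 505, 495, 1200))
#' @export
compute_trimmed_aggregate <- function(values, lab_ids = NULL,
                                      config = scoring_config()) {
  stopifnot(is.numeric(values), inherits(config, "scoring_config"))
  if (anyNA(values)) stop_eqa("values must not contain NA", "cd4eqa_value_error")
  n <- length(values)
  if (is.null(lab_ids)) lab_ids <- sprintf("value_%d", seq_len(n))
  stopifnot(length(lab_ids) == n)
  if (n < config$min_group_n) {
    stop_eqa(sprintf("insufficient group: %d value(s), need at least %d",
                     n, config$min_group_n), "cd4eqa_insufficient_group")
  }

  keep <- rep(TRUE, n)
  for (pass in seq_len(config$trim_passes)) {
    m <- mean(values[keep])
    s <- sd(values[keep])
    if (!is.finite(s) || s == 0) break
    flag <- keep & abs(values - m) > config$outlier_k * s
    if (!any(flag)) break
    if (sum(keep) - sum(flag) < config$min_group_n) break
    keep <- keep & !flag
  }

  structure(
    list(
      n_initial = n,
      n_outliers = sum(!keep),
      trimmed_mean = mean(values[keep]),
      trimmed_sd = sd(values[keep]),
      outlier_lab_ids = sort(lab_ids[!keep]),
      retained_lab_ids = sort(lab_ids[keep]),
      retained = keep
    ),
    class = "eqa_aggregate"
  )
}

#' @export
print.eqa_aggregate <- function(x, ...) {
  cat(sprintf("Trimmed consensus: mean %.4g, SD %.4g (n = %d, %d outlier(s) excluded)\n",
              x$trimmed_mean, x$trimmed_sd, x$n_initial - x$n_outliers,
              x$n_outliers))
  if (x$n_outliers > 0) {
    cat("  outliers:", paste(x$outlier_lab_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standard Deviation Index of reported values
#'
#' The SDI of a reported value is its residual from the consensus mean
#' divided by the consensus SD; its sign indicates whether the laboratory
#' reported above (+) or below (−) the group.  A score is within limit when
#' `|SDI| <= pass_limit`.  When the consensus SD is 0 (unanimous group) the
#' SDI is 0 for an exact match and a signed infinity otherwise, which is
#' out of limit: any deviation from a unanimous consensus fails.
#'
#' @param reported_value Numeric vector of reported values.
#' @param agg An `"eqa_aggregate"` from [compute_trimmed_aggregate()].
#' @param config A [scoring_config()].
#' @param lab_ids Optional character vector parallel to `reported_value`.
#' @return Tibble with columns `lab_id`, `reported_value`, `residual`,
#'   `sdi`, `within_limit`.
#' @examples
#' agg <- compute_trimmed_aggregate(c(500, 510, 490, 505, 495, 1200))
#' compute_sdi(c(500, 516, 524), agg)
#' @export
compute_sdi <- function(reported_value, agg, config = scoring_config(),
                        lab_ids = NULL) {
  stopifnot(inherits(agg, "eqa_aggregate"), inherits(config, "scoring_config"))
  residual <- reported_value - agg$trimmed_mean
  if (agg$trimmed_sd > 0) {
    sdi <- residual / agg$trimmed_sd
  } else {
    sdi <- ifelse(residual == 0, 0, sign(residual) * Inf)
  }
  tibble::tibble(
    lab_id = lab_ids %||% sprintf("value_%d", seq_along(reported_value)),
    reported_value = reported_value,
    residual = residual,
    sdi = sdi,
    within_limit = abs(sdi) <= config$pass_limit
  )
}

#' Adjudicate one laboratory's session outcome
#'
#' Combines a laboratory's SDI scores over both panel specimens into a
#' single verdict: `unable_to_report` if the laboratory returned no result,
#' `fail` if any scored quantity is out of limit (the failing quantities
#' are listed), otherwise `pass`.  Quantities the laboratory did not report
#' (e.g. percent values on a point-of-care counter) are not held against
#' it; a `pass` requires a reported result for both specimens.  A
#' laboratory whose only reported quantities were unscoreable (group below
#' `min_group_n`) passes with the note `"unscored"`.
#'
#' @param lab_submissions Submission rows for one laboratory and session.
#' @param scores Tibble of this laboratory's SDI scores (columns as emitted
#'   by [score_session()]: `specimen_id`, `level`, `marker`, `value_kind`,
#'   `sdi`, `within_limit`, `scoreable`).
#' @param config A [scoring_config()].
#' @param n_specimens Number of specimens in the session panel (default 2).
#' @param lab_long Optional pre-computed [submissions_long()] rows for this
#'   laboratory (avoids re-pivoting when called in a loop).
#' @return One-row tibble: `session_id`, `lab_id`, `instrument`, `outcome`,
#'   `n_scored`, `failing_quantities` (`;`-joined `level.marker.kind`
#'   labels, sorted), `notes`.
#' @export
adjudicate_lab <- function(lab_submissions, scores, config = scoring_config(),
                           n_specimens = 2, lab_long = NULL) {
  stopifnot(nrow(lab_submissions) >= 1,
            length(unique(lab_submissions$lab_id)) == 1,
            length(unique(lab_submissions$session_id)) == 1)
  lab <- lab_submissions$lab_id[1]
  session <- lab_submissions$session_id[1]
  instrument <- lab_submissions$instrument[1]
  reported <- lab_submissions[lab_submissions$status == "reported", ]

  if (nrow(scores) > 0) {
    long <- lab_long %||% submissions_long(lab_submissions)
    have <- paste(long$specimen_id, long$marker, long$value_kind)
    want <- paste(scores$specimen_id, scores$marker, scores$value_kind)
    if (!all(want %in% have)) {
      stop_eqa(sprintf(
        "scores for lab %s reference quantities it never reported", lab),
        "cd4eqa_consistency_error")
    }
  }

  if (nrow(reported) == 0) {
    outcome <- "unable_to_report"
    failing <- character(0)
    reasons <- unique(lab_submissions$unable_reason)
    notes <- paste(reasons[!is.na(reasons)], collapse = ";")
    n_scored <- 0L
  } else {
    if (!"scoreable" %in% names(scores)) scores$scoreable <- TRUE
    scored <- scores[scores$scoreable, ]
    n_scored <- nrow(scored)
    bad <- scored[!scored$within_limit, ]
    failing <- sort(quantity_label(bad$level, bad$marker, bad$value_kind))
    notes <- ""
    if (nrow(reported) < n_specimens) {
      outcome <- "fail"
      notes <- "incomplete_panel"
    } else if (length(failing) > 0) {
      outcome <- "fail"
    } else {
      outcome <- "pass"
      if (n_scored == 0) notes <- "unscored"
    }
  }

  tibble::tibble(
    session_id = session, lab_id = lab, instrument = instrument,
    outcome = outcome, n_scored = as.integer(n_scored),
    failing_quantities = paste(failing, collapse = ";"),
    notes = notes
  )
}

#' Score one EQA session
#'
#' Runs the full scoring rule for one session: for every
#' (specimen, marker, value-kind) group with at least `min_group_n`
#' reported values, the trimmed consensus is computed and every reporting
#' laboratory — including those excluded from the consensus as outliers —
#' receives an SDI against it; every registered laboratory is then
#' adjudicated.  Groups below `min_group_n` are flagged unscoreable rather
#' than scored against a tiny consensus.
#'
#' @param submissions Validated submissions for exactly one session.
#' @param manifest Panel manifest covering the session.
#' @param config A [scoring_config()].
#' @return List of class `"eqa_session_result"` with tibbles `aggregates`
#'   (one row per scoreable quantity), `scores` (one row per laboratory and
#'   quantity, including unscoreable ones with `scoreable = FALSE`) and
#'   `verdicts` (one row per registered laboratory).
#' @export
score_session <- function(submissions, manifest, config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  session <- unique(submissions$session_id)
  if (length(session) != 1) {
    stop_eqa("score_session expects submissions for exactly one session",
             "cd4eqa_consistency_error")
  }
  man <- manifest[manifest$session_id == session, ]
  if (nrow(man) == 0) {
    stop_eqa(sprintf("manifest does not cover session %s", session),
             "cd4eqa_manifest_error")
  }
  unknown_spec <- setdiff(unique(submissions$specimen_id), man$specimen_id)
  if (length(unknown_spec) > 0) {
    stop_eqa(sprintf("submissions reference specimen(s) not in manifest: %s",
                     paste(unknown_spec, collapse = ", ")),
             "cd4eqa_manifest_error")
  }

  long <- submissions_long(submissions, man)
  grp_vars <- c("specimen_id", "level", "marker", "value_kind")
  if (config$by_instrument) grp_vars <- c(grp_vars, "instrument")

  groups <- dplyr::group_split(dplyr::group_by(
    long, dplyr::across(dplyr::all_of(grp_vars))))

  agg_rows <- list()
  score_rows <- list()
  for (g in groups) {
    key <- g[1, grp_vars]
    if (nrow(g) < config$min_group_n) {
      score_rows[[length(score_rows) + 1]] <- dplyr::mutate(
        g, trimmed_mean = NA_real_, trimmed_sd = NA_real_,
        residual = NA_real_, sdi = NA_real_, within_limit = NA,
        is_outlier = NA, scoreable = FALSE)
      next
    }
    agg <- compute_trimmed_aggregate(g$reported_value, g$lab_id, config)
    agg_rows[[length(agg_rows) + 1]] <- tibble::tibble(
      session_id = session, key,
      n_initial = agg$n_initial, n_outliers = agg$n_outliers,
      trimmed_mean = agg$trimmed_mean, trimmed_sd = agg$trimmed_sd,
      outlier_lab_ids = paste(agg$outlier_lab_ids, collapse = ";"))
    sc <- compute_sdi(g$reported_value, agg, config, lab_ids = g$lab_id)
    score_rows[[length(score_rows) + 1]] <- dplyr::mutate(
      g, trimmed_mean = agg$trimmed_mean, trimmed_sd = agg$trimmed_sd,
      residual = sc$residual, sdi = sc$sdi,
      within_limit = sc$within_limit, is_outlier = !agg$retained,
      scoreable = TRUE)
  }

  aggregates <- if (length(agg_rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(agg_rows), .data$specimen_id,
                   .data$marker, .data$value_kind)
  } else {
    tibble::tibble(session_id = character(), specimen_id = character(),
                   level = character(), marker = character(),
                   value_kind = character(), n_initial = integer(),
                   n_outliers = integer(), trimmed_mean = double(),
                   trimmed_sd = double(), outlier_lab_ids = character())
  }
  scores <- if (length(score_rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(score_rows), .data$specimen_id,
                   .data$marker, .data$value_kind, .data$lab_id)
  } else {
    long
  }

  verdicts <- submissions |>
    dplyr::arrange(.data$lab_id) |>
    dplyr::group_split(.data$lab_id) |>
    purrr::map(function(sub_lab) {
      lab <- sub_lab$lab_id[1]
      adjudicate_lab(sub_lab, scores[scores$lab_id == lab, , drop = FALSE],
                     config, n_specimens = nrow(man),
                     lab_long = long[long$lab_id == lab, , drop = FALSE])
    }) |>
    dplyr::bind_rows()

  structure(list(aggregates = aggregates, scores = scores,
                 verdicts = verdicts, session_id = session),
            class = "eqa_session_result")
}

#' Score every session of a program
#'
#' Applies [score_session()] to each session present in the submissions and
#' row-binds the results.
#'
#' @param submissions Validated submissions (any number of sessions).
#' @param manifest Panel manifest covering all sessions.
#' @param config A [scoring_config()].
#' @return List with tibbles `aggregates`, `scores`, `verdicts` spanning all
#'   sessions, plus `sessions`, the list of per-session
#'   `"eqa_session_result"` objects keyed by session id.
#' @export
score_program <- function(submissions, manifest, config = scoring_config()) {
  ids <- sort(unique(submissions$session_id))
  sessions <- lapply(ids, function(sid) {
    score_session(submissions[submissions$session_id == sid, ], manifest, config)
  })
  names(sessions) <- ids
  list(
    aggregates = dplyr::bind_rows(lapply(sessions, `[[`, "aggregates")),
    scores = dplyr::bind_rows(lapply(sessions, `[[`, "scores")),
    verdicts = dplyr::bind_rows(lapply(sessions, `[[`, "verdicts")),
    sessions = sessions
  )
}
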