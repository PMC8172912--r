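#' Default panel nominal values
#'
#' Declared nominal (true) values for the two panel specimens: a low-CD4
#' specimen (~150 CD4 cells/µL, advanced immunosuppression) and a mid-CD4
#' specimen (~500 cells/µL), with plausible fixed CD3/CD8 companions
#' satisfying CD3 >= CD4 on both scales.  These are invented defaults — the
#' program's true panel targets are not public — and every value can be
#' overridden in [synthetic_config()].
#'
#' @return Tibble `level`, `marker`, `value_kind`, `nominal`.
#' @export
default_nominals <- function() {
  tibble::tribble(
    ~level, ~marker, ~value_kind, ~nominal,
    "low", "CD3", "percent",   72,
    "low", "CD3", "absolute", 1100,
    "low", "CD4", "percent",   12,
    "low", "CD4", "absolute",  150,
    "low", "CD8", "percent",   55,
    "low", "CD8", "absolute",  850,
    "mid", "CD3", "percent",   75,
    "mid", "CD3", "absolute", 1400,
    "mid", "CD4", "percent",   30,
    "mid", "CD4", "absolute",  500,
    "mid", "CD8", "percent",   40,
    "mid", "CD8", "absolute",  750
  )
}

#' Configuration of the synthetic EQA program generator
#'
#' Defines a multi-session EQA program with known ground truth.  Each
#' reporting laboratory draws every value as
#' `nominal * (1 + bias) * (1 + eps)`, `eps ~ Normal(0, cv)`, where the
#' laboratory's systematic bias is its persistent base bias (sampled once
#' per laboratory from `Normal(0, bias_sd)`, or injected via
#' `bias_overrides`) plus the mean bias of the instrument it used.  With
#' probability `p_unable` a laboratory registers but returns no result;
#' with probability `p_error` a reporting laboratory commits one injected
#' error whose phase is drawn from `phase_mix`:
#' * pre-analytical — both specimens' values are degraded by
#'   `error_magnitude` (sample-integrity surrogate);
#' * analytical — one quantity is perturbed by `error_magnitude`
#'   (pipetting/gating surrogate);
#' * post-analytical — two reported values are swapped, or a digit is
#'   dropped from an absolute count (transcription surrogate).
#'
#' Absolute counts are clamped at 0, percents to \[0, 100\], and
#' CD3 >= CD4 is enforced at generation (before error injection).
#'
#' @param n_sessions Number of sessions.
#' @param labs_per_session Registered laboratories per session (scalar or
#'   length `n_sessions` growth schedule).
#' @param instrument_mix Per-session proportions over the four instrument
#'   classes: numeric length-4 vector or an `n_sessions` x 4 matrix with
#'   columns FACSCount, CyFlow, PIMA, Other.  Rows are normalised to 1.
#' @param nominal_values Tibble as [default_nominals()].
#' @param instrument_cv Named coefficient of variation (fraction) per
#'   instrument class.
#' @param instrument_bias Named mean systematic bias (fraction) per
#'   instrument class.
#' @param bias_sd SD of the per-laboratory base bias (fraction of nominal).
#' @param noise_cor Fraction of the within-laboratory noise variance shared
#'   across all quantities of a session (same operator, calibration and
#'   reagent batch drive all twelve results of a run); the remainder is
#'   independent per quantity.  In `[0, 1]`, default 0.7.
#' @param bias_overrides Optional named numeric vector `lab_id -> bias`
#'   replacing the sampled base bias for those laboratories (set 0 to force
#'   a clean laboratory, or e.g. 0.30 to inject a miscalibrated one).
#' @param p_unable Probability a registered laboratory is unable to report
#'   (scalar or per-session vector).
#' @param p_error Probability a reporting laboratory commits one injected
#'   error (scalar or per-session vector).
#' @param phase_mix Probabilities of the three phases for injected errors,
#'   in order (pre-analytical, analytical, post-analytical); must sum to 1.
#' @param error_magnitude Multiplier applied to the value(s) affected by a
#'   pre-analytical or analytical error (default 0.6: the value drops to
#'   60\% of what the laboratory would otherwise have reported).
#' @param seed Integer seed; the generator derives an independent
#'   sub-stream per session, so regenerating any one session is
#'   reproducible in isolation.
#' @param start_date Receipt date of the first session; sessions are 122
#'   days apart (three per year).
#' @return A validated list of class `"synthetic_config"`.
#' @seealso [cameroon_program_config()] for the defaults anchored to the
#'   Cameroon national program.
#' @export
synthetic_config <- function(n_sessions = 3,
                             labs_per_session = 30,
                             instrument_mix = c(FACSCount = 0.25, CyFlow = 0.2,
                                                PIMA = 0.45, Other = 0.1),
                             nominal_values = default_nominals(),
                             instrument_cv = c(FACSCount = 0.015,
                                               CyFlow = 0.025,
                                               PIMA = 0.02, Other = 0.02),
                             instrument_bias = c(FACSCount = 0, CyFlow = 0.02,
                                                 PIMA = -0.02, Other = 0),
                             bias_sd = 0.08,
                             noise_cor = 0.7,
                             bias_overrides = NULL,
                             p_unable = 0.05,
                             p_error = 0.15,
                             phase_mix = c(pre_analytical = 0.175,
                                           analytical = 0.770,
                                           post_analytical = 0.055),
                             error_magnitude = 0.6,
                             seed = 48,
                             start_date = as.Date("2014-06-01")) {
  cfg_err <- function(msg) stop_eqa(msg, "cd4eqa_config_error")
  if (!(is.numeric(n_sessions) && length(n_sessions) == 1 && n_sessions >= 1)) {
    cfg_err("n_sessions must be a positive integer")
  }
  n_sessions <- as.integer(n_sessions)

  recycle <- function(x, nm) {
    if (length(x) == 1) x <- rep(x, n_sessions)
    if (length(x) != n_sessions) {
      cfg_err(sprintf("%s must have length 1 or n_sessions (%d)", nm, n_sessions))
    }
    x
  }
  labs_per_session <- recycle(labs_per_session, "labs_per_session")
  if (any(labs_per_session < 1)) cfg_err("labs_per_session must be positive")
  labs_per_session <- as.integer(labs_per_session)
  p_unable <- recycle(p_unable, "p_unable")
  p_error <- recycle(p_error, "p_error")
  if (any(p_unable < 0 | p_unable > 1) || any(p_error < 0 | p_error > 1)) {
    cfg_err("p_unable and p_error must be probabilities in [0,1]")
  }

  if (is.numeric(instrument_mix) && is.null(dim(instrument_mix))) {
    instrument_mix <- matrix(instrument_mix, n_sessions, 4, byrow = TRUE,
                             dimnames = list(NULL, instrument_levels()))
  }
  instrument_mix <- as.matrix(instrument_mix)
  if (nrow(instrument_mix) != n_sessions || ncol(instrument_mix) != 4) {
    cfg_err("instrument_mix must be a length-4 vector or n_sessions x 4 matrix")
  }
  colnames(instrument_mix) <- instrument_levels()
  if (any(instrument_mix < 0) || any(rowSums(instrument_mix) <= 0)) {
    cfg_err("instrument_mix proportions must be non-negative with positive row sums")
  }
  instrument_mix <- instrument_mix / rowSums(instrument_mix)

  needed <- c("level", "marker", "value_kind", "nominal")
  if (!all(needed %in% names(nominal_values)) || nrow(nominal_values) != 12) {
    cfg_err("nominal_values must have 12 rows (2 levels x 3 markers x 2 kinds)")
  }
  nv <- nominal_values
  cd4 <- function(lv) nv$nominal[nv$level == lv & nv$marker == "CD4" &
                                   nv$value_kind == "absolute"]
  if (!(cd4("low") < cd4("mid"))) cfg_err("nominal CD4 low must be below CD4 mid")

  for (nm in c("instrument_cv", "instrument_bias")) {
    x <- get(nm)
    if (!all(instrument_levels() %in% names(x))) {
      cfg_err(sprintf("%s must be named for all instrument classes", nm))
    }
  }
  if (any(instrument_cv < 0)) cfg_err("instrument_cv must be non-negative")
  if (!(is.numeric(noise_cor) && length(noise_cor) == 1 &&
        noise_cor >= 0 && noise_cor <= 1)) {
    cfg_err("noise_cor must be in [0,1]")
  }
  if (!(length(phase_mix) == 3 && all(phase_mix >= 0) &&
        abs(sum(phase_mix) - 1) < 1e-8)) {
    cfg_err("phase_mix must be 3 probabilities summing to 1")
  }
  names(phase_mix) <- phase_levels()
  if (!(is.numeric(error_magnitude) && error_magnitude > 0)) {
    cfg_err("error_magnitude must be positive")
  }
  if (!(is.numeric(seed) && length(seed) == 1 && is.finite(seed))) {
    cfg_err("seed must be a finite number")
  }
  if (!is.null(bias_overrides) &&
      (is.null(names(bias_overrides)) || !is.numeric(bias_overrides))) {
    cfg_err("bias_overrides must be a named numeric vector")
  }

  structure(
    list(n_sessions = n_sessions, labs_per_session = labs_per_session,
         instrument_mix = instrument_mix, nominal_values = nv,
         instrument_cv = instrument_cv[instrument_levels()],
         instrument_bias = instrument_bias[instrument_levels()],
         bias_sd = bias_sd, noise_cor = noise_cor,
         bias_overrides = bias_overrides,
         p_unable = p_unable, p_error = p_error, phase_mix = phase_mix,
         error_magnitude = error_magnitude, seed = seed,
         start_date = as.Date(start_date)),
    class = "synthetic_config"
  )
}

#' Generator configuration anchored to the Cameroon program
#'
#' [synthetic_config()] preset emulating the eleven evaluated sessions of
#' the Cameroon national program: the registrant schedule and per-session
#' instrument mix are derived from the published session counts
#' ([cameroon_session_counts()]); unable-to-report probability is elevated
#' in sessions 7–8 (the reagent-stockout sessions); the injected-error
#' probability declines as the published failure rate declines (the
#' corrective-action effect), floored at 3\% above the ~7\% failure
#' baseline that the bias distribution itself produces.
#'
#' @param seed Integer seed.
#' @param ... Further arguments passed to [synthetic_config()] to override
#'   individual defaults.
#' @return A `"synthetic_config"` for 11 sessions.
#' @export
cameroon_program_config <- function(seed = 48, ...) {
  counts <- cameroon_session_counts()
  per_session <- counts |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(n_reported = sum(.data$n_reported),
                     n_fail = sum(.data$n_fail), .groups = "drop") |>
    dplyr::arrange(.data$session_id)
  mix <- counts |>
    tidyr::pivot_wider(id_cols = "session_id", names_from = "instrument",
                       values_from = "n_reported", values_fill = 0L) |>
    dplyr::arrange(.data$session_id)
  mix <- as.matrix(mix[instrument_levels()])
  p_unable <- rep(0.05, 11)
  p_unable[7:8] <- c(0.30, 0.20)  # stockout sessions
  fail_rate <- per_session$n_fail / per_session$n_reported
  # the bias distribution alone fails ~10% of reporting labs; the injected
  # transient-error probability accounts for the failure rate beyond that
  baseline <- 0.10
  args <- list(
    n_sessions = 11,
    labs_per_session = round(per_session$n_reported / (1 - p_unable)),
    instrument_mix = mix,
    p_unable = p_unable,
    p_error = pmax(0.02, (fail_rate - baseline) / (1 - baseline)),
    seed = seed
  )
  override <- list(...)
  do.call(synthetic_config, utils::modifyList(args, override))
}

# deterministic per-session sub-seed (kept well below 2^31)
session_seed <- function(seed, i) {
  as.integer((abs(seed) %% 499979) * 4001 + i * 101 + 7)
}

session_ids <- function(config) sprintf("S%02d", seq_len(config$n_sessions))

#' Panel manifest of a synthetic program
#' @param config A [synthetic_config()].
#' @return Manifest tibble (`session_id`, `specimen_id`, `level`), two
#'   specimens (one low, one mid) per session.
#' @export
synthetic_manifest <- function(config) {
  sid <- session_ids(config)
  tibble::tibble(
    session_id = rep(sid, each = 2),
    specimen_id = paste0(rep(sid, each = 2), c("-LOW", "-MID")),
    level = rep(c("low", "mid"), length(sid))
  )
}

# persistent per-laboratory base biases for the whole roster, drawn from a
# normal truncated at +/-2 SD: gross persistent miscalibration does not
# survive in a program with corrective action, so the persistent-bias
# distribution is bounded while transient gross errors are injected
# separately via p_error
lab_base_biases <- function(config) {
  n_max <- max(config$labs_per_session)
  set.seed(session_seed(config$seed, 0L))
  u <- runif(n_max, stats::pnorm(-2), stats::pnorm(2))
  b <- stats::qnorm(u) * config$bias_sd
  names(b) <- sprintf("LAB%03d", seq_len(n_max))
  ov <- config$bias_overrides
  if (!is.null(ov)) b[names(ov)[names(ov) %in% names(b)]] <-
      ov[names(ov) %in% names(b)]
  b
}

#' Generate one synthetic EQA session
#'
#' @param config A [synthetic_config()].
#' @param session_index Session number in `1:n_sessions`.
#' @return List with `submissions` (wide schema tibble, valid under
#'   [validate_submissions()]), `ground_truth` (per laboratory: bias,
#'   unable flag, injected error phase/category and affected quantities)
#'   and `errors` (error-log rows for the injected errors).
#' @export
generate_session <- function(config, session_index) {
  stopifnot(inherits(config, "synthetic_config"))
  i <- as.integer(session_index)
  if (i < 1 || i > config$n_sessions) {
    stop_eqa("session_index out of range", "cd4eqa_config_error")
  }
  sid <- session_ids(config)[i]
  n <- config$labs_per_session[i]
  lab_ids <- sprintf("LAB%03d", seq_len(n))
  base_bias <- lab_base_biases(config)[lab_ids]

  nv <- config$nominal_values
  qty <- quantity_label(nv$level, nv$marker, nv$value_kind)
  nominal <- setNames(nv$nominal, qty)

  set.seed(session_seed(config$seed, i))
  instrument <- sample(instrument_levels(), n, replace = TRUE,
                       prob = config$instrument_mix[i, ])
  bias <- unname(base_bias) + unname(config$instrument_bias[instrument])
  unable <- runif(n) < config$p_unable[i]
  reason <- sample(setdiff(unable_reasons(), "other"), n, replace = TRUE)
  cv <- unname(config$instrument_cv[instrument])
  shared <- rnorm(n) * sqrt(config$noise_cor)
  eps <- (shared + matrix(rnorm(n * 12), n, 12) *
            sqrt(1 - config$noise_cor)) * cv
  values <- outer(1 + bias, nominal) * (1 + eps)
  colnames(values) <- qty

  # physiological consistency before error injection: CD3 >= CD4
  for (lv in c("low", "mid")) for (vk in c("percent", "absolute")) {
    c3 <- quantity_label(lv, "CD3", vk); c4 <- quantity_label(lv, "CD4", vk)
    values[, c3] <- pmax(values[, c3], values[, c4])
  }
  values <- clamp_values(values, qty)

  has_error <- !unable & runif(n) < config$p_error[i]
  phase <- sample(phase_levels(), n, replace = TRUE, prob = config$phase_mix)
  tax <- error_taxonomy()
  category <- rep(NA_character_, n)
  affected <- rep(NA_character_, n)
  for (j in which(has_error)) {
    category[j] <- sample(tax$category[tax$phase == phase[j]], 1)
    if (phase[j] == "pre_analytical") {
      values[j, ] <- values[j, ] * config$error_magnitude
      affected[j] <- paste(qty, collapse = ";")
    } else if (phase[j] == "analytical") {
      q <- sample(qty, 1)
      values[j, q] <- values[j, q] * config$error_magnitude
      affected[j] <- q
    } else {
      if (runif(1) < 0.5) {
        lv <- sample(c("low", "mid"), 1)
        vk <- sample(c("percent", "absolute"), 1)
        mk <- sample(markers(), 2)
        q2 <- quantity_label(lv, mk, vk)
        values[j, q2] <- values[j, rev(q2)]
        affected[j] <- paste(sort(q2), collapse = ";")
      } else {
        q <- sample(qty[endsWith(qty, "absolute")], 1)
        values[j, q] <- floor(values[j, q] / 10)
        affected[j] <- q
      }
    }
  }
  values <- clamp_values(values, qty)

  receipt <- config$start_date + (i - 1) * 122
  analysis <- receipt + sample(1:7, n, replace = TRUE)

  man <- synthetic_manifest(config)
  man <- man[man$session_id == sid, ]
  spec_of <- setNames(man$specimen_id, man$level)

  rows <- lapply(c("low", "mid"), function(lv) {
    cols <- quantity_label(
      lv, rep(markers(), each = 2), rep(c("percent", "absolute"), 3))
    v <- values[, cols, drop = FALSE]
    tibble::tibble(
      session_id = sid, lab_id = lab_ids, instrument = instrument,
      specimen_id = unname(spec_of[lv]),
      status = ifelse(unable, "unable_to_report", "reported"),
      unable_reason = ifelse(unable, reason, NA_character_),
      receipt_date = receipt, analysis_date = analysis,
      cd3_pct = ifelse(unable, NA_real_, v[, 1]),
      cd3_abs = ifelse(unable, NA_real_, v[, 2]),
      cd4_pct = ifelse(unable, NA_real_, v[, 3]),
      cd4_abs = ifelse(unable, NA_real_, v[, 4]),
      cd8_pct = ifelse(unable, NA_real_, v[, 5]),
      cd8_abs = ifelse(unable, NA_real_, v[, 6])
    )
  })
  submissions <- dplyr::arrange(dplyr::bind_rows(rows), .data$lab_id,
                                .data$specimen_id)

  ground_truth <- tibble::tibble(
    session_id = sid, lab_id = lab_ids, instrument = instrument,
    bias = bias, unable = unable,
    unable_reason = ifelse(unable, reason, NA_character_),
    error = has_error,
    phase = ifelse(has_error, phase, NA_character_),
    category = category, affected_quantities = affected
  )
  errors <- ground_truth |>
    dplyr::filter(.data$error) |>
    dplyr::transmute(session_id = .data$session_id, lab_id = .data$lab_id,
                     category = .data$category,
                     note = paste0("injected:", .data$affected_quantities))
  list(submissions = submissions, ground_truth = ground_truth, errors = errors)
}

clamp_values <- function(values, qty) {
  pct <- endsWith(qty, "percent")
  values[, pct] <- pmin(pmax(values[, pct], 0), 100)
  values[, !pct] <- pmax(values[, !pct], 0)
  values
}

#' Generate a full synthetic EQA program
#'
#' Runs [generate_session()] for every session of the configuration and
#' binds the results.  Fully reproducible from `config$seed`; each session
#' uses an independent derived sub-stream.
#'
#' @param config A [synthetic_config()].
#' @return List of class `"eqa_program"`: `submissions`, `manifest`,
#'   `ground_truth`, `errors`, `config`.
#' @export
generate_program <- function(config = synthetic_config()) {
  out <- lapply(seq_len(config$n_sessions),
                function(i) generate_session(config, i))
  list(
    submissions = dplyr::bind_rows(lapply(out, `[[`, "submissions")),
    manifest = synthetic_manifest(config),
    ground_truth = dplyr::bind_rows(lapply(out, `[[`, "ground_truth")),
    errors = dplyr::bind_rows(lapply(out, `[[`, "errors")),
    config = config
  )
}

#' Write a generated program to delimited files
#'
#' Writes `submissions.csv`, `manifest.csv`, `errors.csv` and the
#' ground-truth sidecar `ground_truth.csv` under `dir`.
#'
#' @param program Result of [generate_program()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_program <- function(program, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_submissions(program$submissions, file.path(dir, "submissions.csv"))
  write_panel_manifest(program$manifest, file.path(dir, "manifest.csv"))
  write_error_log(program$errors, file.path(dir, "errors.csv"))
  readr::write_csv(program$ground_truth, file.path(dir, "ground_truth.csv"),
                   na = "")
  invisible(dir)
}
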