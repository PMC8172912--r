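# Independent brute-force trimmer used as the oracle for the consensus
# statistics: plain index arithmetic, no shared code with the package path.
trim_oracle <- function(x, k = 2, passes = 1, min_n = 3) {
  kept <- seq_along(x)
  for (p in seq_len(passes)) {
    m <- sum(x[kept]) / length(kept)
    s2 <- sum((x[kept] - m)^2) / (length(kept) - 1)
    s <- sqrt(s2)
    if (s == 0) break
    out <- kept[abs(x[kept] - m) > k * s]
    if (length(out) == 0) break
    if (length(kept) - length(out) < min_n) break
    kept <- setdiff(kept, out)
  }
  m <- sum(x[kept]) / length(kept)
  s <- sqrt(sum((x[kept] - m)^2) / (length(kept) - 1))
  list(mean = m, sd = s, n_outliers = length(x) - length(kept), kept = kept)
}

# all multisets of size n drawn from `grid` (nondecreasing index sequences)
enumerate_multisets <- function(grid, n) {
  recurse <- function(prefix, lo, left) {
    if (left == 0) return(list(prefix))
    out <- list()
    for (i in lo:length(grid)) {
      out <- c(out, recurse(c(prefix, grid[i]), i, left - 1))
    }
    out
  }
  recurse(numeric(0), 1, n)
}

# single-session fixture manifest
fixture_manifest <- function(session = "S01") {
  tibble::tibble(
    session_id = session,
    specimen_id = paste0(session, c("-LOW", "-MID")),
    level = c("low", "mid")
  )
}

# typed submission rows for one reporting lab (named values per column;
# anything not supplied stays NA)
fixture_submission <- function(lab, session = "S01", instrument = "FACSCount",
                               status = "reported", unable_reason = NA,
                               low = NULL, mid = NULL) {
  man <- fixture_manifest(session)
  one <- function(specimen, vals) {
    row <- tibble::tibble(
      session_id = session, lab_id = lab, instrument = instrument,
      specimen_id = specimen, status = status,
      unable_reason = as.character(unable_reason),
      receipt_date = as.Date("2015-01-10"),
      analysis_date = as.Date("2015-01-12"),
      cd3_pct = NA_real_, cd3_abs = NA_real_, cd4_pct = NA_real_,
      cd4_abs = NA_real_, cd8_pct = NA_real_, cd8_abs = NA_real_
    )
    for (nm in names(vals)) row[[nm]] <- vals[[nm]]
    row
  }
  dplyr::bind_rows(one(man$specimen_id[1], low), one(man$specimen_id[2], mid))
}

# a clean session of n labs all reporting `base` values plus per-lab offsets
# on cd4_abs of the low specimen (handy for constructing known SDI patterns)
fixture_session <- function(n, cd4_abs_low, session = "S01",
                            instrument = "FACSCount") {
  labs <- sprintf("L%02d", seq_len(n))
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    fixture_submission(
      labs[i], session, instrument,
      low = list(cd3_pct = 72, cd3_abs = 1100, cd4_pct = 12,
                 cd4_abs = cd4_abs_low[i], cd8_pct = 55, cd8_abs = 850),
      mid = list(cd3_pct = 75, cd3_abs = 1400, cd4_pct = 30,
                 cd4_abs = 500, cd8_pct = 40, cd8_abs = 750)
    )
  }))
}

# raw character-typed submission rows for io validation tests
raw_submission_row <- function(...) {
  defaults <- list(
    session_id = "S01", lab_id = "L01", instrument = "FACSCount",
    specimen_id = "S01-LOW", status = "reported", unable_reason = "",
    receipt_date = "2015-01-10", analysis_date = "2015-01-12",
    cd3_pct = "72", cd3_abs = "1100", cd4_pct = "12", cd4_abs = "150",
    cd8_pct = "55", cd8_abs = "850"
  )
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- as.character(args[[nm]])
  tibble::as_tibble(defaults)
}
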