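test_that("trimmed consensus matches hand-verified and degenerate cases", {
  # unanimous group: zero SD, nothing trimmed
  agg <- compute_trimmed_aggregate(rep(500, 10))
  expect_equal(agg$trimmed_mean, 500)
  expect_equal(agg$trimmed_sd, 0)
  expect_equal(agg$n_outliers, 0)

  # one gross outlier among five concordant laboratories (frozen from the
  # brute-force oracle: full-group mean/SD, >2 SD rule, one recalculation)
  agg <- compute_trimmed_aggregate(c(500, 510, 490, 505, 495, 1200),
                                   lab_ids = sprintf("L%02d", 1:6))
  expect_equal(agg$n_outliers, 1)
  expect_equal(agg$outlier_lab_ids, "L06")
  expect_equal(agg$trimmed_mean, 500)
  expect_equal(agg$trimmed_sd, 7.9056942, tolerance = 1e-7)

  # trimming strictly reduces the SD relative to the full group
  expect_lt(agg$trimmed_sd, sd(c(500, 510, 490, 505, 495, 1200)))

  expect_error(compute_trimmed_aggregate(c(500, 510)),
               class = "cd4eqa_insufficient_group")
})

test_that("trimming agrees with the brute-force oracle on random contaminated groups", {
  set.seed(2021)
  for (rep in 1:200) {
    n <- sample(6:20, 1)
    x <- rnorm(n, 500, 20)
    if (runif(1) < 0.6) x[1] <- 500 + sample(c(-1, 1), 1) * runif(1, 100, 600)
    oracle <- trim_oracle(x)
    agg <- compute_trimmed_aggregate(x)
    expect_equal(agg$trimmed_mean, oracle$mean, tolerance = 1e-12)
    expect_equal(agg$trimmed_sd, oracle$sd, tolerance = 1e-12)
    expect_equal(agg$n_outliers, oracle$n_outliers)
    expect_equal(which(agg$retained), oracle$kept)
  }
})

test_that("iterated trimming and stratified consensus remain available behind the config", {
  # two passes trim a value that only becomes extreme after the first pass
  x <- c(100, 101, 99, 100, 102, 98, 100, 101, 112, 300)
  one <- compute_trimmed_aggregate(x, config = scoring_config(trim_passes = 1))
  two <- compute_trimmed_aggregate(x, config = scoring_config(trim_passes = 2))
  expect_equal(one$n_outliers, trim_oracle(x, passes = 1)$n_outliers)
  expect_equal(two$n_outliers, trim_oracle(x, passes = 2)$n_outliers)
  expect_gte(two$n_outliers, one$n_outliers)

  # a pass never reduces the retained group below min_group_n
  y <- c(0, 0, 1000)
  agg <- compute_trimmed_aggregate(y, config = scoring_config(min_group_n = 3,
                                                              trim_passes = 5))
  expect_equal(agg$n_outliers, 0)
})

test_that("SDI sign, boundary and zero-SD sentinel behave as specified", {
  agg <- structure(list(n_initial = 10, n_outliers = 0, trimmed_mean = 500,
                        trimmed_sd = 8, outlier_lab_ids = character(0),
                        retained_lab_ids = character(0),
                        retained = rep(TRUE, 10)), class = "eqa_aggregate")
  s <- compute_sdi(c(500, 516, 524, 484), agg)
  expect_equal(s$sdi, c(0, 2, 3, -2))
  expect_equal(s$within_limit, c(TRUE, TRUE, FALSE, TRUE))  # |SDI| = 2 passes
  expect_true(all(sign(s$sdi) == sign(s$residual)))

  # unanimous consensus: exact agreement scores 0, any deviation fails
  agg0 <- compute_trimmed_aggregate(rep(500, 6))
  s0 <- compute_sdi(c(500, 501, 499), agg0)
  expect_equal(s0$sdi, c(0, Inf, -Inf))
  expect_equal(s0$within_limit, c(TRUE, FALSE, FALSE))
})

test_that("laboratory adjudication covers pass, fail, unable and partial reporting", {
  man <- fixture_manifest()
  subs <- fixture_session(10, cd4_abs_low = c(150, 152, 148, 151, 149,
                                              150, 153, 147, 150, 210))
  res <- score_session(subs, man)

  expect_equal(sort(unique(res$verdicts$outcome)), c("fail", "pass"))
  v10 <- res$verdicts[res$verdicts$lab_id == "L10", ]
  expect_equal(v10$outcome, "fail")
  expect_equal(v10$failing_quantities, "low.CD4.absolute")
  expect_true(all(res$verdicts$outcome[res$verdicts$lab_id != "L10"] == "pass"))

  # unable to report: registered, no results, reason carried into the verdict
  subs_u <- dplyr::bind_rows(
    fixture_session(5, cd4_abs_low = rep(150, 5)),
    fixture_submission("L99", status = "unable_to_report",
                       unable_reason = "broken_instrument"))
  v <- score_session(subs_u, man)$verdicts
  expect_equal(v$outcome[v$lab_id == "L99"], "unable_to_report")
  expect_equal(v$notes[v$lab_id == "L99"], "broken_instrument")

  # a lab reporting only a subset of quantities is not held to the rest
  subs_p <- dplyr::bind_rows(
    fixture_session(5, cd4_abs_low = c(150, 152, 148, 151, 149)),
    fixture_submission("P01", instrument = "PIMA",
                       low = list(cd4_abs = 150), mid = list(cd4_abs = 500)))
  vp <- score_session(subs_p, man)$verdicts
  expect_equal(vp$outcome[vp$lab_id == "P01"], "pass")

  # reporting only one specimen cannot be a pass
  subs_h <- dplyr::bind_rows(
    fixture_session(5, cd4_abs_low = rep(150, 5)),
    fixture_submission("H01", low = list(cd4_abs = 150))[1, ])
  vh <- score_session(subs_h, man)$verdicts
  expect_equal(vh$outcome[vh$lab_id == "H01"], "fail")
  expect_equal(vh$notes[vh$lab_id == "H01"], "incomplete_panel")

  # scores referencing unreported quantities are a consistency error
  lab_sub <- fixture_submission("X01", low = list(cd4_abs = 150),
                                mid = list(cd4_abs = 500))
  bogus <- tibble::tibble(specimen_id = "S01-LOW", level = "low",
                          marker = "CD8", value_kind = "percent",
                          sdi = 0, within_limit = TRUE, scoreable = TRUE)
  expect_error(adjudicate_lab(lab_sub, bogus),
               class = "cd4eqa_consistency_error")
})

test_that("outlier labs are still scored against the consensus; unanimity passes everyone", {
  man <- fixture_manifest()
  subs <- fixture_session(6, cd4_abs_low = c(150, 152, 148, 151, 149, 400))
  res <- score_session(subs, man)
  sc <- res$scores[res$scores$marker == "CD4" &
                     res$scores$value_kind == "absolute" &
                     res$scores$level == "low", ]
  expect_true(sc$is_outlier[sc$lab_id == "L06"])
  expect_false(sc$within_limit[sc$lab_id == "L06"])
  # excluded from the consensus but still scored against it
  expect_false(is.na(sc$sdi[sc$lab_id == "L06"]))

  # every lab reporting identical values: all pass, all SDI 0
  subs_id <- fixture_session(8, cd4_abs_low = rep(150, 8))
  res_id <- score_session(subs_id, man)
  expect_true(all(res_id$verdicts$outcome == "pass"))
  expect_true(all(res_id$scores$sdi == 0))
})

test_that("quantities below the minimum group size are unscored, not scored", {
  man <- fixture_manifest()
  # only two labs report cd8_pct; everyone reports cd4_abs
  subs <- dplyr::bind_rows(
    fixture_submission("L01", low = list(cd4_abs = 150, cd8_pct = 55),
                       mid = list(cd4_abs = 500)),
    fixture_submission("L02", low = list(cd4_abs = 152, cd8_pct = 54),
                       mid = list(cd4_abs = 498)),
    fixture_submission("L03", low = list(cd4_abs = 149),
                       mid = list(cd4_abs = 502))
  )
  res <- score_session(subs, man)
  cd8 <- res$scores[res$scores$marker == "CD8", ]
  expect_true(all(!cd8$scoreable))
  expect_true(all(is.na(cd8$sdi)))
  expect_false(any(res$aggregates$marker == "CD8"))
  expect_true(all(res$verdicts$outcome == "pass"))

  # a lab whose only reported quantities are unscoreable passes as "unscored"
  subs2 <- dplyr::bind_rows(
    fixture_submission("L01", low = list(cd4_abs = 150),
                       mid = list(cd4_abs = 500)),
    fixture_submission("L02", low = list(cd4_abs = 151),
                       mid = list(cd4_abs = 498)),
    fixture_submission("L03", low = list(cd4_abs = 149),
                       mid = list(cd4_abs = 501)),
    fixture_submission("U01", instrument = "PIMA",
                       low = list(cd8_abs = 850), mid = list(cd8_abs = 750)))
  v <- score_session(subs2, man)$verdicts
  expect_equal(v$outcome[v$lab_id == "U01"], "pass")
  expect_equal(v$notes[v$lab_id == "U01"], "unscored")
})

test_that("scoring is deterministic and invariant to laboratory order", {
  man <- fixture_manifest()
  set.seed(31)
  subs <- fixture_session(15, cd4_abs_low = rnorm(15, 150, 8))
  a <- score_session(subs, man)
  b <- score_session(subs[sample(nrow(subs)), ], man)
  expect_identical(a$verdicts, b$verdicts)
  expect_identical(a$aggregates, b$aggregates)
  expect_identical(a$scores, b$scores)
  c2 <- score_session(subs, man)
  expect_identical(a$scores, c2$scores)
})
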