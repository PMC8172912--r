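make_scored_session <- function() {
  subs <- fixture_session(10, cd4_abs_low = c(150, 152, 148, 151, 149,
                                              150, 153, 147, 150, 210))
  subs <- dplyr::bind_rows(subs, fixture_submission(
    "L99", status = "unable_to_report", unable_reason = "no_reagents"))
  score_session(subs, fixture_manifest())
}

test_that("laboratory reports carry outcome, signed SDI rows and corrective actions", {
  res <- make_scored_session()
  errors <- tibble::tibble(session_id = "S01", lab_id = "L10",
                           category = "pipette_calibration", note = "")

  pass_rep <- render_lab_report(res$verdicts[res$verdicts$lab_id == "L01", ],
                                res$scores, errors)
  expect_equal(pass_rep$outcome, "PASS")
  expect_true(all(pass_rep$results$within_limit))
  expect_equal(nrow(pass_rep$results), 12)

  fail_rep <- render_lab_report(res$verdicts[res$verdicts$lab_id == "L10", ],
                                res$scores, errors)
  expect_equal(fail_rep$outcome, "FAIL")
  expect_equal(fail_rep$failing_quantities, "low.CD4.absolute")
  bad_row <- fail_rep$results[fail_rep$results$quantity == "low.CD4.absolute", ]
  expect_match(bad_row$sdi, "^\\+\\d")  # signed, two decimals
  expect_match(bad_row$sdi, "\\.\\d{2}$")
  expect_false(bad_row$within_limit)
  expect_equal(fail_rep$corrective_actions,
               "pipette_calibration (analytical)")
  txt <- format(fail_rep)
  expect_true(any(grepl("Outcome: FAIL", txt)))

  unable_rep <- render_lab_report(
    res$verdicts[res$verdicts$lab_id == "L99", ], res$scores)
  expect_equal(unable_rep$outcome, "UNABLE_TO_REPORT")
  expect_equal(unable_rep$unable_reason, "no_reagents")
  expect_null(unable_rep$results)

  # negative deviations render with an explicit minus sign
  expect_equal(format_sdi(-2.6), "-2.60")
  expect_equal(format_sdi(c(0, 1.254)), c("0.00", "+1.25"))

  # a reported verdict without any scores is inconsistent
  orphan <- res$verdicts[res$verdicts$lab_id == "L01", ]
  expect_error(render_lab_report(orphan, res$scores[0, ]),
               class = "cd4eqa_consistency_error")
})

test_that("coordinator reports aggregate summary, breakdown, actions and phases", {
  res <- make_scored_session()
  errors <- tibble::tibble(session_id = "S01", lab_id = "L10",
                           category = "pipette_calibration", note = "")
  rep <- render_coordinator_report(res, errors)
  expect_equal(rep$summary$n_reported, 10)
  expect_equal(rep$summary$n_unable, 1)
  expect_equal(length(rep$failing_labs), 1)
  expect_equal(rep$failing_labs[[1]]$lab_id, "L10")
  expect_equal(rep$failing_labs[[1]]$recommended_actions, "pipette_calibration")
  expect_equal(rep$phase_distribution$pct[2], 100)
  txt <- format(rep)
  expect_true(any(grepl("Pass: 9 \\(90\\)", txt)))

  # all-pass session: empty corrective-action section
  subs <- fixture_session(6, cd4_abs_low = rep(150, 6))
  rep2 <- render_coordinator_report(score_session(subs, fixture_manifest()))
  expect_equal(length(rep2$failing_labs), 0)
  expect_true(any(grepl("none - all reporting sites passed", format(rep2))))

  # unscoreable quantity is called out explicitly
  subs3 <- dplyr::bind_rows(
    fixture_submission("L01", low = list(cd4_abs = 150),
                       mid = list(cd4_abs = 500)),
    fixture_submission("L02", low = list(cd4_abs = 151),
                       mid = list(cd4_abs = 499)),
    fixture_submission("L03", low = list(cd4_abs = 149, cd8_abs = 850),
                       mid = list(cd4_abs = 501)))
  rep3 <- render_coordinator_report(score_session(subs3, fixture_manifest()))
  expect_equal(rep3$unscored_quantities, "low.CD8.absolute")
  expect_true(any(grepl("Unscored quantities", format(rep3))))
})

test_that("report rendering and writing are pure and byte-identical across runs", {
  res <- make_scored_session()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    write_report(render_coordinator_report(res), d)
    write_report(render_lab_report(res$verdicts[1, ], res$scores), d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
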