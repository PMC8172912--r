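test_that("a noise-free program reports exactly nominal and passes everywhere", {
  cfg <- synthetic_config(
    n_sessions = 2, labs_per_session = 8,
    instrument_cv = c(FACSCount = 0, CyFlow = 0, PIMA = 0, Other = 0),
    instrument_bias = c(FACSCount = 0, CyFlow = 0, PIMA = 0, Other = 0),
    bias_sd = 0, p_unable = 0, p_error = 0, seed = 3)
  prog <- generate_program(cfg)
  expect_true(all(prog$submissions$status == "reported"))
  nominal <- default_nominals()
  long <- submissions_long(prog$submissions, prog$manifest)
  joined <- dplyr::left_join(long, nominal,
                             by = c("level", "marker", "value_kind"))
  expect_equal(joined$reported_value, joined$nominal)

  res <- score_program(prog$submissions, prog$manifest)
  expect_true(all(res$verdicts$outcome == "pass"))
  expect_true(all(res$scores$sdi == 0))
})

test_that("an all-unable session registers labs but reports none", {
  cfg <- synthetic_config(n_sessions = 1, labs_per_session = 6, p_unable = 1,
                          seed = 4)
  ses <- generate_session(cfg, 1)
  expect_true(all(ses$submissions$status == "unable_to_report"))
  expect_true(all(ses$submissions$unable_reason %in%
                    c("no_login", "broken_instrument", "no_reagents",
                      "expired_reagents")))
  res <- score_session(ses$submissions, synthetic_manifest(cfg))
  ss <- summarize_session(res$verdicts)
  expect_equal(ss$n_registered, 6)
  expect_equal(ss$n_reported, 0)
  expect_equal(ss$n_unable, 6)
})

test_that("generation is deterministic from the seed and follows the growth schedule", {
  cfg <- synthetic_config(n_sessions = 3, labs_per_session = c(14, 50, 48),
                          seed = 42)
  p1 <- generate_program(cfg)
  p2 <- generate_program(cfg)
  expect_identical(p1$submissions, p2$submissions)
  expect_identical(p1$ground_truth, p2$ground_truth)

  # sessions are independently reproducible from the split seed
  s2 <- generate_session(cfg, 2)
  expect_identical(s2$submissions,
                   p1$submissions[p1$submissions$session_id == "S02", ])

  res <- score_program(p1$submissions, p1$manifest)
  expect_equal(participation_series(res$verdicts)$n_registered, c(14, 50, 48))
})

test_that("an injected biased laboratory is trimmed as an outlier and fails CD4", {
  ok <- logical(20)
  trimmed <- logical(20)
  for (s in 1:20) {
    cfg <- synthetic_config(
      n_sessions = 1, labs_per_session = 30,
      instrument_mix = c(FACSCount = 1, CyFlow = 0, PIMA = 0, Other = 0),
      instrument_cv = c(FACSCount = 0.03, CyFlow = 0.03, PIMA = 0.03,
                        Other = 0.03),
      bias_overrides = c(LAB001 = 0.30),
      p_unable = 0, p_error = 0, seed = 1000 + s)
    ses <- generate_session(cfg, 1)
    res <- score_session(ses$submissions, synthetic_manifest(cfg))
    cd4 <- res$scores[res$scores$marker == "CD4" &
                        res$scores$value_kind == "absolute" &
                        res$scores$lab_id == "LAB001", ]
    v <- res$verdicts[res$verdicts$lab_id == "LAB001", ]
    ok[s] <- v$outcome == "fail" && all(!cd4$within_limit)
    trimmed[s] <- all(cd4$is_outlier)

    # cross-check the trimming decision with the brute-force oracle
    g <- submissions_long(ses$submissions, synthetic_manifest(cfg))
    g <- g[g$marker == "CD4" & g$value_kind == "absolute" &
             g$specimen_id == "S01-LOW", ]
    oracle <- trim_oracle(g$reported_value)
    agg <- compute_trimmed_aggregate(g$reported_value, g$lab_id)
    expect_equal(agg$n_outliers, oracle$n_outliers)
    expect_equal(agg$trimmed_mean, oracle$mean, tolerance = 1e-12)
  }
  expect_true(all(ok))
  expect_true(all(trimmed))
})

test_that("injected analytical errors are flagged on the injected quantity", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    cfg <- synthetic_config(n_sessions = 1, labs_per_session = 40,
                            p_unable = 0, p_error = 0.15, seed = 300 + s)
    ses <- generate_session(cfg, 1)
    res <- score_session(ses$submissions, synthetic_manifest(cfg))
    gt <- ses$ground_truth[!is.na(ses$ground_truth$phase) &
                             ses$ground_truth$phase == "analytical", ]
    for (k in seq_len(nrow(gt))) {
      v <- res$verdicts[res$verdicts$lab_id == gt$lab_id[k], ]
      total <- total + 1L
      if (gt$affected_quantities[k] %in%
            strsplit(v$failing_quantities, ";")[[1]]) hits <- hits + 1L
    }
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.9)
})

test_that("every generated file passes the io validation layer", {
  cfg <- synthetic_config(n_sessions = 3, labs_per_session = c(10, 20, 30),
                          p_unable = 0.2, p_error = 0.3, seed = 77)
  prog <- generate_program(cfg)
  d <- withr::local_tempdir()
  write_program(prog, d)
  subs <- parse_submissions(file.path(d, "submissions.csv"))
  expect_equal(nrow(attr(subs, "rejected")), 0)
  expect_equal(nrow(subs), nrow(prog$submissions))
  man <- parse_panel_manifest(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 6)
  errs <- parse_error_log(file.path(d, "errors.csv"))
  expect_true(all(errs$phase %in% c("pre_analytical", "analytical",
                                    "post_analytical")))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(phase_mix = c(0.5, 0.5, 0.5)),
               class = "cd4eqa_config_error")
  expect_error(synthetic_config(p_unable = 1.2), class = "cd4eqa_config_error")
  expect_error(synthetic_config(n_sessions = 3, labs_per_session = c(10, 20)),
               class = "cd4eqa_config_error")
  nv <- default_nominals()
  nv$nominal[nv$level == "low" & nv$marker == "CD4" &
               nv$value_kind == "absolute"] <- 900
  expect_error(synthetic_config(nominal_values = nv),
               class = "cd4eqa_config_error")
  expect_error(generate_session(synthetic_config(n_sessions = 2), 5),
               class = "cd4eqa_config_error")
})

test_that("injected phase proportions converge to the configured mix", {
  cfg <- synthetic_config(n_sessions = 2, labs_per_session = 600,
                          p_unable = 0, p_error = 1, seed = 12)
  prog <- generate_program(cfg)
  pd <- phase_distribution(prog$errors)
  expect_equal(sum(pd$n), 1200)
  expect_lt(max(abs(pd$pct - c(17.5, 77.0, 5.5))), 4)
})
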