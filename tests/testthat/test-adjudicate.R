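test_that("ILD progression rule fires on qualifying FVC/DLco drops only", {
  rules <- adjudication_rules()
  # absolute drop of 11 points within 12 months
  v <- toy_visits("a", c(0, 10), fvc = c(100, 89))
  expect_equal(detect_ild_progression(v, rules), 10)
  # minor drop (7) with a 16.7% relative DLco decline
  v <- toy_visits("a", c(0, 6), fvc = c(100, 93), dlco = c(60, 50))
  expect_equal(detect_ild_progression(v, rules), 6)
  # same FVC drop without the DLco decline: no event
  v <- toy_visits("a", c(0, 6), fvc = c(100, 93), dlco = c(60, 55))
  expect_true(is.na(detect_ild_progression(v, rules)))
  # drop of 9 outside the 12-month window
  v <- toy_visits("a", c(0, 14), fvc = c(100, 91))
  expect_true(is.na(detect_ild_progression(v, rules)))
  # rolling window: qualifying pair need not involve baseline
  v <- toy_visits("a", c(0, 20, 26), fvc = c(100, 98, 87))
  expect_equal(detect_ild_progression(v, rules), 26)
  # earliest qualifying later-visit time is returned
  v <- toy_visits("a", c(0, 6, 12), fvc = c(100, 89, 80))
  expect_equal(detect_ild_progression(v, rules), 6)
  # missing FVC visits are skipped
  v <- toy_visits("a", c(0, 6, 12), fvc = c(100, NA, 89))
  expect_equal(detect_ild_progression(v, rules), 12)
  expect_error(detect_ild_progression(toy_visits("a", c(6, 0))),
               class = "ifnttcw_contract_error")
})

test_that("skin worsening needs >=5 units and >=25% of baseline, both inclusive", {
  rules <- adjudication_rules()
  expect_equal(detect_skin_worsening(4, toy_visits("a", 12, mrss = 9),
                                     rules), 12)
  expect_true(is.na(detect_skin_worsening(20, toy_visits("a", 12, mrss = 24),
                                          rules)))
  # +5 on baseline 20 is exactly 25%: inclusive thresholds
  expect_equal(detect_skin_worsening(20, toy_visits("a", 12, mrss = 25),
                                     rules), 12)
  # +6 on baseline 30 is 20%: absolute met, relative not
  expect_true(is.na(detect_skin_worsening(30, toy_visits("a", 12, mrss = 36),
                                          rules)))
  # baseline 0 qualifies on the absolute increase alone
  expect_equal(detect_skin_worsening(0, toy_visits("a", 18, mrss = 5),
                                     rules), 18)
  expect_error(detect_skin_worsening(-1, toy_visits("a", 6, mrss = 3)),
               class = "ifnttcw_validation_error")
})

test_that("flag events map to types, respect the 'new PAH' qualifier, and censor on non-SSc death", {
  vis <- toy_visits("a", c(0, 30), flags = list(new_pah_rhc = 2))
  # prevalent PAH at baseline: the flag is not a new-PAH event
  res <- detect_flag_events(toy_baseline_row("a", pah = TRUE), vis)
  expect_equal(nrow(res$events), 0L)
  res <- detect_flag_events(toy_baseline_row("a"), vis)
  expect_equal(res$events$event, "pah")
  expect_equal(res$events$time, 30)

  vis <- toy_visits("a", c(0, 18), flags = list(arrhythmia_treated = 2))
  res <- detect_flag_events(toy_baseline_row("a"), vis)
  expect_equal(res$events$event, "cardiac")
  expect_equal(res$events$time, 18)

  vis <- toy_visits("a", c(0, 40), flags = list(nonssc_death = 2))
  res <- detect_flag_events(toy_baseline_row("a"), vis)
  expect_equal(nrow(res$events), 0L)
  expect_equal(res$censor_at, 40)
})

test_that("first-event adjudication takes the earliest event, severity-breaking ties", {
  base <- toy_baseline_row("a", mrss = 4L)
  # skin qualifies at 24 but the PAH flag at 18 comes first
  vis <- toy_visits("a", c(0, 18, 24), mrss = c(4, 4, 9),
                    flags = list(new_pah_rhc = 2))
  out <- adjudicate_first_event(base, vis)
  expect_equal(out$event, "pah")
  expect_equal(out$ttcw_months, 18)

  # nothing fires: censored at the last visit
  vis <- toy_visits("a", seq(0, 89, by = 6), fvc = 100, mrss = 4)
  out <- adjudicate_first_event(base, vis)
  expect_true(out$censored)
  expect_equal(out$ttcw_months, 84)

  # simultaneous ILD and cardiac signals: ILD wins by severity order
  vis <- toy_visits("a", c(0, 30, 36), fvc = c(100, 100, 88),
                    flags = list(arrhythmia_treated = 3))
  out <- adjudicate_first_event(base, vis)
  expect_equal(out$event, "ild_progression")
  expect_equal(out$ttcw_months, 36)

  expect_warning(out <- adjudicate_first_event(base, vis[0, ]),
                 "no visits")
  expect_equal(out$ttcw_months, 0)
  expect_true(out$censored)
})

test_that("adjudication is idempotent and invariant to visit input order", {
  ch <- generate_cohort(sim_config(seed = 41, n_patients = 60))
  oc1 <- adjudicate_cohort(ch$baseline, ch$visits)
  oc2 <- adjudicate_cohort(ch$baseline, ch$visits)
  expect_identical(oc1, oc2)
  set.seed(1)
  shuffled <- ch$visits[sample(nrow(ch$visits)), ]
  oc3 <- adjudicate_cohort(ch$baseline, shuffled)
  expect_identical(oc1, oc3)
})

test_that("adding a later visit never changes an already-detected event", {
  base <- toy_baseline_row("a", mrss = 2L)
  vis <- toy_visits("a", c(0, 6, 12), fvc = c(100, 100, 88), mrss = 2)
  out1 <- adjudicate_first_event(base, vis)
  later <- toy_visits("a", 18, fvc = 70, mrss = 20,
                      flags = list(renal_crisis = 1))
  out2 <- adjudicate_first_event(base, rbind(vis, later))
  expect_identical(out1[, c("event", "ttcw_months")],
                   out2[, c("event", "ttcw_months")])
})

test_that("five-year completeness filter drops only early censorings", {
  oc <- toy_outcomes(c(30, 48, 70, 60, 75),
                     c(FALSE, TRUE, TRUE, TRUE, FALSE))
  kept <- filter_complete_5yr(oc)
  expect_setequal(kept$subject_id, oc$subject_id[c(1, 3, 4, 5)])

  # counting oracle on generator output
  ch <- generate_cohort(sim_config(seed = 42))
  oc <- adjudicate_cohort(ch$baseline, ch$visits)
  kept <- filter_complete_5yr(oc)
  expect_equal(nrow(kept),
               nrow(oc) - sum(oc$censored & oc$ttcw_months < 60))
})

test_that("generated visit streams recover latent truth near-perfectly", {
  ch <- generate_cohort(sim_config(seed = 43))
  oc <- adjudicate_cohort(ch$baseline, ch$visits)
  expect_gte(recovery_rate(ch$truth, oc), 0.99)
})
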