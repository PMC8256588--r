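test_that("consecutive-pair scanning finds every N-to-E transition", {
  expect_equal(nrow(detect_events(c(FALSE, TRUE))), 1)
  ev <- detect_events(c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(ev$initial_idx, c(1L, 4L))
  expect_equal(ev$subsequent_idx, c(2L, 5L))
  expect_equal(nrow(detect_events(c(TRUE, TRUE, TRUE))), 0)
  expect_equal(nrow(detect_events(logical(1))), 0)
  expect_equal(nrow(detect_events(logical(0))), 0)
})

test_that("indeterminate samples are skipped or counted per the rule", {
  calls <- c(FALSE, TRUE, FALSE, TRUE)
  ind <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(detect_events(calls, ind, "skip")$initial_idx, 3L)
  expect_equal(detect_events(calls, ind, "negative")$initial_idx, c(1L, 3L))
})

test_that("streaming scan matches a brute-force pair enumerator", {
  set.seed(21)
  for (rule in c("skip", "negative")) {
    for (rep in 1:200) {
      n <- sample(2:12, 1)
      calls <- runif(n) < 0.4
      ind <- runif(n) < 0.15
      calls[ind] <- FALSE  # indeterminates are never eosinophilic
      expect_identical(detect_events(calls, ind, rule),
                       brute_force_events(calls, ind, rule))
    }
  }
})

test_that("etiology attribution is mutually exclusive and exhaustive", {
  neut_high <- list(neutrophil_pct = 90, ics_dose_mcg = 500, ocs_dose_mg = 0)
  same_dose <- list(neutrophil_pct = 40, ics_dose_mcg = 500, ocs_dose_mg = 0)
  lower_ics <- list(neutrophil_pct = 40, ics_dose_mcg = 250, ocs_dose_mg = 0)

  expect_equal(attribute_etiology(neut_high, same_dose)$etiology,
               "neutrophilia_treated")
  expect_equal(attribute_etiology(same_dose, lower_ics)$etiology,
               "steroid_decrease")
  expect_equal(attribute_etiology(neut_high, lower_ics)$etiology,
               "neutrophilia_and_steroid_decrease")
  expect_equal(attribute_etiology(same_dose, same_dose)$etiology, "flare")
  # OCS fall alone is a steroid decrease
  expect_equal(attribute_etiology(
    list(neutrophil_pct = 40, ics_dose_mcg = 500, ocs_dose_mg = 10),
    list(neutrophil_pct = 40, ics_dose_mcg = 500, ocs_dose_mg = 5))$etiology,
    "steroid_decrease")
})

test_that("unknown neutrophils or doses give indeterminate-false conditions", {
  unk <- list(neutrophil_pct = NA_real_, ics_dose_mcg = NA_real_,
              ocs_dose_mg = NA_real_)
  known <- list(neutrophil_pct = 40, ics_dose_mcg = 250, ocs_dose_mg = 0)
  att <- attribute_etiology(unk, known)
  expect_equal(att$etiology, "flare")
  expect_false(att$neutrophil_known)
  expect_false(att$dose_known)
})

test_that("cohort-level emergence summary aggregates per-patient events", {
  # three patients with 0, 1 and 2 events
  co <- cohort_from_rows(
    sample_row("A", "2020-01-01", eos = 5),
    sample_row("A", "2020-02-01", eos = 5),
    sample_row("B", "2020-01-01", eos = 0.2),
    sample_row("B", "2020-02-01", eos = 5),
    sample_row("C", "2020-01-01", eos = 0.2),
    sample_row("C", "2020-02-01", eos = 5),
    sample_row("C", "2020-03-01", eos = 0.2),
    sample_row("C", "2020-04-01", eos = 5),
    sample_row("D", "2020-01-01", eos = 0.2)  # single-sample: excluded
  )
  em <- summarize_emergence(co, threshold_abnormal())
  expect_equal(em$summary$n_multi_patients, 3)
  expect_equal(em$summary$n_patients_with_event, 2)
  expect_equal(em$summary$fraction_patients, 2 / 3)
  expect_equal(em$summary$n_events, 3)
  expect_equal(em$summary$events_per_patient, 1)
  expect_equal(sum(em$etiology_breakdown$n), em$summary$n_events)
  expect_equal(sum(em$etiology_breakdown$fraction), 1)
  expect_false("D" %in% em$events$patient_id)

  singles <- cohort_from_rows(sample_row("X"), sample_row("Y"))
  expect_error(summarize_emergence(singles, threshold_abnormal()),
               "not estimable")
})

test_that("each event satisfies its own criterion", {
  set.seed(31)
  df <- dplyr::bind_rows(lapply(1:60, function(i) {
    k <- sample(2:5, 1)
    dplyr::bind_rows(lapply(seq_len(k), function(t) {
      sample_row(sprintf("P%02d", i),
                 exam_date = sprintf("2020-%02d-01", t),
                 eos = round(rlnorm(1, log(1), 1.5), 1),
                 feg_clumps = if (runif(1) < 0.4)
                   as.integer(rpois(1, 1)) else NA_integer_)
    }))
  }))
  co <- suppressWarnings(as_sputum_cohort(df))
  for (spec in default_thresholds()) {
    ev <- find_emergence(co, spec)
    if (nrow(ev) == 0) next
    calls <- classify_cohort(co, spec)$calls
    expect_true(all(!calls$eosinophilic[match(ev$initial_row_id,
                                              calls$row_id)]))
    expect_true(all(calls$eosinophilic[match(ev$subsequent_row_id,
                                             calls$row_id)]))
  }
})
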