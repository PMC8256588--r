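test_that("identical seed and configuration reproduce the cohort exactly", {
  cfg <- generator_config(seed = 99, n_patients = 300)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(tibble::as_tibble(a$cohort), tibble::as_tibble(b$cohort))
  expect_identical(a$truth$samples, b$truth$samples)
  # and a different seed does not
  c <- generate_cohort(generator_config(seed = 100, n_patients = 300))
  expect_false(identical(tibble::as_tibble(a$cohort),
                         tibble::as_tibble(c$cohort)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(generator_config(seed = 1, n_patients = 50)))
  expect_identical(.Random.seed, before)
})

test_that("generated cohorts are schema-valid with zero rejects", {
  g <- generate_cohort(generator_config(seed = 5, n_patients = 400))
  expect_equal(nrow(rejects(g$cohort)), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g$cohort, path)
  back <- suppressWarnings(read_cohort(path))
  expect_equal(nrow(rejects(back)), 0)
  expect_equal(nrow(back), nrow(g$cohort))
  # viable rows carry complete differentials summing to 100
  viable <- back[back$differential_viable, ]
  sums <- rowSums(viable[, c("neutrophil_pct", "eosinophil_pct",
                             "macrophage_pct", "lymphocyte_pct",
                             "bronchial_epithelial_pct")])
  expect_true(all(abs(sums - 100) <= 0.5))
})

test_that("a frozen chain with no FEG produces zero emergence events", {
  cfg <- ideal_config(seed = 3, n_patients = 200, p_NE = 0, p_EN = 0,
                      init_state_prob_E = 0)
  g <- generate_cohort(cfg)
  for (spec in default_thresholds()) {
    expect_equal(nrow(find_emergence(g$cohort, spec)), 0)
  }
})

test_that("fully degenerated samples are called on FEG evidence alone", {
  cfg <- generator_config(seed = 4, n_patients = 300,
                          p_nonviable_N = 1, p_nonviable_E = 1)
  g <- generate_cohort(cfg)
  calls <- classify_cohort(g$cohort, threshold_abnormal())$calls
  expect_true(all(calls$basis %in% c("feg_only", "none")))
})

test_that("ground-truth ledger aligns with the generated cohort", {
  g <- generate_cohort(generator_config(seed = 6, n_patients = 200))
  expect_equal(nrow(g$truth$samples), nrow(g$cohort))
  expect_equal(sum(g$truth$patients$n_samples), nrow(g$cohort))
  # degenerated samples in the ledger match the cohort's viability flags
  led <- dplyr::arrange(g$truth$samples, .data$patient_id, .data$visit)
  coh <- dplyr::arrange(tibble::as_tibble(g$cohort), .data$patient_id,
                        .data$exam_date)
  expect_equal(led$nonviable, !coh$differential_viable)
})

test_that("generator configuration round-trips through JSON", {
  cfg <- generator_config(seed = 8, n_patients = 77, p_NE = 0.21)
  paths <- list(cohort = withr::local_tempfile(fileext = ".csv"),
                config = withr::local_tempfile(fileext = ".json"))
  g <- generate_cohort(cfg)
  write_generated(g, paths$cohort, config_path = paths$config)
  cfg2 <- read_generator_config(paths$config)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("invalid configurations fail before any sampling", {
  expect_error(generator_config(p_NE = 1.3), "outside")
  expect_error(generator_config(multi_fraction = -0.1), "outside")
  expect_error(generator_config(ics_tier_probs = c(0.5, 0.5)),
               "length")
  expect_error(generator_config(p_NE = 0, p_EN = 0), "init_state_prob_E")
})

test_that("transition estimates recover the generating chain", {
  p_ne <- 0.3; p_en <- 0.2
  g <- generate_cohort(ideal_config(seed = 13, n_patients = 1500,
                                    p_NE = p_ne, p_EN = p_en))
  calls <- classify_cohort(g$cohort, threshold_clinical())$calls
  m <- estimate_transitions(calls)
  expect_lt(abs(m$p_NE - p_ne),
            3 * sqrt(p_ne * (1 - p_ne) / sum(m$counts["N", ])))
  expect_lt(abs(m$p_EN - p_en),
            3 * sqrt(p_en * (1 - p_en) / sum(m$counts["E", ])))
  # calls mirror the latent states exactly under the noiseless layer
  led <- dplyr::arrange(g$truth$samples, .data$patient_id, .data$visit)
  coh_calls <- dplyr::arrange(calls, .data$patient_id, .data$exam_date)
  expect_equal(coh_calls$eosinophilic, led$latent_E)
})

test_that("closed-form expectations require time-homogeneous configs", {
  expect_error(closed_form_expectations(generator_config()),
               "time-homogeneous")
})

test_that("closed form reduces to hand formulas in simple regimes", {
  # symmetric chain: stationary prevalence one half
  cfg <- ideal_config(seed = 1, n_patients = 2, p_NE = 0.5, p_EN = 0.5,
                      p_dose_decrease = 0)
  expect_equal(closed_form_expectations(cfg)$stationary_prev_E, 0.5)
  # series of length 2: patient emergence = P(N at first visit) * p_NE
  cfg2 <- ideal_config(seed = 1, n_patients = 2, p_NE = 0.3, p_EN = 0.2,
                       series_extra_geom_prob = 1 - 1e-12,
                       p_dose_decrease = 0)
  cf2 <- closed_form_expectations(cfg2)
  pi_N <- 1 - cf2$stationary_prev_E
  expect_equal(cf2$thresholds$patient_emergence,
               rep(pi_N * 0.3, 2), tolerance = 1e-9)
  # noiseless calls: sample prevalence equals latent stationary occupancy
  expect_equal(cf2$thresholds$call_prev, rep(cf2$stationary_prev_E, 2),
               tolerance = 1e-9)
})

test_that("Monte-Carlo runs agree with closed-form expectations", {
  cfg <- generator_config(seed = 17, n_patients = 8000,
                          p_dose_decrease = 0)
  cf <- closed_form_expectations(cfg)
  g <- generate_cohort(cfg)
  n_samp <- nrow(g$cohort)
  parts <- split_by_multiplicity(g$cohort)
  n_multi <- dplyr::n_distinct(parts$multi$patient_id)
  for (i in seq_along(default_thresholds())) {
    spec <- default_thresholds()[[i]]
    exp_row <- cf$thresholds[cf$thresholds$threshold_name == spec$name, ]
    est <- estimate_prevalence(g$cohort, spec, tally_mode = "nested")
    se_prev <- sqrt(exp_row$prev_feg_aug_nested *
                      (1 - exp_row$prev_feg_aug_nested) / n_samp)
    expect_lt(abs(est$prev_feg_aug - exp_row$prev_feg_aug_nested),
              3 * se_prev + 1e-6)
    se_int <- sqrt(exp_row$prev_intact * (1 - exp_row$prev_intact) / n_samp)
    expect_lt(abs(est$prev_intact - exp_row$prev_intact), 3 * se_int + 1e-6)
    em <- summarize_emergence(g$cohort, spec)
    se_em <- sqrt(exp_row$patient_emergence *
                    (1 - exp_row$patient_emergence) / n_multi)
    expect_lt(abs(em$summary$fraction_patients - exp_row$patient_emergence),
              3 * se_em + 1e-6)
  }
})
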