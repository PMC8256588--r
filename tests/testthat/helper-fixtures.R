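# Row builder for schema-valid sputum records. Differential percentages
# are filled so the five sum to exactly 100 when viable.
sample_row <- function(patient_id = "P1", exam_date = "2020-01-01",
                       eos = 0.5, neut = 60, viable = TRUE,
                       feg_clumps = NA_integer_, feg_grade = NA_character_,
                       ics = 500, ocs = 0, state = "stable",
                       total = 6, viability = 75, squamous = 5) {
  mac <- if (viable) 100 - eos - neut - 1 - 0.5 else NA_real_
  tibble::tibble(
    patient_id = patient_id,
    exam_date = exam_date,
    total_cell_count_e6_per_g = total,
    viability_pct = viability,
    squamous_pct = squamous,
    differential_viable = viable,
    neutrophil_pct = if (viable) neut else NA_real_,
    eosinophil_pct = if (viable) eos else NA_real_,
    macrophage_pct = mac,
    lymphocyte_pct = if (viable) 1 else NA_real_,
    bronchial_epithelial_pct = if (viable) 0.5 else NA_real_,
    feg_clumps_per_fov = feg_clumps,
    feg_grade = feg_grade,
    ics_dose_mcg = ics,
    ocs_dose_mg = ocs,
    clinical_state = state
  )
}

cohort_from_rows <- function(...) {
  suppressWarnings(as_sputum_cohort(dplyr::bind_rows(...)))
}

# independent brute-force oracle for emergence scanning: plain loop over
# every consecutive index pair, mirroring the definition rather than the
# implementation
brute_force_events <- function(eosinophilic, indeterminate = NULL,
                               rule = "skip") {
  if (is.null(indeterminate)) indeterminate <- rep(FALSE, length(eosinophilic))
  hits <- list()
  if (length(eosinophilic) >= 2) {
    for (i in seq_len(length(eosinophilic) - 1)) {
      j <- i + 1L
      skip <- if (rule == "skip") indeterminate[i] || indeterminate[j]
              else indeterminate[j]
      if (!skip && !eosinophilic[i] && eosinophilic[j]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(initial_idx = integer(), subsequent_idx = integer()))
  }
  m <- do.call(rbind, hits)
  tibble::tibble(initial_idx = m[, 1], subsequent_idx = m[, 2])
}

# generator configuration with a noiseless observation layer: calls equal
# the latent state exactly (fully separated eosinophil distributions, no
# masking, no degeneration, no FEG), for estimator-recovery tests
ideal_config <- function(seed, n_patients, p_NE, p_EN,
                         multi_fraction = 1, ...) {
  generator_config(
    seed = seed, n_patients = n_patients, multi_fraction = multi_fraction,
    p_NE = p_NE, p_EN = p_EN,
    eos_meanlog_N = log(0.2), eos_sdlog_N = 0.15,
    eos_meanlog_E = log(20), eos_sdlog_E = 0.30,
    patient_effect_sd = 0,
    mask_base = 0, mask_per_ics1000 = 0, mask_ocs_on = 0, mask_neut = 0,
    p_nonviable_N = 0, p_nonviable_E = 0,
    feg_lambda = list(viable_N = 0, viable_E_masked = 0,
                      viable_E_unmasked = 0, nonviable_N = 0,
                      nonviable_E = 0),
    p_feg_missing = 0,
    ...
  )
}
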