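#' Configuration for the synthetic longitudinal sputum cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' each patient carries a latent eosinophilic state evolving as a two-state
#' discrete-time Markov chain over examinations, and every examination
#' yields a noisy observation of that state. Masking is modelled as
#' observation noise: a latent-eosinophilic visit can present a low intact
#' eosinophil percentage when the patient is on corticosteroids or has
#' concurrent neutrophilia, while free eosinophil granules (FEG) may still
#' betray the state — which is what makes re-emergence (unmasking)
#' non-trivial to detect. Sample degeneration (no intact differential) is
#' more likely in the latent-eosinophilic state, and degenerated samples
#' carry only the FEG observation.
#'
#' Default values reproduce the scale and mix of a large clinical sputum
#' database: roughly 31% of patients examined more than once, multi-sample
#' series averaging about 3.7 examinations, intact eosinophilia prevalence
#' near 36% at the 1.2% cutoff, and re-emergence in roughly 28% of
#' multi-sample patients at that cutoff (see the calibration vignette
#' section for how the observation-model defaults were fixed).
#'
#' @param seed Integer seed; together with the configuration it fully
#'   determines the generated cohort.
#' @param n_patients Number of patients.
#' @param multi_fraction Probability a patient is examined more than once.
#' @param series_extra_geom_prob Multi-sample series length is
#'   `2 + rgeom(prob)` truncated at `series_max_length` (default mean about
#'   3.7 examinations).
#' @param series_max_length Truncation for series lengths.
#' @param p_NE,p_EN Latent-chain transition probabilities (non-eosinophilic
#'   to eosinophilic and back) per examination step.
#' @param init_state_prob_E Probability the first visit is latent
#'   eosinophilic; `NULL` (default) uses the chain's stationary value.
#' @param eos_meanlog_N,eos_sdlog_N Log-normal parameters of the observed
#'   intact eosinophil % in the latent non-eosinophilic state (also used
#'   for masked eosinophilic visits).
#' @param eos_meanlog_E,eos_sdlog_E Log-normal parameters in the unmasked
#'   latent eosinophilic state.
#' @param eos_cap Upper cap on the observed eosinophil % (default 97).
#' @param patient_effect_sd SD of a per-patient offset added to both
#'   log-normal means (between-patient heterogeneity; makes observed calls
#'   sticky within a patient).
#' @param mask_base,mask_per_ics1000,mask_ocs_on,mask_neut,mask_cap
#'   Masking probability for a latent-eosinophilic visit:
#'   `min(mask_cap, mask_base + mask_per_ics1000 * ics/1000 +
#'   mask_ocs_on * (ocs > 0) + mask_neut * neut_elevated)`.
#' @param p_neut_elev_N,p_neut_elev_E Per-visit probability of an elevated
#'   neutrophil differential in each latent state.
#' @param neut_elev_cutoff Percent boundary used when drawing elevated vs
#'   non-elevated neutrophil values (matches the default attribution
#'   cutoff).
#' @param ics_tier_doses,ics_tier_probs Initial inhaled-corticosteroid dose
#'   tiers (fluticasone-equivalent micrograms/day) and their probabilities.
#' @param p_ocs,ocs_tier_doses,ocs_tier_probs Probability of oral
#'   corticosteroid use and the dose tiers (mg/day) among users.
#' @param p_dose_decrease Per-visit probability (from the second visit on)
#'   that the steroid dose steps down one tier (step-down-only weaning).
#' @param p_nonviable_N,p_nonviable_E Probability that no intact
#'   differential can be made, by latent state.
#' @param feg_lambda Named list of Poisson means for FEG clump counts per
#'   400x field: `viable_N`, `viable_E_masked`, `viable_E_unmasked`,
#'   `nonviable_N`, `nonviable_E`.
#' @param feg_zero_masked Extra zero-inflation for masked viable
#'   eosinophilic visits (corticosteroids also suppress granule shedding).
#' @param p_feg_missing Probability the FEG observation was not recorded
#'   (a degenerated sample without FEG data is indeterminate).
#' @param p_exacerbation Per-visit probability the clinical state is an
#'   exacerbation.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    n_patients = 9570L,
    multi_fraction = 0.31,
    series_extra_geom_prob = 0.3654,
    series_max_length = 40L,
    p_NE = 0.0382,
    p_EN = 0.0500,
    init_state_prob_E = NULL,
    eos_meanlog_N = -0.7232, eos_sdlog_N = 0.1328,
    eos_meanlog_E = 2.8202, eos_sdlog_E = 3.1149,
    eos_cap = 97,
    patient_effect_sd = 0.9763,
    mask_base = 0.0018,
    mask_per_ics1000 = 0.12,
    mask_ocs_on = 0.12,
    mask_neut = 0.018,
    mask_cap = 0.95,
    p_neut_elev_N = 0.40, p_neut_elev_E = 0.30,
    neut_elev_cutoff = 64.4,
    ics_tier_doses = c(0, 250, 500, 1000, 2000),
    ics_tier_probs = c(0.248, 0.10, 0.25, 0.30, 0.102),
    p_ocs = 0.323,
    ocs_tier_doses = c(5, 10, 25, 50),
    ocs_tier_probs = c(0.45, 0.35, 0.15, 0.05),
    p_dose_decrease = 0.15,
    p_nonviable_N = 0.06, p_nonviable_E = 0.20,
    feg_lambda = list(viable_N = 0.024, viable_E_masked = 15.79,
                      viable_E_unmasked = 0.30, nonviable_N = 1.0,
                      nonviable_E = 2.16),
    feg_zero_masked = 0.7341,
    p_feg_missing = 0.02,
    p_exacerbation = 0.12) {
  cfg <- as.list(environment())
  probs <- c(multi_fraction = multi_fraction,
             series_extra_geom_prob = series_extra_geom_prob,
             p_NE = p_NE, p_EN = p_EN,
             mask_base = mask_base, mask_cap = mask_cap,
             p_neut_elev_N = p_neut_elev_N, p_neut_elev_E = p_neut_elev_E,
             p_ocs = p_ocs, p_dose_decrease = p_dose_decrease,
             p_nonviable_N = p_nonviable_N, p_nonviable_E = p_nonviable_E,
             feg_zero_masked = feg_zero_masked,
             p_feg_missing = p_feg_missing,
             p_exacerbation = p_exacerbation)
  if (any(probs < 0 | probs > 1)) {
    stop("Probability parameter(s) outside [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(init_state_prob_E) &&
      (init_state_prob_E < 0 || init_state_prob_E > 1)) {
    stop("`init_state_prob_E` must be in [0, 1] or NULL.", call. = FALSE)
  }
  stopifnot(n_patients >= 1, series_max_length >= 2,
            series_extra_geom_prob > 0,
            eos_sdlog_N > 0, eos_sdlog_E > 0, eos_cap > 0,
            patient_effect_sd >= 0,
            length(ics_tier_doses) == length(ics_tier_probs),
            length(ocs_tier_doses) == length(ocs_tier_probs),
            abs(sum(ics_tier_probs) - 1) < 1e-8,
             abs(sum(ocs_tier_probs) - 1) < 1e-8,
            all(unlist(feg_lambda) >= 0),
            identical(sort(names(feg_lambda)),
                      sort(c("viable_N", "viable_E_masked",
                             "viable_E_unmasked", "nonviable_N",
                             "nonviable_E"))))
  if (p_NE + p_EN <= 0 && is.null(init_state_prob_E)) {
    stop("Chain with p_NE = p_EN = 0 needs an explicit ",
         "`init_state_prob_E`.", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

stationary_prob_E <- function(config) {
  if (!is.null(config$init_state_prob_E) &&
      config$p_NE + config$p_EN <= 0) {
    return(config$init_state_prob_E)
  }
  config$p_NE / (config$p_NE + config$p_EN)
}

config_init_E <- function(config) {
  config$init_state_prob_E %||% stationary_prob_E(config)
}

#' Generate a synthetic longitudinal sputum cohort
#'
#' Simulates the cohort described by a [generator_config()]: per-patient
#' series lengths, a latent eosinophilic state evolving by the configured
#' two-state chain, and conditional observations (intact differential,
#' FEG clump counts, viability, neutrophilia, steroid doses, clinical
#' state). The output is schema-valid (zero rejects under
#' [as_sputum_cohort()]) and byte-identical for identical seed and
#' configuration.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (a validated `sputum_cohort`) and `truth`, a
#'   ground-truth ledger: `samples` (per-visit latent state, masking,
#'   elevated-neutrophil and dose-decrease indicators), `patients`
#'   (series length, patient effect, initial dose tiers) and the `config`
#'   itself, so recovery of the generating parameters can be scored.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n <- config$n_patients
  multi <- runif(n) < config$multi_fraction
  len <- rep(1L, n)
  len[multi] <- pmin(2L + rgeom(sum(multi), config$series_extra_geom_prob),
                     config$series_max_length)
  start <- cumsum(c(1L, head(len, -1)))
  n_rows <- sum(len)
  row_patient <- rep(seq_len(n), len)
  row_visit <- sequence(len)

  patient_effect <- rnorm(n, 0, config$patient_effect_sd)
  ics_tier0 <- sample.int(length(config$ics_tier_doses), n, replace = TRUE,
                          prob = config$ics_tier_probs)
  on_ocs <- runif(n) < config$p_ocs
  ocs_tier0 <- ifelse(on_ocs,
                      sample.int(length(config$ocs_tier_doses), n,
                                 replace = TRUE,
                                 prob = config$ocs_tier_probs), 0L)

  # latent chain and dose trajectories, iterated over visit index
  latent_E <- logical(n_rows)
  dose_dec <- logical(n_rows)
  ics_tier <- integer(n_rows)
  ocs_tier <- integer(n_rows)
  cur_state <- runif(n) < config_init_E(config)
  cur_ics <- ics_tier0
  cur_ocs <- ocs_tier0
  max_len <- max(len)
  for (t in seq_len(max_len)) {
    active <- which(len >= t)
    if (t > 1) {
      u <- runif(length(active))
      s <- cur_state[active]
      cur_state[active] <- ifelse(s, u >= config$p_EN, u < config$p_NE)
      dec <- runif(length(active)) < config$p_dose_decrease
      cur_ics[active] <- pmax(cur_ics[active] - dec, 1L)
      cur_ocs[active] <- pmax(cur_ocs[active] - dec, 0L)
      dose_dec[start[active] + t - 1L] <- dec &
        (ics_tier[start[active] + t - 2L] > 1L |
           ocs_tier[start[active] + t - 2L] > 0L)
    }
    idx <- start[active] + t - 1L
    latent_E[idx] <- cur_state[active]
    ics_tier[idx] <- cur_ics[active]
    ocs_tier[idx] <- cur_ocs[active]
  }
  ics_dose <- config$ics_tier_doses[ics_tier]
  ocs_dose <- ifelse(ocs_tier == 0L, 0, config$ocs_tier_doses[ocs_tier])

  # per-visit covariates and masking
  p_ne <- ifelse(latent_E, config$p_neut_elev_E, config$p_neut_elev_N)
  neut_elev <- runif(n_rows) < p_ne
  p_mask <- pmin(config$mask_cap,
                 config$mask_base +
                   config$mask_per_ics1000 * ics_dose / 1000 +
                   config$mask_ocs_on * (ocs_dose > 0) +
                   config$mask_neut * neut_elev)
  masked <- latent_E & (runif(n_rows) < p_mask)

  nonviable <- runif(n_rows) < ifelse(latent_E, config$p_nonviable_E,
                                      config$p_nonviable_N)
  viable <- !nonviable

  # observed intact eosinophil % (viable samples only)
  use_N_dist <- !latent_E | masked
  u_eff <- patient_effect[row_patient]
  eos <- rlnorm(n_rows,
                ifelse(use_N_dist, config$eos_meanlog_N,
                       config$eos_meanlog_E) + u_eff,
                ifelse(use_N_dist, config$eos_sdlog_N, config$eos_sdlog_E))
  eos <- round(pmin(eos, config$eos_cap), 1)

  # remaining differential: neutrophil share of what eosinophils leave,
  # macrophage absorbing most of the rest, small lymphocyte/epithelial tail
  rem <- 100 - eos
  neut_share <- ifelse(neut_elev, runif(n_rows, 0.70, 0.98),
                       rbeta(n_rows, 5, 3))
  neut <- round(rem * neut_share, 1)
  rem2 <- 100 - eos - neut
  mac <- rem2 * rbeta(n_rows, 25, 2)
  lym <- round((rem2 - mac) * rbeta(n_rows, 4, 2), 1)
  bec <- round(pmax(rem2 - mac - lym, 0), 1)
  mac <- round(100 - eos - neut - lym - bec, 1)
  fix <- mac < 0
  neut[fix] <- neut[fix] + mac[fix]
  mac[fix] <- 0

  # FEG clump counts
  lam <- numeric(n_rows)
  lam[viable & !latent_E] <- config$feg_lambda$viable_N
  lam[viable & latent_E & masked] <- config$feg_lambda$viable_E_masked
  lam[viable & latent_E & !masked] <- config$feg_lambda$viable_E_unmasked
  lam[nonviable & !latent_E] <- config$feg_lambda$nonviable_N
  lam[nonviable & latent_E] <- config$feg_lambda$nonviable_E
  clumps <- rpois(n_rows, lam)
  zi <- viable & latent_E & masked &
    (runif(n_rows) < config$feg_zero_masked)
  clumps[zi] <- 0L
  feg_missing <- runif(n_rows) < config$p_feg_missing
  clumps[feg_missing] <- NA_integer_

  # examination dates: per-patient baseline plus >= 30-day gaps
  base_date <- as.Date("2004-07-01") + sample.int(5500, n, replace = TRUE)
  gaps <- round(runif(n_rows, 30, 400))
  date_offset <- unlist(lapply(seq_len(n), function(i) {
    k <- len[i]
    if (k == 1) 0 else cumsum(c(0, gaps[start[i] + seq_len(k - 1) - 1]))
  }), use.names = FALSE)
  exam_date <- base_date[row_patient] + date_offset

  cohort_df <- tibble::tibble(
    patient_id = sprintf("P%05d", row_patient),
    exam_date = exam_date,
    total_cell_count_e6_per_g =
      round(pmin(pmax(rlnorm(n_rows, log(6), 1.0), 0.1), 398.1), 1),
    viability_pct = round(rbeta(n_rows, 5, 1.7) * 100, 1),
    squamous_pct = round(rbeta(n_rows, 1.2, 8) * 100, 1),
    differential_viable = viable,
    neutrophil_pct = ifelse(viable, neut, NA_real_),
    eosinophil_pct = ifelse(viable, eos, NA_real_),
    macrophage_pct = ifelse(viable, mac, NA_real_),
    lymphocyte_pct = ifelse(viable, lym, NA_real_),
    bronchial_epithelial_pct = ifelse(viable, bec, NA_real_),
    feg_clumps_per_fov = clumps,
    feg_grade = as.character(grade_feg(clumps)),
    ics_dose_mcg = ics_dose,
    ocs_dose_mg = ocs_dose,
    clinical_state = ifelse(runif(n_rows) < config$p_exacerbation,
                            "exacerbation", "stable")
  )
  cohort <- suppressWarnings(as_sputum_cohort(cohort_df))
  if (nrow(rejects(cohort)) > 0) {
    stop("Internal error: generator produced ", nrow(rejects(cohort)),
         " schema-invalid rows.", call. = FALSE)
  }
  truth_samples <- tibble::tibble(
    patient_id = sprintf("P%05d", row_patient),
    visit = row_visit,
    latent_E = latent_E,
    masked = masked,
    neut_elevated = neut_elev,
    dose_decreased = dose_dec,
    nonviable = nonviable
  )
  truth_patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    n_samples = len,
    patient_effect = patient_effect,
    ics_tier0 = ics_tier0,
    ocs_tier0 = ocs_tier0
  )
  list(cohort = cohort,
       truth = list(samples = truth_samples, patients = truth_patients,
                    config = config))
}

#' Write generator outputs to disk
#'
#' @param generated Result of [generate_cohort()].
#' @param cohort_path CSV path for the cohort.
#' @param truth_path Optional JSON path for the ground-truth ledger.
#' @param config_path Optional JSON path for the (round-trippable)
#'   configuration.
#' @return `cohort_path`, invisibly.
#' @export
write_generated <- function(generated, cohort_path, truth_path = NULL,
                            config_path = NULL) {
  write_cohort(generated$cohort, cohort_path)
  if (!is.null(truth_path)) {
    jsonlite::write_json(
      list(samples = generated$truth$samples,
           patients = generated$truth$patients),
      truth_path, digits = NA, null = "null")
  }
  if (!is.null(config_path)) {
    jsonlite::write_json(unclass(generated$truth$config), config_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(cohort_path)
}

#' Read a generator configuration back from JSON
#'
#' @param path JSON path written by [write_generated()].
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$feg_lambda <- as.list(x$feg_lambda)
  do.call(generator_config, x)
}
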