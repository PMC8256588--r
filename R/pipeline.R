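#' Run the full staged prevalence analysis
#'
#' Wires the stages together for one cohort: descriptive summary,
#' per-threshold classification tallies, re-emergence summary with
#' etiology breakdown, staged prevalence estimate, two-state transition
#' model, and the nested Euler-diagram composition. Cohorts with no
#' multi-sample patients get the single-sample stages only, with the
#' extrapolation and Markov stages marked not estimable.
#'
#' @param cohort A `sputum_cohort`, or a [generator_config()] (in which
#'   case the cohort is simulated first).
#' @param thresholds List of [threshold_spec] objects (default: the 1.2%
#'   and 2.3% specifications).
#' @param tally_mode `"nested"` or `"paper_tally"`; see
#'   [estimate_prevalence()].
#' @param neutrophil_cutoff,indeterminate_rule Passed to the emergence
#'   stage.
#' @return An `eos_analysis` list: `cohort_summary`, `multiplicity`
#'   (patient/sample counts by part) and one entry per threshold under
#'   `thresholds`, each holding `tallies`, `emergence` (or `NULL`),
#'   `prevalence`, `markov` (or `NULL`) and `euler`. A `manifest` records
#'   the parameters (and generator seed, when simulated).
#' @export
run_full_analysis <- function(cohort,
                              thresholds = default_thresholds(),
                              tally_mode = c("nested", "paper_tally"),
                              neutrophil_cutoff = 64.4,
                              indeterminate_rule = "skip") {
  tally_mode <- match.arg(tally_mode)
  seed <- NULL
  if (inherits(cohort, "generator_config")) {
    seed <- cohort$seed
    cohort <- generate_cohort(cohort)$cohort
  }
  parts <- split_by_multiplicity(cohort)
  has_multi <- nrow(parts$multi) > 0

  th_results <- lapply(thresholds, function(spec) {
    cls <- classify_cohort(cohort, spec, mode = "with_feg")
    emergence <- if (has_multi) {
      summarize_emergence(cohort, spec, neutrophil_cutoff,
                          indeterminate_rule)
    }
    prevalence <- estimate_prevalence(
      cohort, spec, tally_mode = tally_mode,
      neutrophil_cutoff = neutrophil_cutoff,
      indeterminate_rule = indeterminate_rule,
      emergence_fraction = if (has_multi)
        emergence$summary$fraction_patients else NULL)
    markov <- if (has_multi) {
      calls_multi <- dplyr::semi_join(
        cls$calls, tibble::tibble(patient_id = unique(parts$multi$patient_id)),
        by = "patient_id")
      estimate_transitions(calls_multi)
    }
    list(threshold = spec,
         tallies = cls$tallies,
         emergence = emergence,
         prevalence = prevalence,
         markov = markov,
         euler = euler_composition(prevalence))
  })
  names(th_results) <- vapply(thresholds, `[[`, character(1), "name")

  structure(
    list(cohort_summary = summarize_cohort(cohort),
         multiplicity = parts$counts,
         thresholds = th_results,
         manifest = list(
           n_samples = nrow(cohort),
           n_patients = dplyr::n_distinct(cohort$patient_id),
           tally_mode = tally_mode,
           neutrophil_cutoff = neutrophil_cutoff,
           indeterminate_rule = indeterminate_rule,
           extrapolation_estimable = has_multi,
           generator_seed = seed,
           package_version = as.character(utils::packageVersion("eosmask"))
         )),
    class = "eos_analysis"
  )
}

#' @export
print.eos_analysis <- function(x, ...) {
  cat("<eos_analysis> ", x$manifest$n_samples, " samples, ",
      x$manifest$n_patients, " patients (", x$manifest$tally_mode,
      " tallies)\n", sep = "")
  for (th in x$thresholds) {
    cat("\n")
    print(th$prevalence)
    if (!is.null(th$emergence)) {
      s <- th$emergence$summary
      cat(sprintf(
        "  emergence: %d/%d patients (%.1f%%), %.3f events/patient\n",
        s$n_patients_with_event, s$n_multi_patients,
        100 * s$fraction_patients, s$events_per_patient))
    } else {
      cat("  emergence/extrapolation/Markov: not estimable ",
          "(no multi-sample patients)\n", sep = "")
    }
    if (!is.null(th$markov) && !is.na(th$markov$stationary["E"])) {
      cat(sprintf("  Markov: p_NE = %.3f, p_EN = %.3f, pi_E = %.3f\n",
                  th$markov$p_NE, th$markov$p_EN,
                  th$markov$stationary["E"]))
    }
  }
  invisible(x)
}
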