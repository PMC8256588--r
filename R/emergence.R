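#' Detect re-emergence events in one patient's call sequence
#'
#' Re-emergence (unmasking) of eosinophilia is a consecutive pair of
#' examinations in which the initial sample is non-eosinophilic and the
#' subsequent one eosinophilic. All consecutive pairs (i, i+1) are scanned,
#' so a patient with several examinations can contribute several events —
#' e.g. between the first and second samples and again between the fourth
#' and fifth.
#'
#' @param eosinophilic Logical vector of per-sample calls in examination
#'   order.
#' @param indeterminate Logical vector flagging indeterminate samples (no
#'   intact differential and no FEG observation); default none.
#' @param indeterminate_rule `"skip"` (default): any pair containing an
#'   indeterminate sample is excluded from scanning; `"negative"`:
#'   indeterminate samples count as non-eosinophilic on the initial side
#'   (they can never supply the eosinophilic side, since their call is
#'   non-eosinophilic by construction).
#' @return Tibble with `initial_idx` and `subsequent_idx` (positions in the
#'   sequence), zero rows for sequences shorter than 2.
#' @examples
#' detect_events(c(FALSE, TRUE, FALSE, FALSE, TRUE))  # two events
#' @export
detect_events <- function(eosinophilic,
                          indeterminate = rep(FALSE, length(eosinophilic)),
                          indeterminate_rule = c("skip", "negative")) {
  indeterminate_rule <- match.arg(indeterminate_rule)
  stopifnot(is.logical(eosinophilic), !anyNA(eosinophilic),
            length(indeterminate) == length(eosinophilic))
  n <- length(eosinophilic)
  if (n < 2) {
    return(tibble::tibble(initial_idx = integer(), subsequent_idx = integer()))
  }
  i <- seq_len(n - 1)
  hit <- !eosinophilic[i] & eosinophilic[i + 1]
  if (indeterminate_rule == "skip") {
    hit <- hit & !indeterminate[i] & !indeterminate[i + 1]
  } else {
    hit <- hit & !indeterminate[i + 1]
  }
  tibble::tibble(initial_idx = i[hit], subsequent_idx = i[hit] + 1L)
}

#' Attribute the suspected etiology of a re-emergence event
#'
#' If the sputum neutrophil differential was elevated in the initial
#' sample, the event is attributed to treatment of bacterial bronchitis
#' (resolution of masking neutrophilia); if the oral or inhaled
#' corticosteroid dose was lower at the subsequent examination, to a
#' decrease in corticosteroid therapy; both conditions give the combined
#' category, neither gives a flare of eosinophilic inflammation. Missing
#' neutrophil or dose data make the corresponding condition
#' indeterminate-false (flagged, never guessed).
#'
#' @param initial,subsequent One-row data frames or lists carrying
#'   `neutrophil_pct`, `ics_dose_mcg`, `ocs_dose_mg` for the two samples.
#' @param neutrophil_cutoff Percent above which the initial neutrophil
#'   differential counts as elevated (default 64.4, a conventional upper
#'   normal for sputum neutrophils).
#' @return List with `etiology` (one of
#'   `neutrophilia_and_steroid_decrease`, `neutrophilia_treated`,
#'   `steroid_decrease`, `flare`), the two condition booleans and
#'   `conditions_known` audit flags.
#' @export
attribute_etiology <- function(initial, subsequent, neutrophil_cutoff = 64.4) {
  res <- attribute_etiology_vec(
    initial_neut = as.numeric(initial$neutrophil_pct %||% NA),
    ics_initial = as.numeric(initial$ics_dose_mcg %||% NA),
    ocs_initial = as.numeric(initial$ocs_dose_mg %||% NA),
    ics_subsequent = as.numeric(subsequent$ics_dose_mcg %||% NA),
    ocs_subsequent = as.numeric(subsequent$ocs_dose_mg %||% NA),
    neutrophil_cutoff = neutrophil_cutoff
  )
  lapply(res, `[[`, 1)
}

etiology_levels <- c("neutrophilia_and_steroid_decrease",
                     "neutrophilia_treated", "steroid_decrease", "flare")

attribute_etiology_vec <- function(initial_neut, ics_initial, ocs_initial,
                                   ics_subsequent, ocs_subsequent,
                                   neutrophil_cutoff) {
  neut_known <- !is.na(initial_neut)
  neut_elev <- neut_known & initial_neut > neutrophil_cutoff
  ocs_known <- !is.na(ocs_initial) & !is.na(ocs_subsequent)
  ics_known <- !is.na(ics_initial) & !is.na(ics_subsequent)
  dose_dec <- (ocs_known & ocs_subsequent < ocs_initial) |
    (ics_known & ics_subsequent < ics_initial)
  etiology <- dplyr::case_when(
    neut_elev & dose_dec ~ etiology_levels[1],
    neut_elev ~ etiology_levels[2],
    dose_dec ~ etiology_levels[3],
    TRUE ~ etiology_levels[4]
  )
  list(etiology = etiology,
       neutrophilia_at_initial = neut_elev,
       steroid_decreased = dose_dec,
       neutrophil_known = neut_known,
       dose_known = ocs_known | ics_known)
}

#' Find all re-emergence events in a cohort
#'
#' Classifies every sample under the with-FEG rule at `spec`, scans each
#' multi-sample patient's consecutive pairs with [detect_events()], and
#' attributes each event's suspected etiology.
#'
#' @param cohort A `sputum_cohort` (any mix of single- and multi-sample
#'   patients; singletons contribute nothing).
#' @param spec A [threshold_spec].
#' @param neutrophil_cutoff Passed to [attribute_etiology()].
#' @param indeterminate_rule Passed to [detect_events()].
#' @return Tibble of events: patient, row ids and dates of the initial and
#'   subsequent samples, threshold name, condition booleans, audit flags
#'   and etiology.
#' @export
find_emergence <- function(cohort, spec, neutrophil_cutoff = 64.4,
                           indeterminate_rule = c("skip", "negative")) {
  indeterminate_rule <- match.arg(indeterminate_rule)
  df <- tibble::as_tibble(cohort)
  if (!"row_id" %in% names(df)) df$row_id <- seq_len(nrow(df))
  cls <- classify_cohort(df, spec, mode = "with_feg")
  calls <- cls$calls

  # scan per patient over examination order (cohort is already date-sorted)
  split_idx <- split(seq_len(nrow(df)), df$patient_id)
  ev_list <- lapply(split_idx, function(idx) {
    if (length(idx) < 2) return(NULL)
    ev <- detect_events(calls$eosinophilic[idx], calls$indeterminate[idx],
                        indeterminate_rule = indeterminate_rule)
    if (nrow(ev) == 0) return(NULL)
    tibble::tibble(i = idx[ev$initial_idx], j = idx[ev$subsequent_idx])
  })
  ev <- dplyr::bind_rows(ev_list)
  if (nrow(ev) == 0) {
    return(tibble::tibble(
      patient_id = character(), initial_row_id = integer(),
      subsequent_row_id = integer(), initial_date = as.Date(character()),
      subsequent_date = as.Date(character()), threshold_name = character(),
      neutrophilia_at_initial = logical(), steroid_decreased = logical(),
      neutrophil_known = logical(), dose_known = logical(),
      etiology = character()
    ))
  }
  att <- attribute_etiology_vec(
    initial_neut = df$neutrophil_pct[ev$i],
    ics_initial = df$ics_dose_mcg[ev$i],
    ocs_initial = df$ocs_dose_mg[ev$i],
    ics_subsequent = df$ics_dose_mcg[ev$j],
    ocs_subsequent = df$ocs_dose_mg[ev$j],
    neutrophil_cutoff = neutrophil_cutoff
  )
  tibble::tibble(
    patient_id = df$patient_id[ev$i],
    initial_row_id = df$row_id[ev$i],
    subsequent_row_id = df$row_id[ev$j],
    initial_date = df$exam_date[ev$i],
    subsequent_date = df$exam_date[ev$j],
    threshold_name = spec$name,
    neutrophilia_at_initial = att$neutrophilia_at_initial,
    steroid_decreased = att$steroid_decreased,
    neutrophil_known = att$neutrophil_known,
    dose_known = att$dose_known,
    etiology = att$etiology
  )
}

#' Summarize re-emergence over the multi-sample part of a cohort
#'
#' @inheritParams find_emergence
#' @return List with `events` (the [find_emergence()] table restricted to
#'   multi-sample patients), `summary` (a one-row tibble:
#'   `n_multi_patients`, `n_patients_with_event`, `fraction_patients`,
#'   `n_events`, `events_per_patient`, `neutrophil_cutoff`) and
#'   `etiology_breakdown` (mutually exclusive event-level counts and
#'   fractions over [etiology categories][attribute_etiology]).
#' @export
summarize_emergence <- function(cohort, spec, neutrophil_cutoff = 64.4,
                                indeterminate_rule = c("skip", "negative")) {
  indeterminate_rule <- match.arg(indeterminate_rule)
  parts <- split_by_multiplicity(cohort)
  multi <- parts$multi
  if (nrow(multi) == 0) {
    stop("No multi-sample patients: emergence is not estimable.",
         call. = FALSE)
  }
  events <- find_emergence(multi, spec, neutrophil_cutoff,
                           indeterminate_rule)
  n_multi <- dplyr::n_distinct(multi$patient_id)
  n_with <- dplyr::n_distinct(events$patient_id)
  breakdown <- tibble::tibble(etiology = etiology_levels) |>
    dplyr::left_join(dplyr::count(events, .data$etiology), by = "etiology") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = if (nrow(events) > 0) .data$n / nrow(events)
                             else NA_real_)
  list(
    events = events,
    summary = tibble::tibble(
      threshold_name = spec$name,
      n_multi_patients = n_multi,
      n_patients_with_event = n_with,
      fraction_patients = n_with / n_multi,
      n_events = nrow(events),
      events_per_patient = nrow(events) / n_multi,
      neutrophil_cutoff = neutrophil_cutoff
    ),
    etiology_breakdown = breakdown
  )
}
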