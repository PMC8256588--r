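#' Classify every sample in a cohort at a threshold
#'
#' A sample is called eosinophilic when its intact eosinophil differential
#' meets the threshold cutoff, or (under the default `with_feg` rule) when
#' its free-eosinophil-granule grade is in the threshold's qualifying set —
#' which is how samples too degenerated for an intact differential can
#' still be classified. A sample with neither an intact differential nor
#' any FEG observation is indeterminate: it is called non-eosinophilic and
#' flagged.
#'
#' @param cohort A `sputum_cohort` (or compatible tibble with a `row_id`).
#' @param spec A [threshold_spec].
#' @param mode `"with_feg"` (default) or `"intact_only"` (FEG disjunct
#'   disabled; the intact-only prevalence tier).
#' @return List with `calls` (one row per sample: `row_id`, `patient_id`,
#'   `exam_date`, `threshold_name`, `eosinophilic`, `basis`,
#'   `intact_available`, `indeterminate`) and `tallies` (see
#'   [classification_tallies()]).
#' @export
classify_cohort <- function(cohort, spec,
                            mode = c("with_feg", "intact_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "threshold_spec"))
  df <- tibble::as_tibble(cohort)
  if (!"row_id" %in% names(df)) df$row_id <- seq_len(nrow(df))
  if (!"patient_id" %in% names(df)) df$patient_id <- NA_character_
  if (!"exam_date" %in% names(df)) df$exam_date <- as.Date(NA)

  viable <- df$differential_viable %in% TRUE
  eos <- df$eosinophil_pct
  intact_pos <- viable & !is.na(eos) & intact_meets(eos, spec)
  feg_qual <- !is.na(df$feg_grade) &
    as.character(df$feg_grade) %in% spec$qualifying_feg_grades
  if (mode == "intact_only") feg_qual <- rep(FALSE, nrow(df))

  eosinophilic <- intact_pos | feg_qual
  basis <- dplyr::case_when(
    intact_pos & feg_qual ~ "intact_and_feg",
    intact_pos ~ "intact_count",
    feg_qual ~ "feg_only",
    TRUE ~ "none"
  )
  indeterminate <- !viable & is.na(df$feg_grade)

  calls <- tibble::tibble(
    row_id = df$row_id,
    patient_id = df$patient_id,
    exam_date = df$exam_date,
    threshold_name = spec$name,
    eosinophilic = eosinophilic,
    basis = basis,
    intact_available = viable,
    indeterminate = indeterminate
  )
  list(calls = calls,
       tallies = classification_tallies(df, calls, spec, mode))
}

#' Category tallies behind a cohort classification
#'
#' The counts that feed prevalence composition: intact-positive samples;
#' samples with an intact differential below the cutoff but qualifying FEG;
#' samples without an intact differential but qualifying FEG (split into
#' few vs moderate/many); nonviable-differential samples by raw grade
#' regardless of the qualifying set (the inputs to the printed-arithmetic
#' tally mode); and indeterminate samples.
#'
#' @param df Cohort tibble.
#' @param calls Calls tibble from [classify_cohort()].
#' @param spec The [threshold_spec] used.
#' @param mode Classification mode used.
#' @return A one-row tibble of counts.
#' @keywords internal
classification_tallies <- function(df, calls, spec, mode) {
  viable <- calls$intact_available
  grade <- as.character(df$feg_grade)
  feg_qual <- !is.na(grade) & grade %in% spec$qualifying_feg_grades
  intact_pos <- calls$basis %in% c("intact_count", "intact_and_feg")
  tibble::tibble(
    threshold_name = spec$name,
    mode = mode,
    n_total = nrow(df),
    n_intact_pos = sum(intact_pos),
    n_feg_with_diff = if (mode == "with_feg")
      sum(viable & !intact_pos & feg_qual) else 0L,
    n_feg_no_diff = if (mode == "with_feg")
      sum(!viable & feg_qual) else 0L,
    n_feg_no_diff_few = if (mode == "with_feg")
      sum(!viable & feg_qual & grade == "few") else 0L,
    n_feg_no_diff_modmany = if (mode == "with_feg")
      sum(!viable & feg_qual & grade %in% c("moderate", "many")) else 0L,
    n_nonviable_few = sum(!viable & !is.na(grade) & grade == "few"),
    n_nonviable_modmany = sum(!viable & !is.na(grade) &
                                grade %in% c("moderate", "many")),
    n_indeterminate = sum(calls$indeterminate),
    n_eosinophilic = sum(calls$eosinophilic)
  )
}

#' Classify a single sputum sample
#'
#' @param sample A one-row data frame (or list coercible to one) with the
#'   cohort columns used for classification: `differential_viable`,
#'   `eosinophil_pct`, `feg_grade` (label or ordered factor) and/or
#'   `feg_clumps_per_fov`.
#' @param spec A [threshold_spec].
#' @param mode `"with_feg"` or `"intact_only"`.
#' @return One-row calls tibble (see [classify_cohort()]).
#' @examples
#' s <- list(differential_viable = TRUE, eosinophil_pct = 2.0,
#'           feg_clumps_per_fov = 1L)
#' classify_sample(s, threshold_abnormal())$eosinophilic
#' classify_sample(s, threshold_clinical())$eosinophilic
#' @export
classify_sample <- function(sample, spec, mode = c("with_feg", "intact_only")) {
  mode <- match.arg(mode)
  df <- tibble::as_tibble(as.list(sample)[!vapply(sample, is.null,
                                                  logical(1))])
  for (col in c("differential_viable", "eosinophil_pct", "feg_grade",
                "feg_clumps_per_fov", "patient_id", "exam_date")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  if (all(is.na(df$feg_grade)) && !all(is.na(df$feg_clumps_per_fov))) {
    df$feg_grade <- grade_feg(df$feg_clumps_per_fov)
  } else {
    df$feg_grade <- as_feg_grade(df$feg_grade)
  }
  classify_cohort(df, spec, mode = mode)$calls
}

#' @rdname classify_sample
#' @export
classify_intact_only <- function(sample, spec) {
  classify_sample(sample, spec, mode = "intact_only")
}
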