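#' Column schema for longitudinal sputum cytometry records
#'
#' One row per sputum examination. Percentages are on the 0--100 scale,
#' total cell count in 10^6 cells per gram, inhaled corticosteroid (ICS)
#' dose in fluticasone-equivalent micrograms per day and oral
#' corticosteroid (OCS) dose in milligrams per day. The five differential
#' percentages (neutrophil, eosinophil, macrophage, lymphocyte, bronchial
#' epithelial) are present only when an intact cell differential could be
#' made (`differential_viable`); otherwise only the free-eosinophil-granule
#' (FEG) observation is available.
#'
#' @format Character vector of required column names.
#' @export
cohort_schema <- c(
  "patient_id", "exam_date", "total_cell_count_e6_per_g", "viability_pct",
  "squamous_pct", "differential_viable", "neutrophil_pct", "eosinophil_pct",
  "macrophage_pct", "lymphocyte_pct", "bronchial_epithelial_pct",
  "feg_clumps_per_fov", "feg_grade", "ics_dose_mcg", "ocs_dose_mg",
  "clinical_state"
)

differential_cols <- c("neutrophil_pct", "eosinophil_pct", "macrophage_pct",
                       "lymphocyte_pct", "bronchial_epithelial_pct")

clinical_states <- c("stable", "exacerbation", "unknown")

new_sputum_cohort <- function(samples, rejects) {
  structure(samples, rejects = rejects,
            class = c("sputum_cohort", class(tibble::tibble())))
}

#' @export
print.sputum_cohort <- function(x, ...) {
  nrej <- nrow(attr(x, "rejects") %||% tibble::tibble())
  cat("<sputum_cohort> ", nrow(x), " samples from ",
      dplyr::n_distinct(x$patient_id), " patients",
      if (nrej > 0) paste0(" (", nrej, " rejected rows; see rejects())"),
      "\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rejected rows of a validated cohort
#'
#' Rows that failed validation during [read_cohort()] or
#' [as_sputum_cohort()] are retained, not silently dropped; each carries a
#' `reject_reason`.
#'
#' @param cohort A `sputum_cohort`.
#' @return Tibble of rejected input rows with a `reject_reason` column.
#' @export
rejects <- function(cohort) {
  attr(cohort, "rejects") %||%
    tibble::tibble(reject_reason = character())
}

#' Validate in-memory sputum records into a cohort
#'
#' Applies per-row validation (range checks, differential-percentage sum,
#' FEG grade/count consistency, date parsing), separates failing rows into
#' a rejects table, orders each patient's samples by examination date
#' (stable with respect to input order; ties generate a warning), and
#' derives the ordinal `feg_grade` from `feg_clumps_per_fov` where only the
#' count was supplied.
#'
#' @param df Data frame with the columns of [cohort_schema].
#' @param pct_sum_tol Tolerance on the differential-percentage sum around
#'   100 (default 0.5, accommodating rounding in source data).
#' @return A `sputum_cohort`: a tibble of valid samples (with `feg_grade`
#'   as an ordered factor and a `row_id` key) carrying the rejects table as
#'   an attribute (see [rejects()]).
#' @export
as_sputum_cohort <- function(df, pct_sum_tol = 0.5) {
  missing_cols <- setdiff(cohort_schema, names(df))
  if (length(missing_cols) > 0) {
    stop("Input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[cohort_schema]
  n <- nrow(df)
  reasons <- vector("list", n)
  add_reason <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }

  pid_bad <- is.na(df$patient_id) | !nzchar(as.character(df$patient_id))
  add_reason(pid_bad, "missing patient_id")

  dates <- df$exam_date
  if (!inherits(dates, "Date")) {
    dates <- suppressWarnings(as.Date(as.character(df$exam_date),
                                      format = "%Y-%m-%d"))
  }
  add_reason(is.na(dates) & !pid_bad, "unparseable exam_date")

  num_in <- function(x, lo, hi) is.na(x) | (!is.na(x) & x >= lo & x <= hi)
  add_reason(!num_in(df$total_cell_count_e6_per_g, 0, Inf),
             "negative total_cell_count_e6_per_g")
  add_reason(!num_in(df$viability_pct, 0, 100), "viability_pct outside [0,100]")
  add_reason(!num_in(df$squamous_pct, 0, 100), "squamous_pct outside [0,100]")
  add_reason(!num_in(df$ics_dose_mcg, 0, Inf), "negative ics_dose_mcg")
  add_reason(!num_in(df$ocs_dose_mg, 0, Inf), "negative ocs_dose_mg")

  dv <- df$differential_viable
  if (!is.logical(dv)) dv <- as.logical(dv)
  add_reason(is.na(dv), "differential_viable missing or not logical")

  diff_mat <- as.matrix(df[differential_cols])
  any_diff_present <- rowSums(!is.na(diff_mat)) > 0
  all_diff_present <- rowSums(is.na(diff_mat)) == 0
  viable <- !is.na(dv) & dv

  add_reason(viable & !all_diff_present,
             "differential_viable but differential percentages incomplete")
  in_range <- diff_mat >= 0 & diff_mat <= 100
  range_ok <- rowSums(!in_range, na.rm = TRUE) == 0
  add_reason(viable & all_diff_present & !range_ok,
             "differential percentage outside [0,100]")
  sums <- rowSums(diff_mat)
  add_reason(viable & all_diff_present & range_ok &
               abs(sums - 100) > pct_sum_tol,
             sprintf("differential percentages do not sum to 100 +/- %g",
                     pct_sum_tol))
  add_reason(!is.na(dv) & !dv & any_diff_present,
             "differential percentages present but differential_viable is false")

  clumps <- df$feg_clumps_per_fov
  clumps_bad <- !is.na(clumps) &
    (!is.numeric(clumps) | clumps < 0 | clumps != floor(clumps))
  add_reason(clumps_bad, "feg_clumps_per_fov not a non-negative integer")

  grade_chr <- as.character(df$feg_grade)
  grade_bad <- !is.na(grade_chr) & !(grade_chr %in% feg_levels)
  add_reason(grade_bad, "feg_grade not one of none/few/moderate/many")

  both <- !is.na(clumps) & !clumps_bad & !is.na(grade_chr) & !grade_bad
  derived <- rep(NA_character_, n)
  if (any(!is.na(clumps) & !clumps_bad)) {
    idx <- !is.na(clumps) & !clumps_bad
    derived[idx] <- as.character(grade_feg(clumps[idx]))
  }
  add_reason(both & derived != grade_chr,
             "feg_grade inconsistent with feg_clumps_per_fov")

  state_chr <- as.character(df$clinical_state)
  state_bad <- !is.na(state_chr) & !(state_chr %in% clinical_states)
  add_reason(state_bad, "clinical_state not one of stable/exacerbation/unknown")

  bad <- !vapply(reasons, is.null, logical(1))
  rejects <- df[bad, , drop = FALSE]
  if (nrow(rejects) > 0) {
    rejects$reject_reason <- vapply(reasons[bad], paste, character(1),
                                    collapse = "; ")
  } else {
    rejects$reject_reason <- character(0)
  }

  ok <- df[!bad, , drop = FALSE]
  ok$exam_date <- dates[!bad]
  ok$differential_viable <- dv[!bad]
  grade_final <- ifelse(is.na(grade_chr[!bad]), derived[!bad],
                        grade_chr[!bad])
  ok$feg_grade <- factor(grade_final, levels = feg_levels, ordered = TRUE)
  ok$clinical_state <- ifelse(is.na(state_chr[!bad]), "unknown",
                              state_chr[!bad])

  # stable sort: date within patient, input order breaking ties
  ok$.input_order <- seq_len(nrow(ok))
  ok <- dplyr::arrange(ok, .data$patient_id, .data$exam_date,
                       .data$.input_order)
  tied <- dplyr::group_by(ok, .data$patient_id, .data$exam_date)
  tied <- dplyr::filter(tied, dplyr::n() > 1)
  if (nrow(tied) > 0) {
    warning("Same-day examinations for ",
            dplyr::n_distinct(tied$patient_id),
            " patient(s); input order retained within ties.", call. = FALSE)
  }
  ok$.input_order <- NULL
  ok$row_id <- seq_len(nrow(ok))
  new_sputum_cohort(ok, rejects)
}

#' Read a longitudinal sputum cohort from CSV
#'
#' Expects the header of [cohort_schema] (UTF-8, ISO-8601 dates). Rows are
#' validated and grouped into per-patient date-ordered series; failing rows
#' are collected into a rejects table rather than dropped.
#'
#' @param path Path to a CSV file.
#' @param pct_sum_tol Passed to [as_sputum_cohort()].
#' @return A `sputum_cohort`.
#' @export
read_cohort <- function(path, pct_sum_tol = 0.5) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      exam_date = readr::col_date(format = "%Y-%m-%d"),
      total_cell_count_e6_per_g = readr::col_double(),
      viability_pct = readr::col_double(),
      squamous_pct = readr::col_double(),
      differential_viable = readr::col_logical(),
      neutrophil_pct = readr::col_double(),
      eosinophil_pct = readr::col_double(),
      macrophage_pct = readr::col_double(),
      lymphocyte_pct = readr::col_double(),
      bronchial_epithelial_pct = readr::col_double(),
      feg_clumps_per_fov = readr::col_integer(),
      feg_grade = readr::col_character(),
      ics_dose_mcg = readr::col_double(),
      ocs_dose_mg = readr::col_double(),
      clinical_state = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(cohort_schema, names(df))
  if (length(missing_cols) > 0) {
    stop("CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_sputum_cohort(df, pct_sum_tol = pct_sum_tol)
}

#' Write a cohort (and optionally its rejects) back to CSV
#'
#' @param cohort A `sputum_cohort`.
#' @param path Output CSV path for the valid samples.
#' @param rejects_path Optional CSV path for the rejects report (with its
#'   `reject_reason` column).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, rejects_path = NULL) {
  out <- tibble::as_tibble(cohort)[cohort_schema]
  out$feg_grade <- as.character(out$feg_grade)
  readr::write_csv(out, path, na = "")
  if (!is.null(rejects_path)) {
    readr::write_csv(rejects(cohort), rejects_path, na = "")
  }
  invisible(path)
}

#' Split a cohort by sampling multiplicity
#'
#' Partitions patients into those with a single sputum examination and
#' those examined on two or more occasions; the longitudinal (emergence and
#' Markov) analyses operate on the multi-sample part only.
#'
#' @param cohort A `sputum_cohort` (or compatible tibble).
#' @return List with `single` and `multi` cohort tibbles and a `counts`
#'   tibble of patients and samples in each part.
#' @export
split_by_multiplicity <- function(cohort) {
  sizes <- dplyr::count(tibble::as_tibble(cohort), .data$patient_id)
  multi_ids <- sizes$patient_id[sizes$n >= 2]
  single <- dplyr::filter(cohort, !(.data$patient_id %in% multi_ids))
  multi <- dplyr::filter(cohort, .data$patient_id %in% multi_ids)
  counts <- tibble::tibble(
    part = c("single", "multi"),
    n_patients = c(dplyr::n_distinct(single$patient_id),
                   dplyr::n_distinct(multi$patient_id)),
    n_samples = c(nrow(single), nrow(multi))
  )
  list(single = single, multi = multi, counts = counts)
}

#' Descriptive summary of a cohort
#'
#' Dose variables and their on-treatment indicators follow the parametric
#' convention (mean with standard deviation, count with percentage);
#' cytometry variables follow the non-parametric convention (median with
#' minimum--maximum), computed over the samples where each is observed.
#'
#' @param cohort A `sputum_cohort`.
#' @return Tibble with one row per variable: `variable`, `convention`
#'   (`"mean (sd)"`, `"median (min-max)"` or `"n (%)"`), the two numeric
#'   components `a` and `b` (`b2` holds the max for ranges), and a
#'   formatted `label`.
#' @export
summarize_cohort <- function(cohort) {
  df <- tibble::as_tibble(cohort)
  if (nrow(df) == 0) stop("Cohort is empty.", call. = FALSE)
  n <- nrow(df)

  mean_sd <- function(var) {
    x <- df[[var]]
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    tibble::tibble(variable = var, convention = "mean (sd)",
                   a = m, b = s, b2 = NA_real_,
                   label = sprintf("%.1f (%.1f)", m, s))
  }
  med_range <- function(var) {
    x <- df[[var]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble::tibble(variable = var, convention = "median (min-max)",
                            a = NA_real_, b = NA_real_, b2 = NA_real_,
                            label = NA_character_))
    }
    tibble::tibble(variable = var, convention = "median (min-max)",
                   a = stats::median(x), b = min(x), b2 = max(x),
                   label = sprintf("%.1f (%.1f-%.1f)", stats::median(x),
                                   min(x), max(x)))
  }
  n_pct <- function(var, flag) {
    k <- sum(flag, na.rm = TRUE)
    tibble::tibble(variable = var, convention = "n (%)",
                   a = k, b = 100 * k / n, b2 = NA_real_,
                   label = sprintf("%d (%.1f)", k, 100 * k / n))
  }

  dplyr::bind_rows(
    mean_sd("ics_dose_mcg"),
    n_pct("on_ics", df$ics_dose_mcg > 0),
    mean_sd("ocs_dose_mg"),
    n_pct("on_ocs", df$ocs_dose_mg > 0),
    med_range("total_cell_count_e6_per_g"),
    med_range("viability_pct"),
    med_range("squamous_pct"),
    med_range("neutrophil_pct"),
    med_range("eosinophil_pct"),
    med_range("macrophage_pct"),
    med_range("lymphocyte_pct"),
    med_range("bronchial_epithelial_pct"),
    n_pct("exacerbation", df$clinical_state == "exacerbation")
  )
}
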