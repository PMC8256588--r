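test_that("rows group into date-ordered patient series", {
  co <- cohort_from_rows(
    sample_row("A", "2020-03-01"),
    sample_row("B", "2020-01-01"),
    sample_row("A", "2020-01-15")
  )
  expect_equal(nrow(co), 3)
  expect_equal(dplyr::n_distinct(co$patient_id), 2)
  a <- co[co$patient_id == "A", ]
  expect_true(!is.unsorted(a$exam_date))
})

test_that("invariant violations become row rejects, not silent drops", {
  bad_eos <- sample_row("A", eos = 3)
  bad_eos$differential_viable <- FALSE  # eos present but no differential
  bad_sum <- sample_row("B")
  bad_sum$macrophage_pct <- bad_sum$macrophage_pct + 5
  bad_date <- sample_row("C", exam_date = "not-a-date")
  bad_feg <- sample_row("D", feg_clumps = 5L, feg_grade = "few")
  co <- cohort_from_rows(sample_row("E"), bad_eos, bad_sum, bad_date,
                         bad_feg)
  expect_equal(nrow(co), 1)
  rej <- rejects(co)
  expect_equal(nrow(rej), 4)
  expect_match(rej$reject_reason[rej$patient_id == "A"],
               "differential_viable is false")
  expect_match(rej$reject_reason[rej$patient_id == "B"], "sum to 100")
  expect_match(rej$reject_reason[rej$patient_id == "C"], "exam_date")
  expect_match(rej$reject_reason[rej$patient_id == "D"], "inconsistent")
})

test_that("feg_grade is derived from clump counts when absent", {
  co <- cohort_from_rows(sample_row("A", feg_clumps = 3L),
                         sample_row("B", feg_grade = "many"),
                         sample_row("C"))
  expect_equal(as.character(co$feg_grade[co$patient_id == "A"]), "moderate")
  expect_equal(as.character(co$feg_grade[co$patient_id == "B"]), "many")
  expect_true(is.na(co$feg_grade[co$patient_id == "C"]))
})

test_that("same-day examinations keep input order and warn", {
  df <- dplyr::bind_rows(sample_row("A", "2020-01-01", eos = 1),
                         sample_row("A", "2020-01-01", eos = 2))
  expect_warning(co <- as_sputum_cohort(df), "input order")
  expect_equal(co$eosinophil_pct, c(1, 2))
})

test_that("cohort CSV round-trips through write and read", {
  co <- cohort_from_rows(
    sample_row("A", "2020-03-01", eos = 2.5, feg_clumps = 2L),
    sample_row("A", "2020-06-01", viable = FALSE, feg_clumps = 4L),
    sample_row("B", "2020-01-01", ocs = 10)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(rejects(back)), 0)
  strip <- function(x) {
    x <- tibble::as_tibble(x)[cohort_schema]
    attr(x, "rejects") <- NULL
    x
  }
  expect_equal(strip(back), strip(co), ignore_attr = "class")
})

test_that("missing mandatory columns are a schema error", {
  df <- sample_row("A")
  df$feg_grade <- NULL
  expect_error(as_sputum_cohort(df), "feg_grade")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  # readr also warns about the parser for the absent column
  expect_error(suppressWarnings(read_cohort(path)), "mandatory column")
})

test_that("empty input yields an empty cohort, not an error", {
  df <- sample_row("A")[0, ]
  co <- as_sputum_cohort(df)
  expect_equal(nrow(co), 0)
  expect_equal(nrow(rejects(co)), 0)
})

test_that("multiplicity split partitions patients exhaustively", {
  co <- cohort_from_rows(
    sample_row("A", "2020-01-01"), sample_row("A", "2020-02-01"),
    sample_row("A", "2020-03-01"),
    sample_row("B", "2020-01-01"),
    sample_row("C", "2020-01-01")
  )
  parts <- split_by_multiplicity(co)
  expect_equal(parts$counts$n_patients, c(2, 1))
  expect_equal(parts$counts$n_samples, c(2, 3))
  expect_equal(nrow(parts$single) + nrow(parts$multi), nrow(co))
  expect_length(intersect(parts$single$patient_id, parts$multi$patient_id), 0)

  all_single <- cohort_from_rows(sample_row("A"), sample_row("B"))
  expect_equal(nrow(split_by_multiplicity(all_single)$multi), 0)
})

test_that("descriptive summary follows the stated conventions", {
  co <- cohort_from_rows(
    sample_row("A", eos = 0.8, ocs = 10),
    sample_row("B", eos = 0.8, viable = TRUE),
    sample_row("C", eos = 0.8, viable = TRUE)
  )
  s <- summarize_cohort(co)
  eos_row <- s[s$variable == "eosinophil_pct", ]
  expect_equal(eos_row$convention, "median (min-max)")
  expect_equal(c(eos_row$a, eos_row$b, eos_row$b2), c(0.8, 0.8, 0.8))
  ocs_row <- s[s$variable == "on_ocs", ]
  expect_equal(ocs_row$a, 1)
  expect_equal(ocs_row$b, 100 / 3, tolerance = 1e-10)
  expect_match(ocs_row$label, "^1 \\(33.3\\)$")
  ics_row <- s[s$variable == "ics_dose_mcg", ]
  expect_equal(ics_row$a, 500)
  expect_error(summarize_cohort(co[0, ]), "empty")
})
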