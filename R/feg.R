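#' Ordinal grades for free eosinophil granules
#'
#' Free eosinophil granules (FEG) are extracellular granules released by
#' eosinophil cytolysis, enumerated on Wright-stained cytospins as clumps of
#' degranulated material per 400x field of view and reported on a
#' semi-quantitative ordinal scale.
#'
#' @format Character vector of the four grades in increasing order.
#' @export
feg_levels <- c("none", "few", "moderate", "many")

#' Default clump-count boundaries for FEG grading
#'
#' The conventional enumeration reports 0 clumps as \code{none}, 1--2 as
#' \code{few}, around 3 as \code{moderate} and more than 3 as \code{many}.
#' The published boundaries overlap at 2 ("1--2 as few, 2--3 as moderate");
#' the default table resolves the ambiguous count of 2 to the milder grade,
#' so the mapping is none = 0, few = 1--2, moderate = 3, many >= 4.
#'
#' @format Integer vector of lower clump-count bounds, named by grade.
#' @export
feg_default_breaks <- c(none = 0L, few = 1L, moderate = 3L, many = 4L)

#' Grade free eosinophil granule clump counts
#'
#' Maps integer clump counts per 400x field of view onto the ordinal
#' none/few/moderate/many scale.
#'
#' @param clumps_per_fov Non-negative integer vector of degranulated
#'   eosinophil clumps per 400x field of view. `NA` is propagated.
#' @param breaks Named integer vector of lower bounds per grade; see
#'   [feg_default_breaks]. Must be strictly increasing and start at 0.
#' @return Ordered factor with levels [feg_levels].
#' @examples
#' grade_feg(c(0, 1, 2, 3, 5))
#' @export
grade_feg <- function(clumps_per_fov, breaks = feg_default_breaks) {
  if (!identical(names(breaks), feg_levels) || breaks[[1]] != 0L ||
      is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing lower bounds named ",
         paste(feg_levels, collapse = ", "), " starting at 0.", call. = FALSE)
  }
  x <- clumps_per_fov
  ok <- is.na(x) | (is.numeric(x) & x >= 0 & x == floor(x))
  if (!all(ok)) {
    stop("`clumps_per_fov` must be non-negative integers (or NA).",
         call. = FALSE)
  }
  idx <- findInterval(x, breaks)
  factor(feg_levels[idx], levels = feg_levels, ordered = TRUE)
}

#' Coerce grade labels to the ordered FEG factor
#'
#' @param grade Character or factor vector of grade labels.
#' @return Ordered factor with levels [feg_levels]; unknown labels become
#'   `NA` with a warning.
#' @export
as_feg_grade <- function(grade) {
  g <- factor(as.character(grade), levels = feg_levels, ordered = TRUE)
  bad <- !is.na(grade) & is.na(g)
  if (any(bad)) {
    warning(sum(bad), " FEG grade label(s) not in {",
            paste(feg_levels, collapse = ", "), "} set to NA.", call. = FALSE)
  }
  g
}

#' Specification of an eosinophilia threshold
#'
#' A threshold couples a cutoff on the intact eosinophil differential
#' percentage with the set of FEG grades regarded as evidence of
#' eosinophilia at that stringency. The two conventional specifications are
#' provided by [threshold_abnormal()] (>= 1.2% or few/moderate/many FEG,
#' the upper limit of normal) and [threshold_clinical()] (>= 2.3% or
#' moderate/many FEG, the clinically relevant endotype definition).
#'
#' @param name Short label used in outputs.
#' @param intact_cutoff Positive cutoff on the intact eosinophil percentage.
#' @param qualifying_feg_grades Character vector of grades (subset of
#'   `few`, `moderate`, `many`) that qualify a sample as eosinophilic.
#' @param operator Comparison for the intact cutoff, `">="` (default,
#'   matching the threshold definitions) or `">"` for sensitivity checks.
#' @return An object of class `threshold_spec`.
#' @examples
#' threshold_spec("eos_1.2", 1.2, c("few", "moderate", "many"))
#' @export
threshold_spec <- function(name, intact_cutoff, qualifying_feg_grades,
                           operator = c(">=", ">")) {
  operator <- match.arg(operator)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(intact_cutoff) || length(intact_cutoff) != 1L ||
      intact_cutoff <= 0) {
    stop("`intact_cutoff` must be a single positive percentage.",
         call. = FALSE)
  }
  q <- unique(as.character(qualifying_feg_grades))
  if (length(q) == 0L) {
    stop("`qualifying_feg_grades` must not be empty.", call. = FALSE)
  }
  if ("none" %in% q || !all(q %in% feg_levels)) {
    stop("`qualifying_feg_grades` must be a non-empty subset of ",
         "{few, moderate, many}.", call. = FALSE)
  }
  structure(
    list(name = name, intact_cutoff = intact_cutoff,
         qualifying_feg_grades = feg_levels[feg_levels %in% q],
         operator = operator),
    class = "threshold_spec"
  )
}

#' @rdname threshold_spec
#' @export
threshold_abnormal <- function(operator = ">=") {
  threshold_spec("eos_1.2", 1.2, c("few", "moderate", "many"),
                 operator = operator)
}

#' @rdname threshold_spec
#' @export
threshold_clinical <- function(operator = ">=") {
  threshold_spec("eos_2.3", 2.3, c("moderate", "many"), operator = operator)
}

#' @rdname threshold_spec
#' @export
default_thresholds <- function() {
  list(threshold_abnormal(), threshold_clinical())
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec> ", x$name, ": intact eosinophil ", x$operator, " ",
      x$intact_cutoff, "% or FEG {",
      paste(x$qualifying_feg_grades, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# intact-percentage comparison under the spec's operator
intact_meets <- function(eos_pct, spec) {
  if (spec$operator == ">=") eos_pct >= spec$intact_cutoff
  else eos_pct > spec$intact_cutoff
}
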