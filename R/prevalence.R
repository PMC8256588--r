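#' FEG-augmented prevalence from category counts
#'
#' Composes the second prevalence tier: intact-positive samples, samples
#' with an intact differential below the cutoff but qualifying FEG, and
#' samples without an intact differential but qualifying FEG, over the
#' total number of samples. The three categories must be disjoint.
#'
#' @param n_intact_pos,n_feg_with_diff,n_feg_no_diff Non-negative counts of
#'   the three categories.
#' @param n_total Positive total number of samples.
#' @return Proportion in \[0, 1\].
#' @examples
#' compose_feg_augmented(6289, 384, 1177, 17693)  # 0.4437
#' @export
compose_feg_augmented <- function(n_intact_pos, n_feg_with_diff,
                                  n_feg_no_diff, n_total) {
  counts <- c(n_intact_pos, n_feg_with_diff, n_feg_no_diff)
  if (any(counts < 0) || n_total <= 0) {
    stop("Counts must be non-negative and n_total positive.", call. = FALSE)
  }
  if (sum(counts) > n_total) {
    stop("Category counts exceed n_total; categories must be disjoint.",
         call. = FALSE)
  }
  sum(counts) / n_total
}

#' Extrapolate prevalence to the whole cohort via the emergence fraction
#'
#' Samples not yet classified eosinophilic are assumed to convert at the
#' re-emergence (unmasking) rate observed among multi-sample patients:
#' `additional = (1 - prev_feg_aug) * emergence_fraction`, so
#' `prev_total = prev_feg_aug + additional`.
#'
#' @param prev_feg_aug FEG-augmented prevalence, in \[0, 1\].
#' @param emergence_fraction Fraction of multi-sample patients with at
#'   least one re-emergence event, in \[0, 1\].
#' @return List with `additional_extrapolated` and `prev_total`.
#' @examples
#' extrapolate_total(7850 / 17693, 834 / 2967)
#' @export
extrapolate_total <- function(prev_feg_aug, emergence_fraction) {
  if (any(c(prev_feg_aug, emergence_fraction) < 0) ||
      any(c(prev_feg_aug, emergence_fraction) > 1)) {
    stop("Both arguments must be proportions in [0, 1].", call. = FALSE)
  }
  additional <- (1 - prev_feg_aug) * emergence_fraction
  list(additional_extrapolated = additional,
       prev_total = prev_feg_aug + additional)
}

#' Relative underestimation of prevalence by the intact-only tier
#'
#' @param prev_intact Intact-only prevalence.
#' @param prev_total Total (extrapolated) prevalence, > 0 and >=
#'   `prev_intact`.
#' @return `(prev_total - prev_intact) / prev_total`.
#' @examples
#' underestimation(0.356, 0.600)  # about 0.41
#' @export
underestimation <- function(prev_intact, prev_total) {
  if (prev_total <= 0 || prev_total > 1) {
    stop("`prev_total` must be in (0, 1].", call. = FALSE)
  }
  if (prev_intact < 0 || prev_intact > prev_total) {
    stop("`prev_intact` must lie in [0, prev_total].", call. = FALSE)
  }
  (prev_total - prev_intact) / prev_total
}

new_prevalence_estimate <- function(x) {
  structure(x, class = "prevalence_estimate")
}

#' Staged prevalence estimate for a cohort at a threshold
#'
#' Runs the full composition: intact-only tier, FEG-augmented tier, and
#' extrapolated total via the multi-sample re-emergence fraction.
#'
#' Two tally modes are available for the non-viable-differential FEG
#' category. `"nested"` (default) counts every nonviable sample whose FEG
#' grade is in the threshold's qualifying set, so calls at a stricter
#' threshold are a subset of calls at a looser one. `"paper_tally"`
#' reproduces the printed-arithmetic convention of assigning nonviable
#' few-granule samples only to thresholds where `few` qualifies and
#' moderate/many samples only to thresholds where it does not — the two
#' conventions differ only in which nonviable FEG samples are credited to
#' each tier.
#'
#' @param cohort A `sputum_cohort`.
#' @param spec A [threshold_spec].
#' @param tally_mode `"nested"` or `"paper_tally"`.
#' @param neutrophil_cutoff,indeterminate_rule Passed to
#'   [summarize_emergence()].
#' @param emergence_fraction Optional externally supplied emergence
#'   fraction; when `NULL` (default) it is estimated from the cohort's
#'   multi-sample patients, and when the cohort has none the extrapolated
#'   tier is `NA` (flagged `extrapolation_estimable = FALSE`).
#' @return A `prevalence_estimate`: counts behind each stage, the three
#'   tier proportions, the emergence fraction used and the relative
#'   underestimation.
#' @export
estimate_prevalence <- function(cohort, spec,
                                tally_mode = c("nested", "paper_tally"),
                                neutrophil_cutoff = 64.4,
                                indeterminate_rule = "skip",
                                emergence_fraction = NULL) {
  tally_mode <- match.arg(tally_mode)
  tal <- classify_cohort(cohort, spec, mode = "with_feg")$tallies
  n_feg_no_diff <- if (tally_mode == "nested") {
    tal$n_feg_no_diff
  } else if ("few" %in% spec$qualifying_feg_grades) {
    tal$n_nonviable_few
  } else {
    tal$n_nonviable_modmany
  }
  prev_intact <- tal$n_intact_pos / tal$n_total
  prev_feg_aug <- compose_feg_augmented(tal$n_intact_pos,
                                        tal$n_feg_with_diff,
                                        n_feg_no_diff, tal$n_total)
  estimable <- TRUE
  if (is.null(emergence_fraction)) {
    parts <- split_by_multiplicity(cohort)
    if (nrow(parts$multi) == 0) {
      estimable <- FALSE
      emergence_fraction <- NA_real_
    } else {
      em <- summarize_emergence(cohort, spec, neutrophil_cutoff,
                                indeterminate_rule)
      emergence_fraction <- em$summary$fraction_patients
    }
  }
  if (estimable) {
    ext <- extrapolate_total(prev_feg_aug, emergence_fraction)
  } else {
    ext <- list(additional_extrapolated = NA_real_, prev_total = NA_real_)
  }
  new_prevalence_estimate(list(
    threshold_name = spec$name,
    tally_mode = tally_mode,
    n_total = tal$n_total,
    n_intact_pos = tal$n_intact_pos,
    n_feg_with_diff = tal$n_feg_with_diff,
    n_feg_no_diff = n_feg_no_diff,
    n_indeterminate = tal$n_indeterminate,
    prev_intact = prev_intact,
    prev_feg_aug = prev_feg_aug,
    emergence_fraction = emergence_fraction,
    additional_extrapolated = ext$additional_extrapolated,
    prev_total = ext$prev_total,
    underestimation = if (estimable && ext$prev_total > 0)
      underestimation(min(prev_intact, ext$prev_total), ext$prev_total)
      else NA_real_,
    extrapolation_estimable = estimable
  ))
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  pc <- function(p) if (is.na(p)) "NA" else sprintf("%.1f%%", 100 * p)
  cat("<prevalence_estimate> ", x$threshold_name,
      " (", x$tally_mode, " tallies, n = ", x$n_total, ")\n",
      "  intact-only:   ", pc(x$prev_intact),
      "  (", x$n_intact_pos, " samples)\n",
      "  FEG-augmented: ", pc(x$prev_feg_aug),
      "  (+", x$n_feg_with_diff, " with differential, +", x$n_feg_no_diff,
      " without)\n",
      "  extrapolated:  ", pc(x$prev_total),
      "  (emergence fraction ", pc(x$emergence_fraction), ")\n",
      "  underestimation by intact-only tier: ", pc(x$underestimation),
      "\n", sep = "")
  invisible(x)
}

#' Nested three-tier composition for a proportional Euler diagram
#'
#' The three tiers — intact-only, plus FEG, plus extrapolated
#' re-emergence — are nested by construction; the returned sizes are
#' suitable for a proportional-area (concentric) diagram.
#'
#' @param estimate A [prevalence_estimate][estimate_prevalence].
#' @return Tibble with `tier`, `count` (rounded to samples) and
#'   `proportion`, in nesting order.
#' @export
euler_composition <- function(estimate) {
  stopifnot(inherits(estimate, "prevalence_estimate"))
  props <- c(intact = estimate$prev_intact,
             feg_augmented = estimate$prev_feg_aug,
             extrapolated_total = estimate$prev_total)
  tibble::tibble(
    tier = names(props),
    count = round(unname(props) * estimate$n_total),
    proportion = unname(props)
  )
}

#' Plot the nested prevalence tiers as concentric proportional circles
#'
#' Requires ggplot2; areas are proportional to each tier's sample count.
#'
#' @param estimate A [prevalence_estimate][estimate_prevalence].
#' @return A ggplot object.
#' @export
plot_euler_composition <- function(estimate) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting.", call. = FALSE)
  }
  comp <- euler_composition(estimate)
  comp <- comp[!is.na(comp$proportion), ]
  comp <- comp[order(-comp$proportion), ]
  theta <- seq(0, 2 * pi, length.out = 181)
  circles <- dplyr::bind_rows(lapply(seq_len(nrow(comp)), function(i) {
    r <- sqrt(comp$proportion[i] / pi)
    tibble::tibble(tier = comp$tier[i], x = r * cos(theta),
                   y = r * sin(theta) + r)  # bottom-aligned nesting
  }))
  circles$tier <- factor(circles$tier, levels = comp$tier)
  ggplot2::ggplot(circles, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$tier)) +
    ggplot2::geom_polygon(alpha = 0.6, colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Eosinophilia prevalence tiers (%s)",
                      estimate$threshold_name),
      subtitle = paste(sprintf("%s: %.1f%%", comp$tier,
                               100 * comp$proportion), collapse = "; "),
      fill = "tier"
    ) +
    ggplot2::theme_void()
}

#' Serialize a prevalence estimate to JSON
#'
#' @param estimate A [prevalence_estimate][estimate_prevalence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prevalence_json <- function(estimate, path) {
  jsonlite::write_json(unclass(estimate), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
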