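#' Estimate a two-state Markov chain over eosinophilia calls
#'
#' The sensitivity analysis conceptualizes each sputum examination as a
#' node in a discrete-time chain with states N (non-eosinophilic) and E
#' (eosinophilic). Consecutive within-patient call pairs are pooled across
#' patients and the transition probabilities are the maximum-likelihood
#' row-normalized counts. Time is the examination index; unequal calendar
#' intervals are ignored. Pairs containing an indeterminate call are
#' excluded.
#'
#' @param sequences Either a list of per-patient logical call vectors
#'   (`TRUE` = eosinophilic, `NA` = indeterminate) in examination order, or
#'   a calls tibble from [classify_cohort()] (grouped by `patient_id`,
#'   assumed date-ordered; indeterminate calls become `NA`).
#' @param threshold_name Label stored on the model (taken from a calls
#'   tibble automatically).
#' @param smoothing Additive (Laplace) count added to each of the four
#'   transition cells, default 0. `smoothing = 1` is useful for sparse
#'   synthetic runs.
#' @return A `transition_model`: `counts` (2x2 matrix over states N, E),
#'   `probs` (row-stochastic matrix, `NA` rows where no outgoing pairs were
#'   observed), `p_NE`, `p_EN`, `stationary` (closed form
#'   `pi_E = p_NE / (p_NE + p_EN)`, `NA` when either row is undefined or
#'   the chain is absorbing in both states), `n_pairs`.
#' @examples
#' m <- estimate_transitions(list(c(FALSE, TRUE, FALSE, FALSE),
#'                                c(TRUE, TRUE)))
#' m$p_NE  # 0.5
#' @export
estimate_transitions <- function(sequences, threshold_name = NA_character_,
                                 smoothing = 0) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("patient_id", "eosinophilic") %in% names(sequences)))
    if (!is.na(sequences$threshold_name[1] %||% NA)) {
      threshold_name <- sequences$threshold_name[1]
    }
    calls <- sequences$eosinophilic
    if ("indeterminate" %in% names(sequences)) {
      calls[sequences$indeterminate] <- NA
    }
    sequences <- split(calls, sequences$patient_id)
  }
  stopifnot(is.list(sequences), smoothing >= 0)
  counts <- matrix(smoothing, 2, 2,
                   dimnames = list(from = c("N", "E"), to = c("N", "E")))
  n_pairs <- 0L
  for (s in sequences) {
    s <- as.logical(s)
    if (length(s) < 2) next
    from <- s[-length(s)]
    to <- s[-1]
    keep <- !is.na(from) & !is.na(to)
    from <- from[keep]; to <- to[keep]
    n_pairs <- n_pairs + length(from)
    counts["N", "N"] <- counts["N", "N"] + sum(!from & !to)
    counts["N", "E"] <- counts["N", "E"] + sum(!from & to)
    counts["E", "N"] <- counts["E", "N"] + sum(from & !to)
    counts["E", "E"] <- counts["E", "E"] + sum(from & to)
  }
  if (n_pairs == 0L && smoothing == 0) {
    stop("No usable consecutive call pairs; need at least one sequence ",
         "of length >= 2 with non-indeterminate calls.", call. = FALSE)
  }
  row_tot <- rowSums(counts)
  probs <- counts / row_tot
  probs[row_tot == 0, ] <- NA_real_
  p_NE <- probs["N", "E"]
  p_EN <- probs["E", "N"]
  stationary <- if (!is.na(p_NE) && !is.na(p_EN) && (p_NE + p_EN) > 0) {
    pe <- p_NE / (p_NE + p_EN)
    c(N = 1 - pe, E = pe)
  } else {
    c(N = NA_real_, E = NA_real_)
  }
  structure(
    list(threshold_name = threshold_name, counts = counts, probs = probs,
         p_NE = p_NE, p_EN = p_EN, stationary = stationary,
         n_pairs = n_pairs, smoothing = smoothing),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model>",
      if (!is.na(x$threshold_name)) paste0(" ", x$threshold_name), " (",
      x$n_pairs, " pairs",
      if (x$smoothing > 0) paste0(", +", x$smoothing, " smoothing"),
      ")\n", sep = "")
  print(round(x$probs, 4))
  if (!is.na(x$stationary["E"])) {
    cat(sprintf("  stationary: pi_N = %.4f, pi_E = %.4f\n",
                x$stationary["N"], x$stationary["E"]))
  } else {
    cat("  stationary: undefined (a state row has no outgoing pairs)\n")
  }
  invisible(x)
}

#' Chain-implied eosinophilia prevalence
#'
#' Two horizons are provided. `"next_step"` answers: starting from a
#' current prevalence `current_prev`, what fraction of samples is
#' eosinophilic now or at the next examination —
#' `current_prev + (1 - current_prev) * p_NE`. `"stationary"` is the
#' long-run occupancy `pi_E = p_NE / (p_NE + p_EN)`.
#'
#' @param model A [transition_model][estimate_transitions].
#' @param horizon `"next_step"` or `"stationary"`.
#' @param current_prev Current prevalence for the next-step composite
#'   (required for `"next_step"`).
#' @return Proportion in \[0, 1\].
#' @export
chain_prevalence <- function(model, horizon = c("next_step", "stationary"),
                             current_prev = NULL) {
  horizon <- match.arg(horizon)
  stopifnot(inherits(model, "transition_model"))
  if (horizon == "stationary") {
    if (is.na(model$stationary["E"])) {
      stop("Stationary distribution undefined for this model.",
           call. = FALSE)
    }
    return(unname(model$stationary["E"]))
  }
  if (is.na(model$p_NE)) {
    stop("p_NE undefined: no observed pairs leaving state N.", call. = FALSE)
  }
  if (is.null(current_prev) || current_prev < 0 || current_prev > 1) {
    stop("`current_prev` must be supplied in [0, 1] for the next-step ",
         "horizon.", call. = FALSE)
  }
  current_prev + (1 - current_prev) * model$p_NE
}

#' Serialize a transition model to JSON
#'
#' @param model A [transition_model][estimate_transitions].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_json <- function(model, path) {
  x <- list(
    threshold_name = model$threshold_name,
    counts = list(NN = model$counts["N", "N"], NE = model$counts["N", "E"],
                  EN = model$counts["E", "N"], EE = model$counts["E", "E"]),
    p_NN = model$probs["N", "N"], p_NE = model$p_NE,
    p_EN = model$p_EN, p_EE = model$probs["E", "E"],
    stationary = as.list(model$stationary),
    n_pairs = model$n_pairs, smoothing = model$smoothing
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
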