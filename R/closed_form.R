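# Gauss-Hermite nodes/weights for E[f(Z)], Z ~ N(0,1), via Golub-Welsch
gauss_hermite_normal <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 1))
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  w <- e$vectors[1, ]^2
  list(nodes = sqrt(2) * e$values, weights = w)
}

# P(FEG grade in `grades`) for clump counts ~ zero-inflated Poisson(lambda),
# by the default grade bands: none=0, few=1-2, moderate=3, many>=4
feg_grade_probs <- function(lambda, zero_infl = 0) {
  d <- stats::dpois(0:3, lambda)
  p <- c(none = d[1], few = d[2] + d[3], moderate = d[4],
         many = 1 - sum(d))
  p <- (1 - zero_infl) * p
  p["none"] <- p["none"] + zero_infl
  p
}

#' Analytic expectations under a generator configuration
#'
#' Closed-form counterparts of the pipeline's estimates under the
#' generator's own assumptions, used as independent oracles against
#' Monte-Carlo runs: the latent-chain stationary prevalence and transition
#' matrix; per-threshold expected sample-level quantities (call
#' prevalence under the with-FEG rule, intact-only prevalence,
#' FEG-augmented prevalence in both tally modes); and the per-pair and
#' patient-level re-emergence probabilities among multi-sample patients
#' (the latter by an exact forward recursion over latent state and call
#' category, averaged over the series-length distribution).
#'
#' The computation is exact (up to quadrature over the patient effect) for
#' time-homogeneous configurations; dose step-downs make the observation
#' process time-inhomogeneous, so `p_dose_decrease` must be 0.
#'
#' @param config A [generator_config()] with `p_dose_decrease = 0`.
#' @param thresholds List of [threshold_spec] objects.
#' @param gh_nodes Number of Gauss-Hermite nodes for the patient-effect
#'   integral.
#' @return List with `stationary_prev_E`, `transition_matrix`,
#'   `mean_series_length_multi` and a `thresholds` tibble of per-threshold
#'   expectations.
#' @export
closed_form_expectations <- function(config,
                                     thresholds = default_thresholds(),
                                     gh_nodes = 151) {
  stopifnot(inherits(config, "generator_config"))
  if (config$p_dose_decrease != 0) {
    stop("Closed-form expectations require a time-homogeneous ",
         "configuration (`p_dose_decrease = 0`).", call. = FALSE)
  }
  P <- matrix(c(1 - config$p_NE, config$p_NE,
                config$p_EN, 1 - config$p_EN),
              2, 2, byrow = TRUE,
              dimnames = list(from = c("N", "E"), to = c("N", "E")))
  pi_E <- stationary_prob_E(config)
  init <- c(N = 1 - config_init_E(config), E = config_init_E(config))

  gh <- if (config$patient_effect_sd > 0) gauss_hermite_normal(gh_nodes)
        else list(nodes = 0, weights = 1)
  u_nodes <- gh$nodes * config$patient_effect_sd

  # patient classes: (u node) x (ics tier) x (ocs off/tier)
  ocs_doses <- c(0, config$ocs_tier_doses)
  ocs_probs <- c(1 - config$p_ocs, config$p_ocs * config$ocs_tier_probs)
  cls <- expand.grid(u = seq_along(u_nodes),
                     i = seq_along(config$ics_tier_doses),
                     o = seq_along(ocs_doses))
  cls$w <- gh$weights[cls$u] * config$ics_tier_probs[cls$i] *
    ocs_probs[cls$o]

  # series-length distribution for multi-sample patients (truncated)
  kmax <- config$series_max_length
  pk <- stats::dgeom(seq(2, kmax) - 2, config$series_extra_geom_prob)
  pk[kmax - 1] <- 1 - sum(pk[-(kmax - 1)])
  mean_k_multi <- sum(seq(2, kmax) * pk)

  # visit-index weights over all samples (for marginal sample quantities)
  mf <- config$multi_fraction
  t_idx <- seq_len(kmax)
  p_len_ge <- c(1, mf, mf * (1 - config$series_extra_geom_prob)^
                  (pmax(t_idx[-(1:2)] - 2, 0)))
  m_t <- matrix(NA_real_, kmax, 2)
  m_t[1, ] <- init
  for (t in 2:kmax) m_t[t, ] <- m_t[t - 1, ] %*% P

  lam <- config$feg_lambda
  pmf <- config$p_feg_missing
  adj <- 0.05  # observed eos % is rounded to one decimal

  th_rows <- lapply(thresholds, function(spec) {
    cut_adj <- spec$intact_cutoff - adj
    qgrades <- spec$qualifying_feg_grades
    q_prob <- function(lambda, zi = 0) {
      sum(feg_grade_probs(lambda, zi)[qgrades])
    }
    q_v_N <- q_prob(lam$viable_N)
    q_v_Em <- q_prob(lam$viable_E_masked, config$feg_zero_masked)
    q_v_Eu <- q_prob(lam$viable_E_unmasked)
    q_nv_N <- q_prob(lam$nonviable_N)
    q_nv_E <- q_prob(lam$nonviable_E)
    # nonviable grade-band probabilities for the paper-tally composition
    band <- if ("few" %in% qgrades) "few" else c("moderate", "many")
    band_nv_N <- sum(feg_grade_probs(lam$nonviable_N)[band])
    band_nv_E <- sum(feg_grade_probs(lam$nonviable_E)[band])

    per_class <- lapply(seq_len(nrow(cls)), function(ci) {
      u <- u_nodes[cls$u[ci]]
      ics <- config$ics_tier_doses[cls$i[ci]]
      ocs <- ocs_doses[cls$o[ci]]
      eos_pos <- function(meanlog, sdlog) {
        1 - stats::plnorm(cut_adj, meanlog + u, sdlog)
      }
      ep_N <- eos_pos(config$eos_meanlog_N, config$eos_sdlog_N)
      ep_E <- eos_pos(config$eos_meanlog_E, config$eos_sdlog_E)
      mask_p <- function(ne) {
        min(config$mask_cap,
            config$mask_base + config$mask_per_ics1000 * ics / 1000 +
              config$mask_ocs_on * (ocs > 0) + config$mask_neut * ne)
      }
      pm_E <- config$p_neut_elev_E * mask_p(1) +
        (1 - config$p_neut_elev_E) * mask_p(0)
      pv_N <- 1 - config$p_nonviable_N
      pv_E <- 1 - config$p_nonviable_E

      callE_N <- pv_N * (ep_N + (1 - ep_N) * (1 - pmf) * q_v_N) +
        (1 - pv_N) * (1 - pmf) * q_nv_N
      callE_E_masked <- pv_E * (ep_N + (1 - ep_N) * (1 - pmf) * q_v_Em) +
        (1 - pv_E) * (1 - pmf) * q_nv_E
      callE_E_unmasked <- pv_E * (ep_E + (1 - ep_E) * (1 - pmf) * q_v_Eu) +
        (1 - pv_E) * (1 - pmf) * q_nv_E
      callE_E <- pm_E * callE_E_masked + (1 - pm_E) * callE_E_unmasked
      callI_N <- (1 - pv_N) * pmf
      callI_E <- (1 - pv_E) * pmf

      intact_N <- pv_N * ep_N
      intact_E <- pv_E * (pm_E * ep_N + (1 - pm_E) * ep_E)
      withdiff_feg_N <- pv_N * (1 - ep_N) * (1 - pmf) * q_v_N
      withdiff_feg_E <- pv_E * (1 - pmf) *
        (pm_E * (1 - ep_N) * q_v_Em + (1 - pm_E) * (1 - ep_E) * q_v_Eu)
      nodiff_q_N <- (1 - pv_N) * (1 - pmf) * q_nv_N
      nodiff_q_E <- (1 - pv_E) * (1 - pmf) * q_nv_E
      nodiff_band_N <- (1 - pv_N) * (1 - pmf) * band_nv_N
      nodiff_band_E <- (1 - pv_E) * (1 - pmf) * band_nv_E

      callprob <- rbind(
        N = c(E = callE_N, I = callI_N, N = 1 - callE_N - callI_N),
        E = c(E = callE_E, I = callI_E, N = 1 - callE_E - callI_E))

      # forward recursion over (latent, call category), event = N -> E call
      f <- callprob * init  # f[s, c] = P(latent s, call c, no event yet)
      no_event <- numeric(kmax)
      no_event[1] <- sum(f)
      for (t in 2:kmax) {
        g <- matrix(0, 2, 3, dimnames = dimnames(callprob))
        for (s2 in 1:2) {
          # a call-N visit may not be followed by a call-E visit
          from_N <- sum(f[, "N"] * P[, s2])
          from_other <- sum((f[, "E"] + f[, "I"]) * P[, s2])
          g[s2, "E"] <- from_other * callprob[s2, "E"]
          g[s2, "I"] <- (from_other + from_N) * callprob[s2, "I"]
          g[s2, "N"] <- (from_other + from_N) * callprob[s2, "N"]
        }
        f <- g
        no_event[t] <- sum(f)
      }
      emerge_k <- 1 - no_event[seq(2, kmax)]
      patient_emergence <- sum(pk * emerge_k)

      # per-pair emergence at stationary
      pi_vec <- c(N = 1 - pi_E, E = pi_E)
      pair <- sum(vapply(1:2, function(s) {
        pi_vec[s] * callprob[s, "N"] *
          sum(P[s, ] * callprob[, "E"])
      }, numeric(1)))

      # sample-level marginals weighted over visit index
      wt <- p_len_ge / sum(p_len_ge)
      sN <- sum(wt * m_t[, 1]); sE <- sum(wt * m_t[, 2])
      c(call_prev = sN * callE_N + sE * callE_E,
        prev_intact = sN * intact_N + sE * intact_E,
        withdiff_feg = sN * withdiff_feg_N + sE * withdiff_feg_E,
        nodiff_q = sN * nodiff_q_N + sE * nodiff_q_E,
        nodiff_band = sN * nodiff_band_N + sE * nodiff_band_E,
        pair_emergence = pair,
        patient_emergence = patient_emergence)
    })
    agg <- Reduce(`+`, Map(`*`, per_class, cls$w))
    tibble::tibble(
      threshold_name = spec$name,
      call_prev = agg[["call_prev"]],
      prev_intact = agg[["prev_intact"]],
      prev_feg_aug_nested = agg[["prev_intact"]] + agg[["withdiff_feg"]] +
        agg[["nodiff_q"]],
      prev_feg_aug_paper = agg[["prev_intact"]] + agg[["withdiff_feg"]] +
        agg[["nodiff_band"]],
      pair_emergence = agg[["pair_emergence"]],
      patient_emergence = agg[["patient_emergence"]]
    )
  })

  list(stationary_prev_E = pi_E,
       transition_matrix = P,
       mean_series_length_multi = mean_k_multi,
       thresholds = dplyr::bind_rows(th_rows))
}
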