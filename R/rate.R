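#' Summed adapter-factor recruitment by active activators
#'
#' Functionally active activators recruit uniformly expressed adapter
#' factors with per-factor strengths \eqn{\alpha}; the recruiting
#' contributions add, lowering the activation energy barrier of
#' initiation: \eqn{E = \sum_i \alpha(tf_i) f^{AQ}_i}. Activators act
#' anywhere between the TSS and the construct end, so no distance term
#' appears. A coactivated target site contributes with its own recruiting
#' strength (`alpha_coact`).
#'
#' @param func Functional occupancy tibble with `f_act_quenched` (from
#'   [apply_quenching()]).
#' @param sites Site tibble.
#' @param params Parameter tibble (`alpha` per activator, `alpha_coact`
#'   per coactivated target).
#' @param config Model configuration.
#' @return Tibble `position`, `E_raw`.
#' @export
sum_activation <- function(func, sites, params,
                           config = default_model_config()) {
  sites <- ensure_site_id(sites)
  alpha <- site_alphas(sites, param_tables(params), config)
  if (any(alpha < 0)) {
    stop("invalid parameter: recruiting strength alpha must be >= 0",
         call. = FALSE)
  }
  func |>
    dplyr::mutate(alpha = alpha[match(.data$site_id, sites$site_id)]) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(E_raw = sum(.data$alpha * .data$f_act_quenched),
                     .groups = "drop")
}

# Recruiting strength per site: activators use alpha[tf]; coactivation
# targets use alpha_coact[tf]; plain repressors recruit nothing. `pt` is
# a param_tables() lookup list.
site_alphas <- function(sites, pt, config) {
  role <- site_roles(sites, config)
  is_target <- config$tfs$coact_target[match(sites$tf, config$tfs$tf)]
  ifelse(role == "activator", lk0(pt$alpha, sites$tf),
         ifelse(is_target, lk0(pt$alpha_coact, sites$tf), 0))
}

#' Direct repression of the transcription machinery
#'
#' Quenchers bound within quenching range of the TSS repress the basal
#' machinery itself rather than a specific activator, attenuating the
#' summed activation:
#' \deqn{E_{eff} = E \prod_j \bigl(1 - \beta_D(j)\, f^Q_j\,
#' r(d_{j,TSS})\bigr)}
#' The same bounded range function as short-range quenching is used, with
#' the distance measured from the quencher site center to the TSS.
#'
#' @param activation Tibble `position`, `E_raw` from [sum_activation()].
#' @param func Functional occupancy tibble (uses `f_quench`).
#' @param sites Site tibble.
#' @param tss TSS coordinate on the construct (0-based bp).
#' @param params Parameter tibble (`beta_d` per repressor).
#' @param config Model configuration.
#' @return `activation` with an `E_eff` column added.
#' @export
apply_direct_repression <- function(activation, func, sites, tss, params,
                                    config = default_model_config()) {
  sites <- ensure_site_id(sites)
  beta_d <- lk0(param_tables(params)$beta_d, sites$tf)
  if (any(beta_d < 0 | beta_d > 1)) {
    stop("invalid efficiency: beta_d must lie in [0, 1]", call. = FALSE)
  }
  rv <- range_value(abs(sites$center - tss),
                    config$quench_r_full, config$quench_r_zero)
  active <- which(beta_d > 0 & rv > 0)
  positions <- activation$position
  surv <- rep(1, length(positions))
  if (length(active)) {
    fq <- func |>
      dplyr::select("position", "site_id", "f_quench") |>
      tidyr::pivot_wider(names_from = "site_id", values_from = "f_quench")
    fq <- fq[match(positions, fq$position), , drop = FALSE]
    for (j in active) {
      col <- as.character(sites$site_id[j])
      if (!col %in% names(fq)) next
      surv <- surv * (1 - beta_d[j] * fq[[col]] * rv[j])
    }
  }
  activation$E_eff <- activation$E_raw * surv
  activation
}

#' Steady state of the three-state transcription initiation cycle
#'
#' The promoter cycles through three states: (1) no polymerase bound;
#' (2) polymerase bound but stalled; (3) polymerase bound and transcription
#' initiated, blocking new binding. Transitions are 1->2 at rate `k1`,
#' 2->1 at `k_minus1`, 2->3 at `k2`, 3->1 at `k3`; each entry into state 3
#' initiates one transcript, so the transcription rate is proportional to
#' the steady-state probability of state 3.
#'
#' Solved in closed form from the balance equations; an independent linear
#' solve of the master-equation steady state is used as a test oracle.
#'
#' @param k1,k_minus1,k2,k3 Positive first-order rate constants.
#' @return Named numeric `c(P1, P2, P3)` summing to 1.
#' @examples
#' three_state_steady_state(1, 1, 1, 1)  # (1/2, 1/4, 1/4)
#' @export
three_state_steady_state <- function(k1, k_minus1, k2, k3) {
  k1 <- unname(k1); k_minus1 <- unname(k_minus1)
  k2 <- unname(k2); k3 <- unname(k3)
  ks <- c(k1, k_minus1, k2, k3)
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("invalid rate: all four rate constants must be positive",
         call. = FALSE)
  }
  p2 <- k1 / (k_minus1 + k2)           # relative to P1
  p3 <- k2 * p2 / k3
  z <- 1 + p2 + p3
  c(P1 = 1 / z, P2 = p2 / z, P3 = p3 / z)
}

#' Diffusion-limited Arrhenius transcription rate law
#'
#' Adapter recruitment lowers the activation energy barrier \eqn{\theta}
#' of initiation; the rate follows
#' \deqn{R = R_{max} \frac{K}{1 + K}, \qquad K = e^{E_{eff} - \theta}}
#' which is exponential in \eqn{E_{eff}} while the barrier dominates
#' (\eqn{K \ll 1}), allowing greater-than-multiplicative synergy between
#' activators, and saturates at \eqn{R_{max}} as the barrier vanishes,
#' when diffusion of new polymerase to the promoter becomes rate
#' limiting. Equivalent to the state-3 occupancy of the three-state
#' initiation cycle under the substitution \eqn{k_2 = k_3},
#' \eqn{k_1 = (k_{-1} + k_2) K / 2} (see
#' [markov_rates_from_energy()]).
#'
#' @param E_eff Effective summed activation (energy units, RT = 1).
#' @param theta Activation energy barrier.
#' @param R_max Saturating transcription rate, > 0.
#' @return Rates in \[0, `R_max`).
#' @export
transcription_rate <- function(E_eff, theta, R_max) {
  if (R_max <= 0) stop("R_max must be > 0", call. = FALSE)
  # logistic form written to stay finite for large barrier deficits
  R_max / (1 + exp(theta - E_eff))
}

#' Kinetic constants realizing the closed-form rate law
#'
#' One substitution of the three-state cycle's rate constants under which
#' the state-3 steady-state occupancy reproduces the closed-form rate law
#' exactly: with \eqn{k_2 = k_3} and
#' \eqn{k_1 = (k_{-1} + k_2)\, e^{E-\theta}/2}, the occupancy is
#' \eqn{P_3 = \tfrac{1}{2} K/(1+K)} and \eqn{P_3 / P_3^{max} = K/(1+K)}.
#' The base constants are configurable; exactness requires `k2 == k3`.
#'
#' @inheritParams transcription_rate
#' @param theta Activation energy barrier.
#' @param k_minus1,k2,k3 Base rate constants.
#' @return Named numeric `c(k1, k_minus1, k2, k3)`.
#' @export
markov_rates_from_energy <- function(E_eff, theta, k_minus1 = 1, k2 = 1,
                                     k3 = k2) {
  K <- exp(E_eff - theta)
  c(k1 = (k_minus1 + k2) * K / 2, k_minus1 = k_minus1, k2 = k2, k3 = k3)
}

#' Predict the spatial transcription-rate profile of a construct
#'
#' Runs the full sequence-to-expression pipeline at every
#' anterior-posterior position: PWM scan of both strands above each
#' factor's threshold, Bcd cooperativity assignment, grouped configuration
#' summation to fractional occupancies, coactivation, short-range
#' quenching, summed adapter recruitment, direct repression at the TSS,
#' and the diffusion-limited Arrhenius rate law, finally scaled by the
#' construct's position-effect factor. Each position is evaluated
#' independently under its own TF concentrations.
#'
#' @param construct A list or one-row tibble with `construct` (id), `seq`
#'   (DNA string), `tss` (0-based coordinate), and optionally `targeted`.
#' @param pwms Named list of [build_pwm()] objects, one per TF.
#' @param tf_profiles Concentration tibble: `position` plus one column per
#'   TF (relative fluorescence).
#' @param params Parameter tibble.
#' @param config Model configuration.
#' @param knockout Optional character vector of mechanisms to remove in
#'   silico; see [apply_knockout()].
#' @param details If TRUE, attach the pipeline intermediates (sites,
#'   occupancies, functional occupancies, activation) as attributes for
#'   dissection.
#' @return A tibble `construct`, `position`, `rate` of class
#'   `expression_profile`.
#' @export
predict_profile <- function(construct, pwms, tf_profiles, params,
                            config = default_model_config(),
                            knockout = NULL, details = FALSE) {
  if (!is.null(knockout)) params <- apply_knockout(params, knockout)
  construct <- as.list(construct)
  sites <- scan_construct(construct$seq, pwms, params, config)
  positions <- tf_profiles$position
  empty_profile <- function() {
    structure(tibble::tibble(construct = construct$construct %||% "construct",
                             position = positions,
                             rate = rep(0, length(positions))),
              class = c("expression_profile", "tbl_df", "tbl", "data.frame"))
  }
  if (nrow(sites) == 0) {
    warning("construct has no binding sites above threshold", call. = FALSE)
    return(empty_profile())
  }
  coop_tf <- config$tfs$tf[config$tfs$cooperative]
  pairs <- assign_cooperativity(sites[sites$tf %in% coop_tf, ],
                                config$coop_range_bp)
  occ <- occupancy_landscape(sites, tf_profiles, params, pairs, config)
  func <- apply_coactivation(occ, sites, params, config)
  func <- apply_quenching(func, sites, params, config)
  activation <- sum_activation(func, sites, params, config)
  activation <- apply_direct_repression(activation, func, sites,
                                        construct$tss, params, config)
  scale <- param_value(params, "pos_effect",
                       construct$construct %||% NA_character_, default = 1)
  theta <- param_value(params, "theta")
  R_max <- param_value(params, "R_max")
  out <- tibble::tibble(
    construct = construct$construct %||% "construct",
    position = activation$position,
    rate = scale * transcription_rate(activation$E_eff, theta, R_max)
  )
  out <- out[match(positions, out$position), ]
  if (details) {
    attr(out, "sites") <- sites
    attr(out, "pairs") <- pairs
    attr(out, "occupancy") <- occ
    attr(out, "functional") <- func
    attr(out, "activation") <- activation
  }
  class(out) <- c("expression_profile", class(tibble::tibble()))
  out
}

# Scan a construct with every PWM at its configured threshold.
scan_construct <- function(seq, pwms, params, config) {
  sites <- purrr::map_dfr(config$tfs$tf, function(tf) {
    if (!tf %in% names(pwms)) {
      stop("no PWM supplied for TF ", tf, call. = FALSE)
    }
    scan_sequence(
      seq, pwms[[tf]],
      threshold = param_value(params, "threshold", tf),
      lam = param_value(params, "lambda", tf),
      footprint_size = config$tfs$footprint[config$tfs$tf == tf]
    )
  })
  sites <- dplyr::arrange(sites, .data$start, .data$tf, .data$strand)
  ensure_site_id(sites)
}
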