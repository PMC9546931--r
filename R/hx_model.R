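#' Intrinsic hydrogen-exchange rate as a function of pH
#'
#' Single-term base-catalysis model: the intrinsic chemical exchange rate of
#' an exposed amide rises one decade per pH unit,
#' `k_int = k_ref * 10^(pH - pH_ref)`. Residue-specific chemistry enters
#' through `k_ref` (the rate at the reference pH); full sequence-dependent
#' intrinsic-rate tables can be supplied instead wherever a `k_int` model is
#' accepted.
#'
#' @param pH solution pH (dimensionless), may be a vector.
#' @param k_ref intrinsic rate at `pH_ref`, s^-1, > 0.
#' @param pH_ref reference pH (default 7).
#' @return intrinsic exchange rate(s), s^-1.
#' @examples
#' intrinsic_rate(8, 1, 7) # 10
#' @export
intrinsic_rate <- function(pH, k_ref = 1, pH_ref = 7) {
  check_positive(k_ref, "k_ref")
  if (!is.numeric(pH)) stop_domain("'pH' must be numeric")
  k_ref * 10^(pH - pH_ref)
}

#' Observed hydrogen-exchange rate under the two-process model
#'
#' Steady-state (Linderstrom-Lang) rate of the scheme
#' `NH(closed) <-> NH(open) -> ND(exchanged)` with opening rate `k_op`,
#' closing rate `k_cl` and intrinsic exchange rate `k_int`:
#' \deqn{k_{obs} = \frac{k_{op} k_{int}}{k_{op} + k_{cl} + k_{int}}}
#' In the EX1 limit (`k_int >> k_cl`) this tends to `k_op`; in the EX2
#' limit (`k_int << k_cl`) it tends to `(k_op/k_cl) * k_int`, i.e. the
#' intrinsic rate scaled by the opening equilibrium constant
#' `K_op = k_op/k_cl`.
#'
#' @param k_op opening rate, s^-1, > 0.
#' @param k_cl closing rate, s^-1, > 0.
#' @param k_int intrinsic exchange rate(s), s^-1, > 0.
#' @param regime_ratio decade ratio R deciding the regime label: EX1 when
#'   `k_int >= R * k_cl`, EX2 when `k_int <= k_cl / R`, otherwise
#'   intermediate. Default 10 (one decade).
#' @return a list with `k_obs` (s^-1) and `regime`
#'   (`"EX1"`, `"EX2"` or `"intermediate"`, per element of `k_int`).
#' @examples
#' hx_observed_rate(2, 3, 5)$k_obs # 10/10 = 1
#' @export
hx_observed_rate <- function(k_op, k_cl, k_int, regime_ratio = 10) {
  check_positive(k_op, "k_op")
  check_positive(k_cl, "k_cl")
  check_positive(k_int, "k_int")
  k_obs <- k_op * k_int / (k_op + k_cl + k_int)
  regime <- ifelse(k_int >= regime_ratio * k_cl, "EX1",
                   ifelse(k_int <= k_cl / regime_ratio, "EX2",
                          "intermediate"))
  list(k_obs = k_obs, regime = regime)
}

#' Exact slow-phase exchange rate (eigenvalue solution)
#'
#' Smaller-magnitude nonzero eigenvalue of the 2x2 rate matrix of the
#' linear scheme `closed <-> open -> exchanged`. Serves as the independent
#' oracle for the steady-state approximation of [hx_observed_rate()]; the
#' two agree closely in the folded-protein regime `k_op << k_cl`.
#'
#' @inheritParams hx_observed_rate
#' @param k_int intrinsic exchange rate(s), s^-1, >= 0 (zero closes the
#'   exchange channel and gives a zero rate).
#' @return slow-phase rate(s), s^-1.
#' @export
hx_exact_slow_rate <- function(k_op, k_cl, k_int) {
  check_positive(k_op, "k_op")
  check_positive(k_cl, "k_cl")
  if (any(!is.finite(k_int)) || any(k_int < 0)) {
    stop_domain("'k_int' must be finite and >= 0")
  }
  s <- k_op + k_cl + k_int
  # lambda_slow = (s - sqrt(s^2 - 4 k_op k_int)) / 2, computed in the
  # cancellation-free form 2 k_op k_int / (s + sqrt(...))
  disc <- sqrt(pmax(s^2 - 4 * k_op * k_int, 0))
  2 * k_op * k_int / (s + disc)
}

#' Proton occupancy after a labeling pulse
#'
#' Fraction of amide protons still unexchanged after a pulse of duration
#' `t` at observed exchange rate `k_obs`: `exp(-k_obs * t)`.
#'
#' @param k_obs observed exchange rate, s^-1, >= 0.
#' @param t pulse duration, s, >= 0.
#' @return occupancy fraction in `[0, 1]`.
#' @export
occupancy_after_pulse <- function(k_obs, t) {
  if (any(!is.finite(k_obs)) || any(k_obs < 0)) {
    stop_domain("'k_obs' must be finite and >= 0")
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_domain("'t' must be finite and >= 0")
  }
  exp(-k_obs * t)
}
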