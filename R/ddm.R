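# Intra-trial choice process: two-boundary drift diffusion with unit
# diffusion coefficient. Boundaries sit at 0 (lower) and a (upper); the
# upper boundary is, by convention throughout the package, the correct
# item. The diffusion coefficient is fixed at 1, so omega and a absorb the
# scale; fitted values are only comparable across studies under the same
# convention.

#' DDM parameter bundle
#'
#' @param d drift rate (evidence units per second, signed toward the upper
#'   = correct boundary).
#' @param a boundary separation (> 0).
#' @param z starting point as a fraction in (0, 1) of the distance from the
#'   lower to the upper boundary; 0.5 is unbiased.
#' @param s_nd non-decision time in seconds (>= 0).
#' @return list of class `ddm_params`.
#' @export
ddm_params <- function(d, a, z = 0.5, s_nd = 0) {
  if (a <= 0) stop("boundary separation a must be positive")
  if (z <= 0 || z >= 1) stop("starting fraction z must lie strictly in (0, 1)")
  if (s_nd < 0) stop("non-decision time must be non-negative")
  structure(list(d = d, a = a, z = z, s_nd = s_nd), class = "ddm_params")
}

#' Drift rate from a belief
#'
#' \eqn{d = \omega (P(A) - P(B)) = \omega (2 p_a - 1)}: the drift is the
#' belief difference scaled by the weighting term omega.
#'
#' @param p_a probability that the correct item is correct, in [0, 1].
#' @param omega weighting term translating probabilities into drift rates.
#' @return drift rate; vectorized.
#' @export
drift_rate <- function(p_a, omega) {
  if (any(p_a < 0 | p_a > 1)) stop("p_a must lie in [0, 1]")
  omega * (2 * p_a - 1)
}

#' Preference-biased starting fraction
#'
#' \eqn{z = 1/(1 + e^{-\kappa \Delta v})}: a logistic (softmax) function of
#' the bid difference with inverse temperature kappa. kappa = 0 gives the
#' unbiased 0.5.
#'
#' @param delta_v bid difference in pounds.
#' @param kappa inverse temperature (per pound).
#' @return starting fraction in (0, 1); vectorized.
#' @export
start_fraction <- function(delta_v, kappa) {
  plogis(kappa * delta_v)
}

#' Log first-passage-time density
#'
#' Log density of absorption at the given boundary at time `t` (seconds,
#' including non-decision time), for a diffusion with unit noise
#' coefficient. Evaluated by automatic selection between the small-time
#' and large-time series expansions with truncation error below 1e-7.
#' Observations at or before the non-decision time are impossible and
#' return `-Inf`.
#'
#' @param t observed response time(s) in seconds.
#' @param boundary "upper" or "lower" (scalar or vector).
#' @param params a [ddm_params()].
#' @return log density, same length as `t`.
#' @export
wfpt_log_density <- function(t, boundary, params) {
  boundary <- match.arg(boundary, c("upper", "lower"), several.ok = TRUE)
  boundary <- rep_len(boundary, length(t))
  .wfpt_log_density_cpp(as.numeric(t), boundary == "upper",
                        params$d, params$a, params$z, params$s_nd)
}

#' Probability of an upper-boundary (correct) response
#'
#' Closed-form absorption probability for the two-boundary diffusion:
#' \eqn{P(upper) = (1 - e^{-2 d a z}) / (1 - e^{-2 d a})}, with the
#' zero-drift limit \eqn{P(upper) = z}.
#'
#' @param params a [ddm_params()].
#' @return probability in (0, 1).
#' @export
choice_probability <- function(params) {
  .ddm_prob_upper_cpp(params$d, params$a, params$z)
}

# vectorized internal version used by the simulation code
prob_upper_vec <- function(d, a, z) {
  va <- d * a
  out <- ifelse(abs(va) < 1e-10, z, expm1(-2 * va * z) / expm1(-2 * va))
  out
}

#' Sample choices and response times from the DDM
#'
#' Inverse-CDF sampling: the boundary is drawn from the analytic absorption
#' probability and the decision time from the numerically inverted
#' conditional first-passage CDF (trapezoid integration of the series
#' density on a 1024-point log grid). Exact in distribution up to grid
#' interpolation error; uses R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param n number of trials.
#' @param params a [ddm_params()].
#' @return data.frame with logical `upper` and numeric `rt` (seconds,
#'   non-decision time included).
#' @export
simulate_trial <- function(n, params) {
  .ddm_sample_cpp(as.integer(n), params$d, params$a, params$z, params$s_nd)
}

#' Euler-Maruyama reference simulator
#'
#' Simulates the diffusion path explicitly with time step `dt`. Slower and
#' subject to O(sqrt(dt)) discretization bias at the boundaries; kept as an
#' independent cross-check of [wfpt_log_density()] and [simulate_trial()].
#' Uses its own seeded generator so large runs are cheap.
#'
#' @param n number of trials.
#' @param params a [ddm_params()].
#' @param dt Euler time step in seconds.
#' @param seed integer seed for the internal generator.
#' @return data.frame with `upper` and `rt` as in [simulate_trial()].
#' @export
simulate_trial_em <- function(n, params, dt = 1e-4, seed = 1L) {
  .ddm_sample_em_cpp(as.integer(n), params$d, params$a, params$z,
                     params$s_nd, dt, as.integer(seed))
}
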