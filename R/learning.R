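# Inter-trial belief formation: influenced priors, Bayesian updating under
# probabilistic feedback, and a minimal Rescorla-Wagner alternative.

#' Influenced prior probability
#'
#' The belief, before any feedback, that the correct item is inferable as
#' correct: a logistic function of the preference signal and (optionally)
#' item popularity,
#' \deqn{P(A)_{n=1} = 1 / (1 + e^{-(\beta_{\Delta v} \Delta v + \beta_\rho \rho)}).}
#' With both weights zero the prior is flat (0.5).
#'
#' @param delta_v bid difference in pounds (correct minus incorrect item).
#' @param rho relative popularity in [-0.5, 0.5].
#' @param beta_dv inverse temperature on delta_v (per pound).
#' @param beta_rho inverse temperature on rho.
#' @return probability in (0, 1); vectorized over inputs.
#' @export
prior_probability <- function(delta_v, rho = 0, beta_dv = 0, beta_rho = 0) {
  plogis(beta_dv * delta_v + beta_rho * rho)
}

#' Create a belief state for one item pair
#'
#' Tracks the running posterior that the target item is correct, plus the
#' feedback counts it is based on. Internally the probability is held in
#' log-odds so long runs of one-sided feedback cannot underflow.
#'
#' @param p_a prior probability in (0, 1).
#' @param pair_id optional identifier.
#' @return object of class `belief_state` with fields `pair_id`, `p_a`,
#'   `log_odds`, `n` (feedback count), `x` (count of feedback on A).
#' @export
belief_state <- function(p_a = 0.5, pair_id = NA_character_) {
  if (p_a <= 0 || p_a >= 1) stop("p_a must lie strictly inside (0, 1)")
  structure(list(pair_id = pair_id, p_a = p_a, log_odds = qlogis(p_a),
                 n = 0L, x = 0L),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state %s: P(A)=%.4f after %d feedback (%d on A)>\n",
              x$pair_id, x$p_a, x$n, x$x))
  invisible(x)
}

#' Single Bayesian feedback update
#'
#' Multiplies the prior odds by `p_fb/(1-p_fb)` if the feedback box
#' indicated the target item A, or its reciprocal if it indicated B, per
#' Bayes's rule with the feedback reliability as likelihood. Computed in
#' log-odds space.
#'
#' @param belief a [belief_state()].
#' @param feedback_on_a logical; did feedback indicate item A?
#' @param p_fb feedback reliability (probability feedback is veridical).
#' @return updated `belief_state`.
#' @export
bayes_update <- function(belief, feedback_on_a, p_fb = 0.8) {
  stopifnot(inherits(belief, "belief_state"))
  step <- log(p_fb / (1 - p_fb))
  belief$log_odds <- belief$log_odds + if (feedback_on_a) step else -step
  belief$p_a <- plogis(belief$log_odds)
  belief$n <- belief$n + 1L
  belief$x <- belief$x + as.integer(feedback_on_a)
  belief
}

#' Posterior from aggregated feedback counts
#'
#' Equivalent closed form of n sequential updates: with x of n feedback
#' presentations indicating item A, the binomial likelihoods
#' \eqn{p_{fb}^x (1-p_{fb})^{n-x}} (A correct) and
#' \eqn{(1-p_{fb})^x p_{fb}^{n-x}} (B correct) share their binomial
#' coefficient, so the posterior log-odds are the prior log-odds plus
#' \eqn{(2x - n) \log(p_{fb}/(1-p_{fb}))}.
#'
#' @param prior prior probability in (0, 1).
#' @param x number of feedback presentations indicating item A.
#' @param n total feedback presentations.
#' @param p_fb feedback reliability.
#' @return posterior probability; vectorized over `x`, `n`.
#' @export
batch_posterior <- function(prior, x, n, p_fb = 0.8) {
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  plogis(qlogis(prior) + (2 * x - n) * log(p_fb / (1 - p_fb)))
}

#' Coupled Rescorla-Wagner update
#'
#' Minimal delta-rule alternative to the Bayesian learner: the fed-back
#' item's value moves toward 1 and the alternative toward 0 at rate
#' `alpha`, so values that start summing to one remain a complementary
#' pair. Flagged experimental: it stands in for a family of possible
#' delta-rule learners, not any particular published variant.
#'
#' @param value_a,value_b current values in [0, 1].
#' @param feedback_on_a logical; did feedback indicate item A?
#' @param alpha learning rate in (0, 1].
#' @return numeric vector c(value_a, value_b).
#' @export
rw_update <- function(value_a, value_b, feedback_on_a, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  ta <- as.numeric(feedback_on_a)
  c(value_a + alpha * (ta - value_a),
    value_b + alpha * ((1 - ta) - value_b))
}
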