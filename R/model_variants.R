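# The competing model variants: neutral, influenced prior, influenced
# choice, dual influence, and dual influence with item popularity. Each
# composes the inter-trial learner with the intra-trial DDM; variants
# differ only in which influence parameters are free.

VARIANTS <- c("neutral", "influenced_prior", "influenced_choice",
              "dual", "dual_popularity")

#' Model specification
#'
#' @param variant one of `"neutral"` (no preference influence),
#'   `"influenced_prior"` (delta_v enters the learning prior),
#'   `"influenced_choice"` (delta_v biases the DDM starting point),
#'   `"dual"` (both), `"dual_popularity"` (both, plus popularity in the
#'   prior).
#' @param learner `"bayes"` (ideal observer; default) or
#'   `"rescorla_wagner"` (experimental coupled delta rule).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(variant = c("dual", "neutral", "influenced_prior",
                                   "influenced_choice", "dual_popularity"),
                       learner = c("bayes", "rescorla_wagner")) {
  variant <- match.arg(variant)
  learner <- match.arg(learner)
  structure(list(variant = variant, learner = learner), class = "model_spec")
}

# names of the parameters a variant leaves free (besides omega, a, s_nd)
active_params <- function(spec) {
  switch(spec$variant,
         neutral = character(0),
         influenced_prior = "beta_dv",
         influenced_choice = "kappa",
         dual = c("beta_dv", "kappa"),
         dual_popularity = c("beta_dv", "beta_rho", "kappa"))
}

# zero out the parameters a variant fixes
apply_variant <- function(spec, params) {
  act <- active_params(spec)
  for (nm in c("beta_dv", "beta_rho", "kappa")) {
    if (!(nm %in% act)) params[[nm]] <- 0
  }
  params
}

#' Per-participant parameter bundle
#'
#' @param beta_dv influence of preference (delta_v) on the prior, per pound.
#' @param beta_rho influence of item popularity (rho) on the prior.
#' @param kappa influence of preference on the DDM starting point, per pound.
#' @param omega weighting term translating beliefs into drift rates.
#' @param a boundary separation (> 0).
#' @param s_nd non-decision time in seconds (>= 0; must stay below the
#'   participant's minimum response time for the likelihood to be finite).
#' @param alpha Rescorla-Wagner learning rate (only used by the
#'   `"rescorla_wagner"` learner).
#' @return list of class `participant_params`.
#' @export
participant_params <- function(beta_dv = 0, beta_rho = 0, kappa = 0,
                               omega = 1.5, a = 2, s_nd = 0.3, alpha = 0.2) {
  if (a <= 0) stop("a must be positive")
  if (s_nd < 0) stop("s_nd must be non-negative")
  structure(list(beta_dv = beta_dv, beta_rho = beta_rho, kappa = kappa,
                 omega = omega, a = a, s_nd = s_nd, alpha = alpha),
            class = "participant_params")
}

#' Log-likelihood of a single trial
#'
#' Maps the current belief to a drift rate, the preference signal to a
#' starting fraction (0.5 if the variant disables the choice bias), and
#' evaluates the Wiener first-passage log density at the observed response
#' and response time. The upper boundary is the correct item.
#'
#' @param spec a [model_spec()].
#' @param params a [participant_params()] (variant constraints are applied
#'   internally, so a dual spec ignores `beta_rho` etc.).
#' @param delta_v bid difference for the trial's pair.
#' @param p_a current belief that the correct item is correct (for the
#'   first presentation, the variant's prior; see [prior_probability()]).
#' @param resp_is_a logical; was the correct item chosen?
#' @param rt response time in seconds.
#' @return scalar log-likelihood (`-Inf` when `rt <= s_nd`).
#' @export
trial_loglik <- function(spec, params, delta_v, p_a, resp_is_a, rt) {
  params <- apply_variant(spec, params)
  d <- drift_rate(p_a, params$omega)
  z <- start_fraction(delta_v, params$kappa)
  p <- ddm_params(d = d, a = params$a, z = z, s_nd = params$s_nd)
  wfpt_log_density(rt, if (resp_is_a) "upper" else "lower", p)
}

# build the integer/logical vectors the C++ session walker needs
prepare_session <- function(trials, pairs, prefs) {
  for (pid in unique(trials$pair)) {
    nn <- trials$n[trials$pair == pid]
    if (!all(nn == seq_along(nn)))
      stop("unordered trials: presentation index must increase within pair")
  }
  pair_idx <- match(trials$pair, pairs$pair)
  if (anyNA(pair_idx)) stop("trial references unknown pair")
  item_a <- pairs$item_a[pair_idx]
  item_b <- pairs$item_b[pair_idx]
  if (!all(trials$response == item_a | trials$response == item_b))
    stop("response is not an item of the trial's pair")
  list(pair_idx = pair_idx - 1L,
       resp_is_a = trials$response == item_a,
       fb_on_a = trials$feedback_item == item_a,
       rt = trials$rt_s,
       delta_v = prefs$delta_v[match(pairs$pair, prefs$pair)],
       rho = prefs$rho[match(pairs$pair, prefs$pair)])
}

#' Per-trial log-likelihood vector for one session
#'
#' Threads beliefs pair-by-pair in presentation order: the belief entering
#' presentation n uses the displayed feedback from presentations 1..n-1
#' only (participants never observe ground truth). The sum of the vector
#' is the session's joint log-likelihood.
#'
#' @param spec a [model_spec()].
#' @param params a [participant_params()].
#' @param prefs data.frame `pair`, `delta_v`, `rho` (see
#'   [preference_pairs()]).
#' @param trials one participant's trial records in presentation order.
#' @param pairs the [item_pairs()] table.
#' @param p_fb feedback reliability assumed by the learner.
#' @return numeric vector, one log-likelihood per trial.
#' @export
session_loglik_vector <- function(spec, params, prefs, trials, pairs,
                                  p_fb = 0.8) {
  if (nrow(trials) == 0) return(numeric(0))
  params <- apply_variant(spec, params)
  ses <- prepare_session(trials, pairs, prefs)
  if (anyNA(ses$delta_v)) stop("missing delta_v for some pair")
  if (spec$learner == "bayes") {
    .session_loglik_cpp(ses$pair_idx, ses$delta_v, ses$rho,
                        ses$fb_on_a, ses$resp_is_a, ses$rt,
                        params$beta_dv, params$beta_rho, params$kappa,
                        params$omega, params$a, params$s_nd, p_fb)
  } else {
    session_loglik_rw(spec, params, ses)
  }
}

# Rescorla-Wagner path, R-level (experimental; not used by the fitter)
session_loglik_rw <- function(spec, params, ses) {
  npair <- length(ses$delta_v)
  va <- prior_probability(ses$delta_v, ses$rho, params$beta_dv, params$beta_rho)
  vb <- 1 - va
  out <- numeric(length(ses$rt))
  for (i in seq_along(ses$rt)) {
    j <- ses$pair_idx[i] + 1L
    d <- params$omega * (va[j] - vb[j])
    z <- plogis(params$kappa * ses$delta_v[j])
    out[i] <- .wfpt_log_density_cpp(ses$rt[i], ses$resp_is_a[i],
                                    d, params$a, z, params$s_nd)
    upd <- rw_update(va[j], vb[j], ses$fb_on_a[i], params$alpha)
    va[j] <- upd[1]; vb[j] <- upd[2]
  }
  out
}

#' Simulate a participant session
#'
#' Generative counterpart of [session_loglik_vector()]: runs the learner
#' and DDM forward over a schedule. Feedback is determined by the
#' schedule's `feedback_veridical` column (veridical feedback indicates
#' the correct item); belief updates condition on the displayed feedback,
#' not on ground truth. Choices and response times are drawn with
#' [simulate_trial()], so results are reproducible under `set.seed()`.
#'
#' @inheritParams session_loglik_vector
#' @param schedule a [build_schedule()] data.frame.
#' @param participant id recorded in the output.
#' @return data.frame in the `trials.csv` schema (`participant`, `pair`,
#'   `n`, `block`, `side_of_a`, `response`, `rt_s`, `feedback_item`).
#' @export
simulate_participant <- function(spec, params, prefs, schedule, pairs,
                                 participant = "sim", p_fb = 0.8) {
  params <- apply_variant(spec, params)
  nt <- nrow(schedule)
  pair_idx <- match(schedule$pair, pairs$pair)
  if (anyNA(pair_idx)) stop("schedule references unknown pair")
  dv <- prefs$delta_v[match(pairs$pair, prefs$pair)]
  rho <- prefs$rho[match(pairs$pair, prefs$pair)]
  step <- log(p_fb / (1 - p_fb))

  use_rw <- spec$learner == "rescorla_wagner"
  if (use_rw) {
    va <- prior_probability(dv, rho, params$beta_dv, params$beta_rho)
    vb <- 1 - va
  } else {
    lo <- params$beta_dv * dv + params$beta_rho * rho
  }
  z <- plogis(params$kappa * dv)

  response <- character(nt); rt <- numeric(nt); fb_item <- character(nt)
  for (i in seq_len(nt)) {
    j <- pair_idx[i]
    p_a <- if (use_rw) va[j] / (va[j] + vb[j]) else plogis(lo[j])
    d <- params$omega * (2 * p_a - 1)
    draw <- .ddm_sample_cpp(1L, d, params$a, z[j], params$s_nd)
    response[i] <- if (draw$upper[1]) pairs$item_a[j] else pairs$item_b[j]
    rt[i] <- draw$rt[1]
    ver <- schedule$feedback_veridical[i]
    fb_item[i] <- if (ver) pairs$item_a[j] else pairs$item_b[j]
    if (use_rw) {
      upd <- rw_update(va[j], vb[j], ver, params$alpha)
      va[j] <- upd[1]; vb[j] <- upd[2]
    } else {
      lo[j] <- lo[j] + if (ver) step else -step
    }
  }
  data.frame(participant = participant, pair = schedule$pair, n = schedule$n,
             block = schedule$block, side_of_a = schedule$side_of_a,
             response = response, rt_s = rt, feedback_item = fb_item,
             stringsAsFactors = FALSE)
}
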