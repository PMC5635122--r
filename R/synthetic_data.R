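# Synthetic data: preference populations with controlled inter-participant
# agreement, and behavioral datasets generated by known-parameter agents.
#
# Population model: each item i has a common-value factor c_i and each
# participant p an idiosyncratic taste e_pi, combined as
#   z_pi = sqrt(r) c_i + sqrt(1-r) e_pi,  c, e ~ N(0, 1),
# so any two participants' latent values for the same item correlate r.
# Bids are a monotone map of z to truncated-lognormal marginals on
# [0, 3], which preserves all sign comparisons. For a bivariate normal
# pair with correlation r, P(two participants order a pair the same way)
# = 1/2 + asin(r)/pi (orthant probability), so a target mean agreement A
# is hit exactly in distribution by r = sin(pi (A - 1/2)).

bid_matrix_to_df <- function(B) {
  data.frame(participant = rep(rownames(B), each = ncol(B)),
             item = rep(colnames(B), nrow(B)),
             bid_gbp = as.vector(t(B)), stringsAsFactors = FALSE)
}

choices_from_bids <- function(B, pairs) {
  ch <- matrix(NA_character_, nrow(B), nrow(pairs),
               dimnames = list(rownames(B), pairs$pair))
  for (j in seq_len(nrow(pairs))) {
    a <- pairs$item_a[j]; b <- pairs$item_b[j]
    ch[, j] <- ifelse(B[, a] >= B[, b], a, b)
  }
  ch
}

mean_pairwise_agreement <- function(choices) {
  n <- nrow(choices)
  per_pair <- apply(choices, 2, function(col) {
    k <- max(table(col))
    if (k == n) 1 else (choose(k, 2) + choose(n - k, 2)) / choose(n, 2)
  })
  mean(per_pair)
}

#' Generate a synthetic preference population
#'
#' Bids in pounds on [0, 3] for `n_participants` over `2 * n_pairs` snack
#' items, with the mean pairwise agreement (how often two participants
#' prefer the same item of a pair) controlled at `agreement`; the
#' reference population's value is 0.698. The realized agreement is
#' checked against the target (within `tol`) and the population resampled
#' up to `max_tries` times before erroring.
#'
#' @param n_participants number of participants (>= 2).
#' @param n_pairs number of item pairs (default 20).
#' @param agreement target mean pairwise agreement in [0.5, 1].
#' @param bid_meanlog,bid_sdlog lognormal bid marginal parameters (before
#'   truncation to [0, 3]).
#' @param tol acceptance tolerance on realized agreement.
#' @param max_tries resampling budget.
#' @param seed integer seed; same seed gives the same population.
#' @return list of class `preference_population`: `bids` (data.frame),
#'   `bid_matrix`, `pairs`, `choices` (participant x pair item ids),
#'   `agreement_realized`, `agreement_target`.
#' @export
generate_population <- function(n_participants, n_pairs = 20,
                                agreement = 0.698,
                                bid_meanlog = log(1), bid_sdlog = 0.8,
                                tol = 0.03, max_tries = 30L, seed = 1L) {
  if (n_participants < 2) stop("need at least 2 participants")
  if (agreement < 0.5 || agreement > 1) stop("agreement must lie in [0.5, 1]")
  r <- sin(pi * (agreement - 0.5))
  r <- min(r, 1 - 1e-9)
  n_items <- 2 * n_pairs
  items <- sprintf("i%02d", seq_len(n_items))
  pairs <- item_pairs(sprintf("p%02d", seq_len(n_pairs)),
                      items[seq(1, n_items, 2)], items[seq(2, n_items, 2)])
  ids <- sprintf("s%02d", seq_len(n_participants))
  p_max <- plnorm(3, bid_meanlog, bid_sdlog)

  set.seed(seed)
  for (attempt in seq_len(max_tries)) {
    common <- rnorm(n_items)
    z <- sqrt(r) * matrix(common, n_participants, n_items, byrow = TRUE) +
      sqrt(1 - r) * matrix(rnorm(n_participants * n_items),
                           n_participants, n_items)
    B <- qlnorm(pnorm(z) * p_max, bid_meanlog, bid_sdlog)
    dimnames(B) <- list(ids, items)
    choices <- choices_from_bids(B, pairs)
    realized <- mean_pairwise_agreement(choices)
    if (abs(realized - agreement) <= tol) {
      return(structure(list(bids = bid_matrix_to_df(B), bid_matrix = B,
                            pairs = pairs, choices = choices,
                            agreement_realized = realized,
                            agreement_target = agreement),
                       class = "preference_population"))
    }
  }
  stop(sprintf(
    "could not realize mean agreement %.3f +/- %.3f in %d tries (last %.3f); target may be unattainable at this population size",
    agreement, tol, max_tries, realized))
}

#' @export
print.preference_population <- function(x, ...) {
  cat(sprintf("<preference_population: %d participants, %d pairs, agreement %.3f (target %.3f)>\n",
              nrow(x$bid_matrix), nrow(x$pairs), x$agreement_realized,
              x$agreement_target))
  invisible(x)
}

#' Correlation between preference congruence and popularity
#'
#' Pearson correlation, across learners and pairs, between delta_v (the
#' learner's bid difference anchored to the partner-correct item) and the
#' leave-one-out popularity of the correct item. Partners are assigned in
#' a ring (each participant learns the next participant's choices).
#'
#' @param population a [generate_population()] result.
#' @return Pearson r.
#' @export
deltav_popularity_cor <- function(population) {
  B <- population$bid_matrix
  pairs <- population$pairs
  n <- nrow(B)
  dv <- matrix(NA_real_, n, nrow(pairs))
  rho <- matrix(NA_real_, n, nrow(pairs))
  # popularity counts per pair (shares of the population preferring item_a)
  prefers_a <- 1 * (B[, pairs$item_a] > B[, pairs$item_b]) +
    0.5 * (B[, pairs$item_a] == B[, pairs$item_b])
  tot_a <- colSums(prefers_a)
  for (p in seq_len(n)) {
    partner <- if (p == n) 1L else p + 1L
    correct_a <- population$choices[partner, ] == pairs$item_a
    sign <- ifelse(correct_a, 1, -1)
    dv[p, ] <- sign * (B[p, pairs$item_a] - B[p, pairs$item_b])
    frac_a <- (tot_a - prefers_a[p, ]) / (n - 1)
    rho[p, ] <- ifelse(correct_a, frac_a, 1 - frac_a) - 0.5
  }
  cor(as.vector(dv), as.vector(rho))
}

#' Group-level generating parameters
#'
#' The study conditions used by the synthetic behavior generator:
#' participant parameters are drawn from normal distributions with these
#' means and SDs (omega and a truncated positive), non-decision time
#' uniform on `s_nd_range`. Defaults: omega 1.53 and a 2.10 (the reference
#' task's fitted group means), with influence weights chosen once as
#' plausible per-pound scales (see the vignette).
#'
#' @param beta_dv,beta_dv_sd prior preference weight (per pound).
#' @param beta_rho,beta_rho_sd prior popularity weight.
#' @param kappa,kappa_sd starting-point preference weight (per pound).
#' @param omega,omega_sd drift weight.
#' @param a,a_sd boundary separation.
#' @param s_nd_range non-decision time range in seconds.
#' @return list of class `group_params`.
#' @export
group_params <- function(beta_dv = 0.55, beta_dv_sd = 0.25,
                         beta_rho = 1.0, beta_rho_sd = 0.5,
                         kappa = 0.15, kappa_sd = 0.08,
                         omega = 1.53, omega_sd = 0.3,
                         a = 2.10, a_sd = 0.3,
                         s_nd_range = c(0.25, 0.45)) {
  structure(list(beta_dv = beta_dv, beta_dv_sd = beta_dv_sd,
                 beta_rho = beta_rho, beta_rho_sd = beta_rho_sd,
                 kappa = kappa, kappa_sd = kappa_sd,
                 omega = omega, omega_sd = omega_sd, a = a, a_sd = a_sd,
                 s_nd_range = s_nd_range),
            class = "group_params")
}

rtnorm_pos <- function(n, mu, sd) {
  x <- rnorm(n, mu, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mu, sd)
  x
}

#' Draw participant parameters from group-level distributions
#'
#' @param n number of participants.
#' @param group a [group_params()].
#' @return data.frame, one row per participant.
#' @export
draw_participant_params <- function(n, group = group_params()) {
  data.frame(
    beta_dv = rnorm(n, group$beta_dv, group$beta_dv_sd),
    beta_rho = rnorm(n, group$beta_rho, group$beta_rho_sd),
    kappa = rnorm(n, group$kappa, group$kappa_sd),
    omega = rtnorm_pos(n, group$omega, group$omega_sd),
    a = rtnorm_pos(n, group$a, group$a_sd),
    s_nd = runif(n, group$s_nd_range[1], group$s_nd_range[2]))
}

#' Generate a full behavioral dataset from known parameters
#'
#' One designated participant of the population acts as the partner whose
#' choices define the correct item of every pair (the pairs table is
#' re-oriented so `item_a` is the partner's choice); the remaining
#' participants are learners simulated with [simulate_participant()]
#' under parameters drawn from `group`. Each learner gets an independent
#' pseudorandomized schedule.
#'
#' @param population a [generate_population()] result.
#' @param spec a [model_spec()] naming the generating variant.
#' @param group a [group_params()].
#' @param presentations,blocks,p_fb,feedback schedule settings (see
#'   [build_schedule()]).
#' @param partner id of the partner participant (default: the last one,
#'   excluded from the learners).
#' @param seed integer seed.
#' @return list with `bids`, `pairs` (oriented), `trials`, `true_params`
#'   (per-learner generating values, zeroed where the variant fixes them),
#'   `schedules`.
#' @export
generate_behavior <- function(population, spec = model_spec("dual"),
                              group = group_params(), presentations = 30L,
                              blocks = 3L, p_fb = 0.8,
                              feedback = "balanced", partner = NULL,
                              seed = 1L) {
  set.seed(seed)
  ids <- rownames(population$bid_matrix)
  if (is.null(partner)) partner <- ids[length(ids)]
  learners <- setdiff(ids, partner)
  pairs0 <- population$pairs
  correct <- population$choices[partner, ]
  pairs <- item_pairs(pairs0$pair, correct,
                      ifelse(correct == pairs0$item_a,
                             pairs0$item_b, pairs0$item_a))
  params <- draw_participant_params(length(learners), group)
  rownames(params) <- learners
  # zero the parameters the generating variant fixes, so true values match
  for (i in seq_len(nrow(params))) {
    pp <- do.call(participant_params, as.list(params[i, ]))
    pp <- apply_variant(spec, pp)
    params[i, c("beta_dv", "beta_rho", "kappa")] <-
      unlist(pp[c("beta_dv", "beta_rho", "kappa")])
  }
  trials <- vector("list", length(learners))
  schedules <- vector("list", length(learners))
  for (i in seq_along(learners)) {
    id <- learners[i]
    prefs <- preference_pairs(population$bids, pairs, id)
    sched <- build_schedule(pairs, presentations = presentations %/% blocks,
                            blocks = blocks, p_fb = p_fb, feedback = feedback)
    schedules[[i]] <- sched
    pp <- do.call(participant_params, as.list(params[i, ]))
    trials[[i]] <- simulate_participant(spec, pp, prefs, sched, pairs,
                                        participant = id, p_fb = p_fb)
  }
  list(bids = population$bids, pairs = pairs,
       trials = do.call(rbind, trials), true_params = params,
       schedules = setNames(schedules, learners), partner = partner)
}

#' Deterministic fixture bundles
#'
#' Small, seeded datasets used throughout the test-suite: `"smoke"` (4
#' learners x 5 pairs x 6 presentations), `"recovery"` (20 learners x 20
#' pairs x 30 presentations from dual-influence agents), `"grid"` (a
#' 12-participant preference population, no behavior).
#'
#' @param name `"smoke"`, `"recovery"` or `"grid"`.
#' @param dir optional directory; when given the dataset is written with
#'   [write_dataset()].
#' @return the dataset bundle (for `"grid"`, the population).
#' @export
make_fixture <- function(name = c("smoke", "recovery", "grid"), dir = NULL) {
  name <- match.arg(name)
  out <- switch(name,
    smoke = {
      pop <- generate_population(5, n_pairs = 5, seed = 101)
      generate_behavior(pop, model_spec("dual"), group_params(),
                        presentations = 6L, blocks = 3L,
                        feedback = "bernoulli", seed = 102)
    },
    recovery = {
      pop <- generate_population(21, n_pairs = 20, seed = 201)
      generate_behavior(pop, model_spec("dual"), group_params(),
                        presentations = 30L, blocks = 3L, seed = 202)
    },
    grid = generate_population(12, n_pairs = 20, seed = 301))
  if (!is.null(dir) && name != "grid") write_dataset(out, dir)
  out
}
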