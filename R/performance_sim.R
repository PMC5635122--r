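# Strategy-advantage simulations: how much does being influenced by one's
# own preferences (through the prior, the choice bias, or both) help or
# hurt relative to a neutral Bayesian actor with the same drift weight and
# threshold?
#
# The engine exploits two exact identities to cut Monte-Carlo variance:
# feedback does not depend on the agent's responses, so (1) the same
# feedback realizations are shared by every strategy cell and the neutral
# comparator (common random numbers), and (2) accuracy is reported as the
# mean analytic probability of a correct response given the belief state
# (Rao-Blackwellized over the within-trial diffusion noise), which has the
# same expectation as drawing the choices.

#' Simulation configuration
#'
#' @param kappa_grid,beta_grid numeric axes of the strategy grid (absolute
#'   parameter values; use [grid_from_multiples()] to express them as
#'   multiples of fitted group means).
#' @param reps feedback realizations per dyad.
#' @param omega,a,s_nd DDM parameters shared by every strategy including
#'   the neutral comparator (defaults 1.53 and 2.10, the reference task's
#'   fitted group means).
#' @param p_fb feedback reliability in (0.5, 1].
#' @param presentations,blocks schedule shape per pair.
#' @param feedback `"balanced"` (exact veridical count per block) or
#'   `"bernoulli"`.
#' @param max_dyads optional cap on the number of (learner, partner)
#'   ordered dyads, subsampled without replacement.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(kappa_grid = seq(0, 8 * 0.15, length.out = 17),
                       beta_grid = seq(0, 8 * 0.55, length.out = 17),
                       reps = 100L, omega = 1.53, a = 2.10, s_nd = 0.3,
                       p_fb = 0.8, presentations = 30L, blocks = 3L,
                       feedback = c("balanced", "bernoulli"),
                       max_dyads = NULL, seed = 1L) {
  if (p_fb <= 0.5 || p_fb > 1) stop("p_fb must lie in (0.5, 1]")
  if (reps < 1) stop("reps must be >= 1")
  structure(list(kappa_grid = kappa_grid, beta_grid = beta_grid,
                 reps = as.integer(reps), omega = omega, a = a, s_nd = s_nd,
                 p_fb = p_fb, presentations = as.integer(presentations),
                 blocks = as.integer(blocks),
                 feedback = match.arg(feedback),
                 max_dyads = max_dyads, seed = as.integer(seed)),
            class = "sim_config")
}

#' Express grid axes as multiples of fitted group means
#'
#' @param kappa_mean,beta_mean group-mean parameter values (e.g. posterior
#'   means from [fit_hierarchical()]).
#' @param multiples numeric multipliers (the reference analysis used 0-8).
#' @param n number of grid points.
#' @return list with `kappa_grid` and `beta_grid`.
#' @export
grid_from_multiples <- function(kappa_mean, beta_mean,
                                multiples = c(0, 8), n = 17) {
  list(kappa_grid = seq(multiples[1] * kappa_mean, multiples[2] * kappa_mean,
                        length.out = n),
       beta_grid = seq(multiples[1] * beta_mean, multiples[2] * beta_mean,
                       length.out = n))
}

# within-column ranks of a (rows x C) uniform matrix, used to place the
# non-veridical feedback trials uniformly at random within each block
col_ranks <- function(u) {
  nr <- nrow(u); C <- ncol(u)
  o <- order(col(u), u)
  rk <- integer(nr * C)
  rk[o] <- rep(seq_len(nr), C)
  matrix(rk, nr, C)
}

# feedback veridicality array: presentations x C columns
draw_feedback <- function(C, config) {
  per_block <- config$presentations / config$blocks
  if (config$feedback == "bernoulli") {
    return(matrix(runif(config$presentations * C) < config$p_fb,
                  config$presentations, C))
  }
  n_true <- round(per_block * config$p_fb)
  out <- matrix(NA, config$presentations, C)
  for (b in seq_len(config$blocks)) {
    rk <- col_ranks(matrix(runif(per_block * C), per_block, C))
    out[(b - 1) * per_block + seq_len(per_block), ] <- rk <= n_true
  }
  out
}

# Core engine. dv: delta_v per column-group unit (one value per
# (dyad, pair)); returns p(correct) as a C x presentations matrix where
# C = length(dv) * reps, plus the grouping needed for session means.
# evid: precomputed C x presentations matrix of cumulative feedback
# log-odds steps (excluding the trial's own feedback).
accuracy_matrix <- function(dv_cols, evid, kappa, beta, omega, a) {
  lo <- beta * dv_cols + evid          # dv_cols recycles down columns
  p <- plogis(lo)
  d <- omega * (2 * p - 1)
  z <- plogis(kappa * dv_cols)
  prob_upper_vec(d, a, z)
}

build_evidence <- function(dv, config) {
  C <- length(dv) * config$reps
  ver <- draw_feedback(C, config)
  step <- log(config$p_fb / (1 - config$p_fb))
  s <- apply(2 * ver - 1, 2, cumsum)            # presentations x C
  evid <- t(rbind(0, s[-nrow(s), , drop = FALSE])) * step  # C x presentations
  evid
}

#' Simulate one learner-partner dyad
#'
#' Runs the two-level agent with the learner's preference signal per pair
#' (sign-anchored to the partner's choice) over `reps` feedback
#' realizations and returns expected accuracy by presentation index.
#'
#' @param delta_v numeric vector: the learner's bid difference for each
#'   pair, positive when the learner shares the partner's preference.
#' @param kappa,beta_dv the strategy's influence parameters.
#' @param config a [sim_config()] (grids are ignored here).
#' @return numeric vector of length `config$presentations`: P(correct) by
#'   presentation index, averaged over pairs and reps.
#' @export
simulate_dyad <- function(delta_v, kappa, beta_dv, config = sim_config()) {
  if (any(is.na(delta_v))) stop("delta_v must be defined for every pair")
  set.seed(config$seed)
  dv_cols <- rep(delta_v, config$reps)
  evid <- build_evidence(delta_v, config)
  acc <- accuracy_matrix(dv_cols, evid, kappa, beta_dv, config$omega, config$a)
  colMeans(acc)
}

# delta_v for every ordered dyad of a population: list with one numeric
# vector (pairs) per dyad, names "learner->partner"
dyad_delta_v <- function(population, max_dyads = NULL) {
  B <- population$bid_matrix
  pairs <- population$pairs
  ids <- rownames(B)
  combos <- expand.grid(learner = ids, partner = ids,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$learner != combos$partner, ]
  if (!is.null(max_dyads) && nrow(combos) > max_dyads)
    combos <- combos[sample.int(nrow(combos), max_dyads), ]
  lapply(seq_len(nrow(combos)), function(i) {
    L <- combos$learner[i]; P <- combos$partner[i]
    correct <- population$choices[P, ]
    other <- ifelse(correct == pairs$item_a, pairs$item_b, pairs$item_a)
    setNames(B[L, correct] - B[L, other], pairs$pair)
  })
}

#' Strategy-advantage grid
#'
#' For every (kappa, beta_dv) cell, the mean percentage-point accuracy
#' advantage over a neutral Bayesian actor (kappa = 0, beta_dv = 0) with
#' identical omega and a, sharing the same feedback realizations. Dyads
#' pair every participant with every other participant (optionally
#' subsampled via `config$max_dyads`).
#'
#' @param population a [generate_population()] result (or any list with
#'   `bid_matrix`, `choices`, `pairs`).
#' @param config a [sim_config()].
#' @return object of class `strategy_advantage`: `grid` (long data.frame
#'   `kappa`, `beta_dv`, `advantage_pp`, `mc_se`), `curves` (per-cell
#'   advantage by presentation index, percentage points), `neutral_curve`
#'   (neutral accuracy by presentation index), `config`.
#' @export
advantage_grid <- function(population, config = sim_config()) {
  set.seed(config$seed)
  dyads <- dyad_delta_v(population, config$max_dyads)
  if (length(dyads) < 1) stop("need at least 2 participants for dyads")
  P <- length(dyads[[1]])
  dv <- unlist(dyads, use.names = FALSE)          # (pair, dyad)
  dv_cols <- rep(dv, config$reps)
  evid <- build_evidence(dv, config)
  # session grouping: one session = (dyad, rep); pairs averaged within
  session <- rep(seq_len(length(dyads) * config$reps), each = P)

  acc0 <- accuracy_matrix(dv_cols, evid, 0, 0, config$omega, config$a)
  sess0 <- rowsum(rowMeans(acc0), session) / P
  curve0 <- colMeans(acc0)

  nk <- length(config$kappa_grid); nb <- length(config$beta_grid)
  grid <- expand.grid(kappa = config$kappa_grid, beta_dv = config$beta_grid)
  grid$advantage_pp <- NA_real_; grid$mc_se <- NA_real_
  curves <- matrix(NA_real_, nrow(grid), config$presentations)
  for (i in seq_len(nrow(grid))) {
    acc <- accuracy_matrix(dv_cols, evid, grid$kappa[i], grid$beta_dv[i],
                           config$omega, config$a)
    dsess <- rowsum(rowMeans(acc), session) / P - sess0
    grid$advantage_pp[i] <- 100 * mean(dsess)
    grid$mc_se[i] <- 100 * sd(dsess) / sqrt(length(dsess))
    curves[i, ] <- 100 * (colMeans(acc) - curve0)
  }
  structure(list(grid = grid, curves = curves, neutral_curve = curve0,
                 config = config),
            class = "strategy_advantage")
}

#' @export
print.strategy_advantage <- function(x, ...) {
  best <- x$grid[which.max(x$grid$advantage_pp), ]
  cat(sprintf(
    "<strategy_advantage: %d cells, best %.2f pp (MC SE %.2f) at kappa=%.3g beta_dv=%.3g>\n",
    nrow(x$grid), best$advantage_pp, best$mc_se, best$kappa, best$beta_dv))
  invisible(x)
}

#' Permuted-preference (random) control population
#'
#' Shuffles each participant's bid vector across items, preserving the
#' marginal bid distribution while destroying the alignment between own
#' preferences and partners' choices. Partner choices are recomputed from
#' the permuted bids of the partner, while learners' delta_v comes from
#' their own permuted bids, so preference no longer predicts the correct
#' answer.
#'
#' @param population a [generate_population()] result.
#' @param seed integer seed.
#' @return population list of the same shape.
#' @export
permute_preferences <- function(population, seed = 1L) {
  set.seed(seed)
  B <- population$bid_matrix
  for (i in seq_len(nrow(B))) B[i, ] <- B[i, sample.int(ncol(B))]
  pop <- population
  pop$bid_matrix <- B
  pop$choices <- choices_from_bids(B, population$pairs)
  pop$bids <- bid_matrix_to_df(B)
  pop
}

#' Expected strategy value under transfer uncertainty
#'
#' Linear blend of a strategy's value in the predictive and random
#' regimes: \eqn{E = p(random) V_{random} + (1 - p(random)) V_{predictive}}.
#'
#' @param p_random probability that stimulus values do not transfer.
#' @param v_random,v_predictive strategy values under each regime.
#' @return expected value; vectorized.
#' @export
expected_value <- function(p_random, v_random, v_predictive) {
  if (any(p_random < 0 | p_random > 1)) stop("p_random must lie in [0, 1]")
  p_random * v_random + (1 - p_random) * v_predictive
}

#' Best strategy cell across transfer uncertainty
#'
#' Applies [expected_value()] cellwise to a predictive-regime and a
#' random-regime advantage grid sharing the same axes, and reports the
#' argmax cell(s) for each p_random. Ties (within numerical equality) are
#' all returned.
#'
#' @param adv_predictive,adv_random `strategy_advantage` objects on
#'   identical grids.
#' @param p_random numeric vector of transfer-failure probabilities.
#' @return data.frame `p_random`, `kappa`, `beta_dv`, `expected_pp`.
#' @export
efficiency_map <- function(adv_predictive, adv_random,
                           p_random = seq(0, 1, by = 0.1)) {
  gp <- adv_predictive$grid; gr <- adv_random$grid
  if (!isTRUE(all.equal(gp[, c("kappa", "beta_dv")],
                        gr[, c("kappa", "beta_dv")])))
    stop("advantage grids do not share axes")
  out <- lapply(p_random, function(p) {
    e <- expected_value(p, gr$advantage_pp, gp$advantage_pp)
    best <- which(e >= max(e) - 1e-12)
    data.frame(p_random = p, kappa = gp$kappa[best],
               beta_dv = gp$beta_dv[best], expected_pp = e[best])
  })
  do.call(rbind, out)
}
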