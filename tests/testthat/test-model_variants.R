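test_that("session log-likelihoods match an independent sequential computation", {
  ds <- smoke_dataset()
  spec <- model_spec("dual_popularity")
  pp <- participant_params(beta_dv = 0.6, beta_rho = 0.8, kappa = 0.2,
                           omega = 1.4, a = 1.9, s_nd = 0.2)
  id <- unique(ds$trials$participant)[1]
  trials <- ds$trials[ds$trials$participant == id, ]
  prefs <- preference_pairs(ds$bids, ds$pairs, id)

  vec <- session_loglik_vector(spec, pp, prefs, trials, ds$pairs)
  expect_length(vec, nrow(trials))

  # oracle: explicit R loop over belief_state / trial_loglik
  beliefs <- list()
  oracle <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    pid <- trials$pair[i]
    k <- match(pid, ds$pairs$pair)
    if (is.null(beliefs[[pid]])) {
      pr <- prior_probability(prefs$delta_v[match(pid, prefs$pair)],
                              prefs$rho[match(pid, prefs$pair)],
                              pp$beta_dv, pp$beta_rho)
      beliefs[[pid]] <- belief_state(pr, pid)
    }
    oracle[i] <- trial_loglik(spec, pp,
                              delta_v = prefs$delta_v[match(pid, prefs$pair)],
                              p_a = beliefs[[pid]]$p_a,
                              resp_is_a = trials$response[i] == ds$pairs$item_a[k],
                              rt = trials$rt_s[i])
    beliefs[[pid]] <- bayes_update(beliefs[[pid]],
                                   trials$feedback_item[i] == ds$pairs$item_a[k])
  }
  expect_equal(vec, oracle, tolerance = 1e-10)
})

test_that("zeroing parameters reproduces the nested variants exactly", {
  ds <- smoke_dataset()
  id <- unique(ds$trials$participant)[2]
  trials <- ds$trials[ds$trials$participant == id, ]
  prefs <- preference_pairs(ds$bids, ds$pairs, id)
  base <- participant_params(beta_dv = 0.7, beta_rho = 0.9, kappa = 0.25,
                             omega = 1.5, a = 2, s_nd = 0.22)
  ll <- function(spec, ...) {
    p <- base
    mods <- list(...)
    for (nm in names(mods)) p[[nm]] <- mods[[nm]]
    session_loglik_vector(spec, p, prefs, trials, ds$pairs)
  }
  dual <- model_spec("dual")
  # dual ignores beta_rho entirely
  expect_identical(ll(dual), ll(model_spec("dual_popularity"), beta_rho = 0))
  # dual with kappa = 0 is the influenced-prior model
  expect_identical(ll(dual, kappa = 0), ll(model_spec("influenced_prior")))
  # dual with beta_dv = 0 is the influenced-choice model
  expect_identical(ll(dual, beta_dv = 0), ll(model_spec("influenced_choice")))
  # both zero: neutral
  expect_identical(ll(dual, kappa = 0, beta_dv = 0), ll(model_spec("neutral")))
})

test_that("beliefs never use feedback from the current or later presentations", {
  ds <- smoke_dataset()
  id <- unique(ds$trials$participant)[1]
  trials <- ds$trials[ds$trials$participant == id, ]
  prefs <- preference_pairs(ds$bids, ds$pairs, id)
  spec <- model_spec("dual")
  pp <- participant_params(beta_dv = 0.5, kappa = 0.2)
  base <- session_loglik_vector(spec, pp, prefs, trials, ds$pairs)

  # flip the feedback of one pair's first presentation: only later
  # presentations of that pair may change
  pid <- trials$pair[1]
  k <- match(pid, ds$pairs$pair)
  i1 <- which(trials$pair == pid)[1]
  mod <- trials
  mod$feedback_item[i1] <- ifelse(mod$feedback_item[i1] == ds$pairs$item_a[k],
                                  ds$pairs$item_b[k], ds$pairs$item_a[k])
  after <- session_loglik_vector(spec, pp, prefs, mod, ds$pairs)
  same_pair_later <- trials$pair == pid & seq_len(nrow(trials)) > i1
  expect_equal(base[!same_pair_later], after[!same_pair_later])
  expect_false(isTRUE(all.equal(base[same_pair_later], after[same_pair_later])))
})

test_that("session vectors are additive, ordered, and error on bad input", {
  ds <- smoke_dataset()
  id <- unique(ds$trials$participant)[1]
  trials <- ds$trials[ds$trials$participant == id, ]
  prefs <- preference_pairs(ds$bids, ds$pairs, id)
  spec <- model_spec("dual")
  pp <- participant_params(beta_dv = 0.5, kappa = 0.2)

  expect_identical(
    session_loglik_vector(spec, pp, prefs, trials[0, ], ds$pairs),
    numeric(0))
  # unordered presentations are rejected
  shuffled <- trials[rev(seq_len(nrow(trials))), ]
  expect_error(session_loglik_vector(spec, pp, prefs, shuffled, ds$pairs),
               "unordered")
  # rt at or below non-decision time yields -Inf for that trial
  slow <- participant_params(s_nd = min(trials$rt_s) + 0.01)
  v <- session_loglik_vector(model_spec("neutral"), slow, prefs, trials, ds$pairs)
  expect_true(any(v == -Inf))
  expect_identical(which(v == -Inf), which(trials$rt_s <= slow$s_nd))
})

test_that("the Rescorla-Wagner learner path matches an explicit delta-rule loop", {
  ds <- smoke_dataset()
  id <- unique(ds$trials$participant)[3]
  trials <- ds$trials[ds$trials$participant == id, ]
  prefs <- preference_pairs(ds$bids, ds$pairs, id)
  spec <- model_spec("dual", learner = "rescorla_wagner")
  pp <- participant_params(beta_dv = 0.5, kappa = 0.2, alpha = 0.3)
  vec <- session_loglik_vector(spec, pp, prefs, trials, ds$pairs)

  va <- prior_probability(prefs$delta_v, 0, pp$beta_dv, 0)
  vb <- 1 - va
  oracle <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    k <- match(trials$pair[i], prefs$pair)
    d <- pp$omega * (va[k] - vb[k])
    par <- ddm_params(d, pp$a, plogis(pp$kappa * prefs$delta_v[k]), pp$s_nd)
    oracle[i] <- wfpt_log_density(
      trials$rt_s[i],
      if (trials$response[i] == ds$pairs$item_a[k]) "upper" else "lower", par)
    upd <- rw_update(va[k], vb[k],
                     trials$feedback_item[i] == ds$pairs$item_a[k], pp$alpha)
    va[k] <- upd[1]; vb[k] <- upd[2]
  }
  expect_equal(vec, oracle, tolerance = 1e-10)
})

test_that("simulated participants behave like the generating process", {
  pairs <- item_pairs(sprintf("p%d", 1:5), sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  prefs <- data.frame(pair = pairs$pair, delta_v = c(-2, -1, 0, 1, 2), rho = 0)
  sched <- build_schedule(pairs, presentations = 6L, blocks = 1L,
                          feedback = "bernoulli", seed = 21)
  # neutral spec: first-presentation accuracy is 0.5 in expectation
  set.seed(22)
  neut <- participant_params(omega = 1.5, a = 2, s_nd = 0.3)
  firsts <- replicate(150, {
    tr <- simulate_participant(model_spec("neutral"), neut, prefs, sched, pairs)
    f <- tr[tr$n == 1, ]
    mean(f$response == pairs$item_a[match(f$pair, pairs$pair)])
  })
  n_obs <- 150 * 5
  expect_lt(abs(mean(firsts) - 0.5), 3 * sqrt(0.25 / n_obs))
  # learning: later presentations are more accurate than first ones
  # (balanced feedback guarantees net veridical evidence per pair)
  sched10 <- build_schedule(pairs, presentations = 10L, blocks = 1L,
                            feedback = "balanced", seed = 24)
  set.seed(23)
  accs <- replicate(60, {
    tr <- simulate_participant(model_spec("dual"),
                               participant_params(beta_dv = 0.6, kappa = 0.2),
                               prefs, sched10, pairs)
    correct <- tr$response == pairs$item_a[match(tr$pair, pairs$pair)]
    c(first = mean(correct[tr$n == 1]), last = mean(correct[tr$n == 10]))
  })
  expect_gt(mean(accs["last", ]), mean(accs["first", ]) + 0.1)
  # all response times exceed non-decision time
  tr <- simulate_participant(model_spec("dual"), neut, prefs, sched, pairs)
  expect_true(all(tr$rt_s > neut$s_nd))
})
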