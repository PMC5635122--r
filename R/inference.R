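# Hierarchical Bayesian estimation and predictive model comparison.
#
# Structure of the joint density: each participant's beta_dv, beta_rho,
# kappa, omega and a (as free in the variant) are drawn from group-level
# normal distributions with mean mu and SD sigma (omega, a truncated
# positive); non-decision time is per-participant, non-hierarchical,
# uniform on (0, min RT). Sampling is adaptive random-walk
# Metropolis-within-Gibbs: one block per participant, one block per
# group-level (mu, log sigma) pair, with proposal scales adapted toward a
# 30% acceptance rate during warmup only.

HIER_PARAMS <- c("beta_dv", "beta_rho", "kappa", "omega", "a")
POSITIVE_PARAMS <- c("omega", "a")

#' Default weakly-informative hyperpriors
#'
#' Group means: normal(0, 2) for the influence parameters, normal(1.5, 1)
#' truncated positive for omega, normal(2, 1) truncated positive for a.
#' Group SDs: half-normal(1). Non-decision time: uniform(0, min RT) per
#' participant. All scales overridable.
#'
#' @return named list of c(location, scale) pairs plus `sigma_scale`.
#' @export
default_hyperpriors <- function() {
  list(beta_dv = c(0, 2), beta_rho = c(0, 2), kappa = c(0, 2),
       omega = c(1.5, 1), a = c(2, 1), sigma_scale = 1)
}

# participant-level log prior: normal(mu, sigma), truncated >0 for omega/a
lp_participant <- function(x, mu, sigma, positive) {
  lp <- dnorm(x, mu, sigma, log = TRUE)
  if (positive) {
    if (x <= 0) return(-Inf)
    lp <- lp - pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  }
  lp
}

# univariate slice sampler (stepping out + shrinkage); used for the
# group-level conditionals, which are 1-D, cheap and unimodal
slice1 <- function(logf, x0, w = 0.5, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  ly <- f0 - stats::rexp(1)
  L <- x0 - runif(1) * w
  R <- L + w
  k <- max_steps
  while (k > 0 && is.finite(logf(L)) && logf(L) > ly) { L <- L - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && is.finite(logf(R)) && logf(R) > ly) { R <- R + w; k <- k - 1 }
  for (i in 1:100) {
    x1 <- runif(1, L, R)
    f1 <- logf(x1)
    if (is.finite(f1) && f1 >= ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

lp_hyper <- function(mu, sigma, prior, positive, sigma_scale) {
  lp <- dnorm(mu, prior[1], prior[2], log = TRUE) +
    dnorm(sigma, 0, sigma_scale, log = TRUE)   # half-normal, sigma > 0
  if (sigma <= 0) return(-Inf)
  if (positive && mu <= -5 * sigma) return(-Inf)  # guard degenerate truncation
  lp
}

# assemble per-participant session data once (validated, 0-based indices)
build_sessions <- function(dataset, pairs = NULL) {
  bids <- dataset$bids
  pairs <- if (is.null(pairs)) dataset$pairs else pairs
  trials <- dataset$trials
  ids <- unique(trials$participant)
  sessions <- lapply(ids, function(id) {
    tr <- trials[trials$participant == id, , drop = FALSE]
    prefs <- preference_pairs(bids, pairs, id)
    ses <- prepare_session(tr, pairs, prefs)
    ses$min_rt <- min(ses$rt)
    ses$n_trials <- length(ses$rt)
    ses$fb_int <- as.integer(ses$fb_on_a)
    ses$resp_int <- as.integer(ses$resp_is_a)
    ses
  })
  names(sessions) <- ids
  sessions
}

#' Fit a model variant hierarchically
#'
#' Posterior sampling of all participant- and group-level parameters by
#' adaptive Metropolis-within-Gibbs (see the package vignette for the
#' sampler design). Convergence is checked with split-R-hat and effective
#' sample size on every latent; failures raise a loud warning carrying the
#' diagnostic table and set `convergence_ok = FALSE` rather than silently
#' succeeding.
#'
#' @param spec a [model_spec()] (learner must be `"bayes"`).
#' @param dataset list with `bids`, `pairs`, `trials` (see
#'   [read_dataset()]).
#' @param p_fb feedback reliability assumed by the learner.
#' @param chains number of chains (>= 2 for diagnostics).
#' @param iter total iterations per chain (including warmup).
#' @param warmup adaptation iterations discarded from the draws.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; identical seed and configuration give
#'   identical draws.
#' @param hyperpriors see [default_hyperpriors()].
#' @param rhat_max split-R-hat threshold for the convergence gate.
#' @return object of class `prefdiff_fit`: draws (`chains` x kept x
#'   params array), `diagnostics` (R-hat/ESS per parameter), the frozen
#'   session data, and bookkeeping.
#' @export
fit_hierarchical <- function(spec, dataset, p_fb = 0.8, chains = 2L,
                             iter = 3000L, warmup = floor(iter / 2),
                             thin = max(1L, floor((iter - warmup) / 500)),
                             seed = 1L, hyperpriors = default_hyperpriors(),
                             rhat_max = 1.01) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$learner != "bayes")
    stop("hierarchical fitting is implemented for the Bayesian learner")
  sessions <- build_sessions(dataset)
  np <- length(sessions)
  hier <- c(active_params(spec), "omega", "a")
  part_par <- c(hier, "s_nd")

  par_names <- c(
    unlist(lapply(names(sessions), function(id) paste0(part_par, "[", id, "]"))),
    paste0("mu_", hier), paste0("sigma_", hier))
  n_keep <- floor((iter - warmup) / thin)
  draws <- array(NA_real_, dim = c(chains, n_keep, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))

  PARAM6 <- c("beta_dv", "beta_rho", "kappa", "omega", "a", "s_nd")
  base_sd <- c(beta_dv = 0.2, beta_rho = 0.4, kappa = 0.12, omega = 0.12,
               a = 0.1, s_nd = 0.03)
  init_mu <- c(beta_dv = 0.3, beta_rho = 0.3, kappa = 0.15, omega = 1.5, a = 2)
  update6 <- PARAM6 %in% part_par
  hier6 <- PARAM6 %in% hier
  pos6 <- PARAM6 %in% POSITIVE_PARAMS
  sel <- match(part_par, PARAM6)   # stored-draw order per participant

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    mu <- init_mu[hier] * (1 + 0.1 * (ch - 1))
    sigma <- setNames(rep(0.4, length(hier)), hier)
    theta <- lapply(sessions, function(ses) {
      th <- setNames(numeric(6), PARAM6)
      th[hier] <- mu + rnorm(length(hier), 0, 0.05)
      th[["omega"]] <- max(th[["omega"]], 0.2)
      th[["a"]] <- max(th[["a"]], 0.5)
      th[["s_nd"]] <- 0.5 * ses$min_rt
      th
    })
    cur_ll <- rep(NA_real_, np)   # recomputed lazily by the first sweep

    # per-coordinate proposal scales, adapted toward 44% acceptance
    log_scale_p <- matrix(0, np, 6, dimnames = list(NULL, PARAM6))
    k <- 0L
    mu6 <- sigma6 <- setNames(numeric(6), PARAM6)
    for (it in seq_len(iter)) {
      gam <- if (it <= warmup) 1 / (20 + it)^0.6 else 0
      mu6[hier] <- mu; sigma6[hier] <- sigma; sigma6[!hier6] <- 1
      # participant blocks: componentwise random-walk Metropolis in C++
      for (p in seq_len(np)) {
        ses <- sessions[[p]]
        res <- .mh_sweep_cpp(ses$pair_idx, ses$delta_v, ses$rho,
                             ses$fb_int, ses$resp_int, ses$rt,
                             theta[[p]], cur_ll[p], update6,
                             exp(log_scale_p[p, ]) * base_sd,
                             mu6, sigma6, hier6, pos6, ses$min_rt, p_fb)
        theta[[p]][] <- res$theta
        cur_ll[p] <- res$loglik
        if (gam > 0) {
          ap <- res$acc_prob
          upd <- !is.na(ap)
          log_scale_p[p, upd] <- log_scale_p[p, upd] +
            gam * (ap[upd] - 0.44) * 3
        }
      }
      # group-level blocks: slice-sample mu_j and log sigma_j
      for (nm in hier) {
        pos <- nm %in% POSITIVE_PARAMS
        pr <- hyperpriors[[nm]]
        th_nm <- vapply(theta, function(th) th[[nm]], numeric(1))
        cond <- function(m, s) {
          lp <- lp_hyper(m, s, pr, pos, hyperpriors$sigma_scale)
          if (!is.finite(lp)) return(-Inf)
          ll <- dnorm(th_nm, m, s, log = TRUE)
          if (pos) ll <- ll - pnorm(0, m, s, lower.tail = FALSE, log.p = TRUE)
          lp + sum(ll)
        }
        mu[nm] <- slice1(function(m) cond(m, sigma[nm]), mu[nm], w = 0.4)
        ls <- slice1(function(l) cond(mu[nm], exp(l)) + l,
                     log(sigma[nm]), w = 0.5)
        sigma[nm] <- exp(ls)
      }
      if (it > warmup && (it - warmup) %% thin == 0) {
        k <- (it - warmup) %/% thin
        if (k <= n_keep) {
          draws[ch, k, ] <- c(unlist(lapply(theta, function(th) th[sel])),
                              mu, sigma)
        }
      }
    }
  }

  diag <- mcmc_diagnostics(draws)
  ok <- all(diag$rhat < rhat_max, na.rm = TRUE)
  fit <- structure(list(spec = spec, draws = draws, par_names = par_names,
                        participants = names(sessions), hier = hier,
                        part_par = part_par, sessions = sessions,
                        p_fb = p_fb, seed = seed, diagnostics = diag,
                        divergences = 0L, convergence_ok = ok),
                   class = "prefdiff_fit")
  if (!ok) {
    bad <- diag[diag$rhat >= rhat_max, , drop = FALSE]
    warning(sprintf(
      "convergence gate failed: %d parameter(s) with split-Rhat >= %.3f (worst %s = %.3f); inspect $diagnostics",
      nrow(bad), rhat_max, bad$param[which.max(bad$rhat)], max(bad$rhat)),
      call. = FALSE)
  }
  fit
}

#' @export
print.prefdiff_fit <- function(x, ...) {
  cat(sprintf("<prefdiff_fit: %s/%s, %d participants, %d chains x %d draws, %s>\n",
              x$spec$variant, x$spec$learner, length(x$participants),
              dim(x$draws)[1], dim(x$draws)[2],
              if (x$convergence_ok) "converged" else "NOT CONVERGED"))
  print(head(x$diagnostics[order(-x$diagnostics$rhat), ], 5))
  invisible(x)
}

#' Posterior summary of the group-level means
#'
#' @param fit a [fit_hierarchical()] result.
#' @param prob central interval probability.
#' @return data.frame with mean, median and interval bounds per group mean.
#' @export
group_summary <- function(fit, prob = 0.95) {
  alpha <- (1 - prob) / 2
  nms <- paste0("mu_", fit$hier)
  do.call(rbind, lapply(nms, function(nm) {
    x <- as.vector(fit$draws[, , nm])
    data.frame(param = nm, mean = mean(x), median = median(x),
               lower = quantile(x, alpha), upper = quantile(x, 1 - alpha),
               row.names = NULL)
  }))
}

# split-Rhat and a basic autocorrelation ESS for every parameter
mcmc_diagnostics <- function(draws) {
  pn <- dimnames(draws)[[3]]
  out <- data.frame(param = pn, rhat = NA_real_, ess = NA_real_)
  for (j in seq_along(pn)) {
    m <- draws[, , j, drop = FALSE]
    dim(m) <- dim(draws)[1:2]
    out$rhat[j] <- split_rhat(m)
    out$ess[j] <- ess_basic(m)
  }
  out
}

split_rhat <- function(m) {
  half <- floor(ncol(m) / 2)
  if (half < 2) return(NA_real_)
  sub <- rbind(m[, seq_len(half), drop = FALSE],
               m[, (ncol(m) - half + 1):ncol(m), drop = FALSE])
  n <- ncol(sub)
  mns <- rowMeans(sub)
  B <- n * var(mns)
  W <- mean(apply(sub, 1, var))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(m) {
  n <- ncol(m); nc <- nrow(m)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  for (ch in seq_len(nc)) {
    x <- m[ch, ] - mean(m[ch, ])
    v <- mean(x^2)
    if (v == 0) next
    ac <- stats::acf(m[ch, ], lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    # Geyer initial positive sequence on pairs
    s <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + 1 / (1 + 2 * s)
  }
  if (rho_sum == 0) return(NA_real_)
  n * rho_sum   # summed per-chain n/(1+2*sum rho)
}

#' Pointwise log-likelihood matrix from a fit
#'
#' Recomputes the per-trial log-likelihood for a subset of posterior
#' draws; rows are draws, columns are trials (participants concatenated in
#' fitting order).
#'
#' @param fit a [fit_hierarchical()] result.
#' @param n_draws number of draws to use (taken evenly across chains).
#' @return S x N matrix with attribute `trial_participant`.
#' @export
pointwise_loglik <- function(fit, n_draws = 400L) {
  nc <- dim(fit$draws)[1]; nk <- dim(fit$draws)[2]
  per_chain <- max(1L, min(nk, ceiling(n_draws / nc)))
  idx <- unique(round(seq(1, nk, length.out = per_chain)))
  n_trials <- sum(vapply(fit$sessions, function(s) s$n_trials, numeric(1)))
  out <- matrix(NA_real_, nrow = nc * length(idx), ncol = n_trials)
  row <- 0L
  for (ch in seq_len(nc)) for (i in idx) {
    row <- row + 1L
    col <- 0L
    for (p in seq_along(fit$sessions)) {
      ses <- fit$sessions[[p]]
      id <- fit$participants[p]
      get <- function(nm) {
        key <- paste0(nm, "[", id, "]")
        if (key %in% fit$par_names) fit$draws[ch, i, key] else 0
      }
      ll <- .session_loglik_cpp(ses$pair_idx, ses$delta_v, ses$rho,
                                ses$fb_on_a, ses$resp_is_a, ses$rt,
                                get("beta_dv"), get("beta_rho"), get("kappa"),
                                get("omega"), get("a"), get("s_nd"), fit$p_fb)
      out[row, col + seq_len(ses$n_trials)] <- ll
      col <- col + ses$n_trials
    }
  }
  attr(out, "trial_participant") <- rep(fit$participants,
                                        vapply(fit$sessions, function(s)
                                          s$n_trials, numeric(1)))
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Zhang-Stephens (2009) generalized Pareto fit with the usual
# weakly-informative k regularization; returns c(k, sigma)
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xq <- x[max(1, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xq)
  k_of_b <- vapply(b, function(bi) -mean(log1p(-bi * x)), numeric(1))
  l <- n * (log(b / k_of_b) + k_of_b - 1)
  w <- 1 / vapply(seq_len(m), function(i) sum(exp(l - l[i])), numeric(1))
  b_hat <- sum(b * w)
  k_hat <- -mean(log1p(-b_hat * x))
  sigma <- k_hat / b_hat
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)   # shrink toward 0.5
  c(k = k_hat, sigma = sigma)
}

# Pareto-smooth a vector of log importance weights in place
psis_smooth <- function(lw) {
  lw <- lw - max(lw)   # normalization-invariant shift; keeps exp() in range
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw - log_sum_exp(lw), k = Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids] - cutoff) - 1  # on the ratio scale above u
  if (all(exceed <= 0)) return(list(lw = lw - log_sum_exp(lw), k = 0))
  fit <- gpd_fit(exceed * exp(cutoff))
  k <- fit["k"]; sigma <- fit["sigma"]
  p <- (seq_len(M) - 0.5) / M
  q <- if (abs(k) < 1e-8) -sigma * log1p(-p) else sigma * ((1 - p)^(-k) - 1) / k
  smoothed <- log(q + exp(cutoff))
  smoothed <- pmin(smoothed, max(lw))
  lw[tail_ids] <- smoothed
  list(lw = lw - log_sum_exp(lw), k = unname(k))
}

#' PSIS leave-one-out expected log predictive density
#'
#' Pareto-smoothed importance-sampling estimate of the leave-one-out
#' predictive density, pointwise per trial, with its standard error and
#' the Pareto shape diagnostics. A warning is attached when many trials
#' have shape k above 0.7 (unreliable importance weights).
#'
#' @param loglik S x N pointwise log-likelihood matrix (draws x trials).
#' @return object of class `elpd_result`: `elpd`, `se`, `pointwise`,
#'   `pareto_k`, `n_bad_k`.
#' @export
elpd_loo <- function(loglik) {
  if (!is.matrix(loglik) || any(!is.finite(loglik)))
    stop("loglik must be a finite draws x trials matrix")
  N <- ncol(loglik); S <- nrow(loglik)
  pointwise <- numeric(N); ks <- numeric(N)
  for (i in seq_len(N)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)          # log importance ratios: -loglik
    pointwise[i] <- log_sum_exp(ll + sm$lw)
    ks[i] <- sm$k
  }
  n_bad <- sum(ks > 0.7)
  res <- structure(list(elpd = sum(pointwise),
                        se = sd(pointwise) * sqrt(N),
                        pointwise = pointwise, pareto_k = ks,
                        n_bad_k = n_bad, n_trials = N, n_draws = S),
                   class = "elpd_result")
  if (n_bad > 0.1 * N)
    warning(sprintf("%d of %d trials have Pareto k > 0.7; ELPD may be unreliable",
                    n_bad, N), call. = FALSE)
  res
}

#' @export
print.elpd_result <- function(x, ...) {
  cat(sprintf("<elpd_result: elpd = %.1f (SE %.1f), %d trials, %d draws, %d high-k>\n",
              x$elpd, x$se, x$n_trials, x$n_draws, x$n_bad_k))
  invisible(x)
}

#' Compare two models by ELPD
#'
#' Paired difference of the pointwise LOO contributions (trial indexing
#' must match), with the standard error of the difference and a two-tailed
#' paired t-test p value.
#'
#' @param a,b `elpd_result` objects for the same trials.
#' @return list `elpd_diff` (a minus b), `se_diff`, `p_value`.
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "elpd_result"), inherits(b, "elpd_result"))
  if (a$n_trials != b$n_trials)
    stop("models were evaluated on different numbers of trials")
  d <- a$pointwise - b$pointwise
  se <- sd(d) * sqrt(length(d))
  diff <- sum(d)
  p <- if (se == 0) as.numeric(diff != 0) else
    2 * pt(-abs(diff / se), df = length(d) - 1)
  list(elpd_diff = diff, se_diff = se, p_value = p)
}
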