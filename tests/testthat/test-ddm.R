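test_that("drift rate and starting fraction follow their link functions", {
  expect_equal(drift_rate(0.5, 1.53), 0)
  expect_equal(drift_rate(1, 1.53), 1.53)
  expect_equal(drift_rate(0.9, 2), 1.6)
  expect_error(drift_rate(1.2, 1), "p_a")
  expect_equal(start_fraction(1.7, 0), 0.5)
  expect_equal(start_fraction(0, 5), 0.5)
  expect_equal(start_fraction(100, 1), 1)   # saturation
  dv <- seq(-3, 3, 0.5)
  expect_true(all(diff(start_fraction(dv, 0.4)) > 0))
})

test_that("first-passage densities are symmetric, positive where they must be, and conserve mass", {
  # unbiased zero drift: both boundaries identical at every t
  p0 <- ddm_params(d = 0, a = 2, z = 0.5)
  tt <- c(0.1, 0.3, 0.7, 1.5, 3)
  expect_equal(wfpt_log_density(tt, "upper", p0), wfpt_log_density(tt, "lower", p0))
  # label symmetry: upper density under (d, z) equals lower under (-d, 1-z)
  p1 <- ddm_params(d = 0.8, a = 1.6, z = 0.65)
  p1m <- ddm_params(d = -0.8, a = 1.6, z = 0.35)
  expect_equal(wfpt_log_density(tt, "upper", p1), wfpt_log_density(tt, "lower", p1m),
               tolerance = 1e-10)
  # t <= non-decision time is impossible
  pn <- ddm_params(d = 1, a = 2, z = 0.5, s_nd = 0.3)
  expect_identical(wfpt_log_density(c(0.1, 0.3), "upper", pn), c(-Inf, -Inf))
  # mass conservation on a small parameter grid
  for (d in c(-1, 0, 1.5)) for (z in c(0.3, 0.5, 0.7)) {
    p <- ddm_params(d = d, a = 1.8, z = z)
    m <- integrate(function(t) exp(wfpt_log_density(t, "upper", p)), 0, 80,
                   rel.tol = 1e-9)$value +
      integrate(function(t) exp(wfpt_log_density(t, "lower", p)), 0, 80,
                rel.tol = 1e-9)$value
    expect_equal(m, 1, tolerance = 1e-6)
  }
})

test_that("choice probability matches the density mass at each boundary", {
  expect_equal(choice_probability(ddm_params(0, 2, 0.5)), 0.5)
  expect_gt(choice_probability(ddm_params(0, 2, 0.999)), 0.99)
  for (d in c(-0.7, 0.5, 1.53)) for (z in c(0.35, 0.5, 0.6)) {
    p <- ddm_params(d = d, a = 2.10, z = z)
    mass_up <- integrate(function(t) exp(wfpt_log_density(t, "upper", p)), 0, 80,
                         rel.tol = 1e-9)$value
    expect_equal(choice_probability(p), mass_up, tolerance = 1e-6)
  }
})

test_that("the sampler reproduces the analytic choice probabilities and density", {
  set.seed(5)
  for (d in c(-0.5, 0, 1)) for (z in c(0.35, 0.6)) {
    p <- ddm_params(d = d, a = 2, z = z, s_nd = 0.25)
    n <- 2e4
    s <- simulate_trial(n, p)
    expect_true(all(s$rt > p$s_nd))
    pu <- choice_probability(p)
    mc_se <- sqrt(pu * (1 - pu) / n)
    expect_lt(abs(mean(s$upper) - pu), 3 * mc_se + 1e-3)
  }
  # RT distribution agrees with the analytic CDF (upper boundary)
  p <- ddm_params(d = 1, a = 2, z = 0.5)
  set.seed(6)
  s <- simulate_trial(4e4, p)
  up <- sort(s$rt[s$upper])
  qs <- seq(0.1, 0.9, by = 0.2)
  for (q in qs) {
    tq <- quantile(up, q)
    Fq <- integrate(function(t) exp(wfpt_log_density(t, "upper", p)), 0, tq,
                    rel.tol = 1e-8)$value / choice_probability(p)
    expect_lt(abs(Fq - q), 0.015)
  }
})

test_that("Euler-Maruyama oracle agrees with the exact sampler", {
  p <- ddm_params(d = 0.8, a = 1.8, z = 0.55, s_nd = 0)
  em <- simulate_trial_em(2e4, p, dt = 2e-4, seed = 11)
  expect_lt(abs(mean(em$upper) - choice_probability(p)), 0.015)
  set.seed(12)
  s <- simulate_trial(2e4, p)
  # discretization inflates EM response times by O(sqrt(dt)) only
  expect_lt(abs(mean(em$rt) - mean(s$rt)), 0.03)
  expect_lt(abs(median(em$rt) - median(s$rt)), 0.03)
})

test_that("a starting point biased toward the correct boundary slows errors", {
  p <- ddm_params(d = 1, a = 2, z = 0.65)
  cond_mean <- function(boundary) {
    mass <- integrate(function(t) exp(wfpt_log_density(t, boundary, p)), 0, 80,
                      rel.tol = 1e-9)$value
    integrate(function(t) t * exp(wfpt_log_density(t, boundary, p)), 0, 80,
              rel.tol = 1e-9)$value / mass
  }
  expect_gt(cond_mean("lower"), cond_mean("upper"))  # errors slower
  set.seed(13)
  s <- simulate_trial(4e4, p)
  expect_gt(mean(s$rt[!s$upper]), mean(s$rt[s$upper]))
})

test_that("raising the threshold trades speed for accuracy", {
  lo <- ddm_params(d = 0.8, a = 1.2, z = 0.5)
  hi <- ddm_params(d = 0.8, a = 2.6, z = 0.5)
  expect_gt(choice_probability(hi), choice_probability(lo))
  mean_rt <- function(p) {
    integrate(function(t) t * (exp(wfpt_log_density(t, "upper", p)) +
                                 exp(wfpt_log_density(t, "lower", p))),
              0, 120, rel.tol = 1e-8)$value
  }
  expect_gt(mean_rt(hi), mean_rt(lo))
})
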