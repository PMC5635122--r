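test_that("expected value blends regimes linearly", {
  expect_equal(expected_value(0, -1, 2), 2)
  expect_equal(expected_value(1, -1, 2), -1)
  expect_equal(expected_value(0.5, -1, 2), 0.5)
  expect_error(expected_value(1.2, 0, 1), "p_random")
  # linear in p_random for any fixed cell
  p <- seq(0, 1, 0.25)
  e <- expected_value(p, -0.4, 0.9)
  expect_equal(diff(e), rep(diff(e)[1], 4))
})

test_that("the efficiency map interpolates between the per-regime optima", {
  fake_adv <- function(vals) {
    g <- expand.grid(kappa = c(0, 0.5), beta_dv = c(0, 1))
    g$advantage_pp <- vals; g$mc_se <- 0.01
    structure(list(grid = g, curves = NULL, config = NULL),
              class = "strategy_advantage")
  }
  pred <- fake_adv(c(0.1, 0.3, 0.5, 0.9))   # argmax at (0.5, 1)
  rand <- fake_adv(c(0.4, -0.2, -0.1, -0.8)) # argmax at (0, 0)
  em <- efficiency_map(pred, rand, p_random = c(0, 0.5, 1))
  at0 <- em[em$p_random == 0, ]
  expect_equal(c(at0$kappa, at0$beta_dv), c(0.5, 1))
  expect_equal(at0$expected_pp, 0.9)
  at1 <- em[em$p_random == 1, ]
  expect_equal(c(at1$kappa, at1$beta_dv), c(0, 0))
  expect_equal(at1$expected_pp, 0.4)
  # cellwise linearity: E at 0.5 is the midpoint for the best cell found
  e_mid <- expected_value(0.5, rand$grid$advantage_pp, pred$grid$advantage_pp)
  expect_equal(em[em$p_random == 0.5, "expected_pp"], max(e_mid))
  # mismatched axes are rejected
  bad <- fake_adv(1:4); bad$grid$kappa <- bad$grid$kappa + 1
  expect_error(efficiency_map(pred, bad), "share axes")
})

test_that("dyad simulations respect the analytic limits", {
  cfg <- sim_config(reps = 200, seed = 9, presentations = 30L, blocks = 3L)
  dv <- c(-1.5, -0.5, 0.2, 0.8, 2.0)
  # neutral strategy: first-presentation accuracy is exactly 0.5
  acc <- simulate_dyad(dv, kappa = 0, beta_dv = 0, cfg)
  expect_length(acc, 30)
  expect_equal(acc[1], 0.5)
  # learning raises accuracy from first to last presentation
  acc2 <- simulate_dyad(dv, kappa = 0.15, beta_dv = 0.55, cfg)
  expect_gt(acc2[30], acc2[1] + 0.15)
  # saturated prior with fully shared preferences approaches the analytic
  # first-trial ceiling: choice probability at drift omega (p_a -> 1)
  shared <- rep(2, 5)
  acc3 <- simulate_dyad(shared, kappa = 0, beta_dv = 50, cfg)
  ceiling_acc <- choice_probability(ddm_params(cfg$omega, cfg$a, 0.5))
  expect_equal(acc3[1], ceiling_acc, tolerance = 1e-6)
  expect_error(simulate_dyad(c(1, NA), 0, 0, cfg), "every pair")
})

test_that("advantage grids are anchored at zero and favor aligned preferences", {
  pop <- grid_population()
  cfg <- sim_config(kappa_grid = c(0, 0.15), beta_grid = c(0, 0.55),
                    reps = 30, max_dyads = 40, seed = 31)
  adv <- advantage_grid(pop, cfg)
  expect_s3_class(adv, "strategy_advantage")
  origin <- adv$grid[adv$grid$kappa == 0 & adv$grid$beta_dv == 0, ]
  # common random numbers make the origin cell identically zero
  expect_identical(origin$advantage_pp, 0)
  expect_identical(origin$mc_se, 0)
  # aligned population: the dual cell helps
  dual_cell <- adv$grid[adv$grid$kappa == 0.15 & adv$grid$beta_dv == 0.55, ]
  expect_gt(dual_cell$advantage_pp, 0)
  # curves are on the percentage-point scale and match the grid means
  expect_identical(dim(adv$curves), c(4L, 30L))
  expect_equal(rowMeans(adv$curves)[4], dual_cell$advantage_pp,
               tolerance = 0.15)
})

test_that("influenced priors fade with evidence while choice bias persists", {
  pop <- grid_population()
  cfg <- sim_config(kappa_grid = c(0, 0.3), beta_grid = c(0, 1.2),
                    reps = 60, max_dyads = 60, seed = 77)
  adv <- advantage_grid(pop, cfg)
  g <- adv$grid
  prior_row <- which(g$kappa == 0 & g$beta_dv == 1.2)
  choice_row <- which(g$kappa == 0.3 & g$beta_dv == 0)
  late <- 26:30
  # prior-only advantage collapses once learning has plateaued
  expect_gt(mean(adv$curves[prior_row, 1:3]), 1)
  expect_lt(mean(adv$curves[prior_row, late]),
            0.25 * mean(adv$curves[prior_row, 1:3]))
  # choice-only advantage is still positive late in the task
  expect_gt(mean(adv$curves[choice_row, late]), 0)
})

test_that("permuted preferences turn the advantage into a disadvantage", {
  pop <- grid_population()
  rand_pop <- permute_preferences(pop, seed = 13)
  cfg <- sim_config(kappa_grid = c(0, 0.3), beta_grid = c(0, 1.2),
                    reps = 40, max_dyads = 50, seed = 55)
  adv <- advantage_grid(rand_pop, cfg)
  biased <- adv$grid[!(adv$grid$kappa == 0 & adv$grid$beta_dv == 0), ]
  # no biased cell should beat neutral beyond Monte-Carlo noise
  expect_true(all(biased$advantage_pp < 2 * biased$mc_se))
  expect_lt(mean(biased$advantage_pp), 0)
})
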