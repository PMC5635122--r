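test_that("delta_v is the signed bid difference anchored to the correct item", {
  bids <- toy_bids()
  pair <- toy_pair()
  expect_equal(compute_delta_v(bids, pair[1, ], "p1"), 1.50)
  expect_equal(compute_delta_v(bids, pair[1, ], "p4"), 0.00)
  ext <- bid_profiles(c("q", "q"), c("apple", "crisps"), c(0, 3))
  expect_equal(compute_delta_v(ext, pair[1, ], "q"), -3.00)
  # swapping the items flips the sign
  swapped <- item_pairs("pr1", "crisps", "apple")
  expect_equal(compute_delta_v(bids, swapped[1, ], "p1"), -1.50)
  expect_error(compute_delta_v(bids, pair[1, ], "nobody"), "no bid")
  expect_error(
    compute_delta_v(bid_profiles("p9", "apple", 1), pair[1, ], "p9"),
    "crisps")
})

test_that("popularity is the excess share of others preferring the correct item", {
  bids <- toy_bids()
  pair <- toy_pair()
  # others of p4: p1, p2 prefer apple, p3 does not -> 2/3 - 0.5
  expect_equal(compute_popularity(bids, pair[1, ], exclude = "p4"), 2 / 3 - 0.5)
  # tie contributes half a count: others of p1 are p2 (yes), p3 (no), p4 (tie)
  expect_equal(compute_popularity(bids, pair[1, ], exclude = "p1"), 1.5 / 3 - 0.5)
  # antisymmetric under swapping item_a / item_b
  swapped <- item_pairs("pr1", "crisps", "apple")
  expect_equal(compute_popularity(bids, swapped[1, ], exclude = "p4"),
               -compute_popularity(bids, pair[1, ], exclude = "p4"))
  # unanimous population: everyone prefers the correct item -> 0.5 exactly
  unan <- bid_profiles(rep(c("u1", "u2", "u3"), each = 2),
                       rep(c("apple", "crisps"), 3),
                       rep(c(2, 1), 3))
  expect_identical(compute_popularity(unan, pair[1, ], exclude = "u1"), 0.5)
  only <- bid_profiles(c("solo", "solo"), c("apple", "crisps"), c(1, 2))
  expect_error(compute_popularity(only, pair[1, ], exclude = "solo"),
               "empty reference population")
})

test_that("schedules satisfy every pseudorandomization invariant", {
  pairs <- item_pairs(sprintf("p%02d", 1:20),
                      sprintf("i%02d", 1:20), sprintf("j%02d", 1:20))
  for (seed in 1:40) {
    sched <- build_schedule(pairs, seed = seed)
    expect_identical(nrow(sched), 600L)
    expect_identical(as.integer(table(sched$block)), rep(200L, 3))
    expect_silent(validate_schedule(sched))
  }
  # explicit spot checks of the headline constraints on one schedule
  sched <- build_schedule(pairs, seed = 99)
  expect_false(any(sched$pair[-1] == sched$pair[-600]))
  expect_true(all(table(sched$block, sched$pair) == 10))
  expect_true(all(table(sched$block, sched$pair, sched$side_of_a) == 5))
  expect_true(all(tapply(sched$feedback_veridical,
                         list(sched$block, sched$pair), sum) == 8))
  # determinism
  expect_identical(build_schedule(pairs, seed = 7), build_schedule(pairs, seed = 7))
  # bernoulli dialect: marginal rate near 0.8, not exact per block
  sb <- build_schedule(pairs, feedback = "bernoulli", seed = 11)
  expect_gt(mean(sb$feedback_veridical), 0.72)
  expect_lt(mean(sb$feedback_veridical), 0.88)
})

test_that("datasets round-trip through CSV and are validated on read", {
  ds <- smoke_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$bids, ds$bids, ignore_attr = TRUE)
  expect_equal(back$pairs, ds$pairs, ignore_attr = TRUE)
  expect_equal(back$trials, ds$trials, tolerance = 1e-12, ignore_attr = TRUE)

  # out-of-range bid
  bad <- ds; bad$bids$bid_gbp[3] <- 3.50
  d2 <- withr::local_tempdir(); write_dataset(bad, d2)
  expect_error(read_dataset(d2), "outside \\[0, 3\\]")

  # missing RT column
  bad2 <- ds; bad2$trials$rt_s <- NULL
  d3 <- withr::local_tempdir(); write_dataset(bad2, d3)
  expect_error(read_dataset(d3), "missing column")

  # foreign response item
  bad3 <- ds; bad3$trials$response[5] <- "not_an_item"
  d4 <- withr::local_tempdir(); write_dataset(bad3, d4)
  expect_error(read_dataset(d4), "not an item")
})
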