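test_that("configs validate their geometry", {
  expect_error(engagement_config(r_intercept = 6, r_nearmiss = 5))
  expect_error(engagement_config(dz = -1))
  cfg <- engagement_config()
  expect_equal(cfg$r_intercept, 0.2)
  expect_equal(cfg$r_nearmiss, 5)
  expect_equal(cfg$blind_halfangle, pi / 4)
  expect_equal(cfg$head_start, 10)
})

test_that("same seed gives identical outcomes, different seeds differ", {
  cfg <- quick_cfg(dz = 50, dx = 200)
  a <- run_engagements(male, starling, cfg, n = 4, seed = 5)
  b <- run_engagements(male, starling, cfg, n = 4, seed = 5)
  expect_identical(a, b)
  c <- run_engagements(male, starling, cfg, n = 4, seed = 6)
  expect_false(identical(a$t_end, c$t_end))
  # sharding: the batch equals the concatenation of its shards
  d1 <- run_engagements(male, starling, cfg, n = 2, seed = 5, start_index = 0)
  d2 <- run_engagements(male, starling, cfg, n = 2, seed = 5, start_index = 2)
  expect_equal(rbind(d1, d2)$t_end, a$t_end)
})

test_that("outcome categories are exclusive, exhaustive and terminal", {
  oc <- run_engagements(male, morphs[["Common chaffinch"]],
    quick_cfg(dz = 50, dx = 200),
    n = 25, seed = 9
  )
  expect_true(all(oc$category %in% c("intercept", "near_miss", "timeout")))
  expect_true(all(oc$t_end <= 30 + 1e-9))
  # an intercept implies the minimum distance fell below the radius
  expect_true(all(oc$min_distance[oc$category == "intercept"] < 0.2))
  # a near-miss implies the falcon got within the arming radius
  expect_true(all(oc$min_distance[oc$category == "near_miss"] < 5))
})

test_that("head-on capped agents intercept at the closed-form time", {
  # falcon at 40 m/s chases prey fleeing directly away at 20 m/s from
  # 200 m: closing speed 20 m/s -> intercept at ~10 s (the pursuer keeps
  # a modest turning cap so it can align with off-axis headings)
  fal <- capped_agent(speed = 40, n_max = 2, rollacc_max = 1000)
  prey <- capped_agent(speed = 20, n_max = 0, rollacc_max = 0)
  found <- FALSE
  for (idx in 0:99) {
    oc <- run_engagements(fal, prey,
      engagement_config(
        dz = 0, dx = 200, head_start = 0, timeout = 30,
        erratic = erratic_params(c3 = 0),
        ppn = ppn_config(N = 3, delay = 0, sigma_v = 0)
      ),
      n = 1, seed = 3, start_index = idx
    )
    if (oc$category == "intercept") {
      # directly-away flight is the slowest geometry: 10 s is the cap
      expect_lte(oc$t_end, 200 / (40 - 20) + 0.15)
      # runs whose random heading is close to directly away realise it
      if (oc$t_end > 9.7) found <- TRUE
    }
  }
  expect_true(found)
})

test_that("a stationary-limit target directly ahead is run down", {
  fal <- capped_agent(speed = 30, n_max = 2, rollacc_max = 1000)
  prey <- capped_agent(speed = 0.1, n_max = 0, rollacc_max = 0)
  oc <- run_engagements(fal, prey,
    engagement_config(
      dz = 0, dx = 150, head_start = 0, timeout = 20,
      ppn = ppn_config(N = 3, delay = 0, sigma_v = 0),
      erratic = erratic_params(c3 = 0)
    ),
    n = 3, seed = 8
  )
  expect_true(all(oc$category == "intercept"))
  expect_equal(oc$t_end, rep(150 / 30, 3), tolerance = 0.05)
})

test_that("high stoops intercept much faster than low-level attacks", {
  hi <- run_engagements(male, starling,
    engagement_config(dz = 1500, dx = 50, erratic = erratic_params(c3 = 0)),
    n = 8, seed = 11
  )
  lo <- run_engagements(male, starling,
    engagement_config(dz = 50, dx = 200, erratic = erratic_params(c3 = 0)),
    n = 8, seed = 11
  )
  sp_hi <- hi$falcon_speed[hi$category == "intercept"]
  sp_lo <- lo$falcon_speed[lo$category == "intercept"]
  expect_gt(mean(sp_hi), 85) # over 100 m/s dives, some bleed at intercept
  expect_lt(mean(sp_lo), 45) # low attacks arrive near 35 m/s
  prof <- high_speed_stoop_profile(hi)
  expect_equal(prof$mean_intercept_speed, mean(sp_hi))
  expect_equal(prof$n_intercepts, length(sp_hi))
})

test_that("catch success summaries match their definitions", {
  oc <- data.frame(category = c("intercept", "near_miss", "intercept"))
  cs <- catch_success(oc)
  expect_equal(cs$k, 2)
  expect_equal(cs$n, 3)
  expect_equal(cs$estimate, 2 / 3)
})
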