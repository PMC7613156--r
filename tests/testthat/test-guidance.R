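test_that("sensing returns the true line of sight without delay or noise", {
  oh <- matrix(c(0, 0, 0), 1, 3, byrow = TRUE)
  th <- matrix(c(10, 0, 0), 1, 3, byrow = TRUE)
  expect_equal(sense_los(oh, th, dt = 0.005), c(1, 0, 0))
})

test_that("delayed sensing uses the stale geometry until it catches up", {
  # target steps sideways at sample 6; with a 5-sample delay the
  # apparent direction is unchanged until 5 samples later
  k <- 12
  oh <- matrix(0, k, 3)
  th <- cbind(10, c(rep(0, 5), rep(5, k - 5)), 0)
  dirs <- t(sapply(6:k, function(i) {
    sense_los(oh[1:i, , drop = FALSE], th[1:i, , drop = FALSE],
      dt = 1, delay = 5
    )
  }))
  expect_equal(dirs[1, ], c(1, 0, 0)) # still sees the old position
  expect_equal(dirs[5, ], c(1, 0, 0))
  expect_equal(dirs[6, ], c(10, 5, 0) / sqrt(125)) # delay elapsed
  # insufficient history falls back to the earliest sample
  expect_equal(
    sense_los(oh[1:2, ], th[1:2, ], dt = 1, delay = 10),
    c(1, 0, 0)
  )
})

test_that("visual noise is unbiased and of the configured scale", {
  set.seed(42)
  draws <- t(replicate(3000, sense_los(
    matrix(0, 1, 3), matrix(c(20, 0, 0), 1, 3),
    dt = 0.005, sigma_v = 0.01
  )))
  ang <- acos(pmin(draws[, 1], 1))
  expect_lt(abs(mean(draws[, 2])), 5e-4) # mean deviation ~ 0
  expect_lt(abs(mean(draws[, 3])), 5e-4)
  expect_equal(mean(ang), 0.01 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("line-of-sight rate has its defining geometric properties", {
  # constant-bearing geometry: zero rate
  expect_equal(los_rate(c(1, 0, 0), c(1, 0, 0), 0.01), c(0, 0, 0))
  # target circling at omega: rate magnitude omega, perpendicular to LOS
  om <- 0.75
  dt <- 1e-4
  u1 <- c(cos(0), sin(0), 0)
  u2 <- c(cos(om * dt), sin(om * dt), 0)
  r <- los_rate(u1, u2, dt)
  expect_equal(sqrt(sum(r^2)), om, tolerance = 1e-6)
  expect_equal(sum(r * u1), 0, tolerance = 1e-9)
})

test_that("the PPN command is N (omega x v) normal to the velocity", {
  cfg <- ppn_config(N = 3)
  expect_equal(ppn_command(cfg, c(30, 0, 0), c(0, 0, 0)), c(0, 0, 0))
  a <- ppn_command(cfg, c(30, 0, 0), c(0, 0, 0.2))
  expect_equal(sqrt(sum(a^2)), 3 * 30 * 0.2)
  expect_equal(sum(a * c(1, 0, 0)), 0)
  # any component along the velocity is removed
  a2 <- ppn_command(cfg, c(30, 0, 0), c(0.5, 0, 0.2))
  expect_equal(sum(a2 * c(1, 0, 0)), 0)
})

test_that("PPN converges to a collision course against a straight target", {
  # classical property: with no noise or delay the LOS rate shrinks to
  # zero well before intercept
  cfg <- quick_cfg(
    dz = 200, dx = 100,
    ppn = ppn_config(N = 3, delay = 0, sigma_v = 0),
    erratic = erratic_params(c3 = 0)
  )
  oc <- run_engagements(male, starling, cfg, n = 5, seed = 101)
  expect_true(all(oc$category == "intercept"))
  expect_true(all(oc$min_distance < 0.2))
})

test_that("erratic commands alternate sides and respect the cap", {
  p <- erratic_params(c1 = 0.6, c2 = 0.2, c3 = 0.8, c4 = 0.05)
  a_plus <- erratic_command(p, c(20, 0, 0), 30, side = 1)
  a_minus <- erratic_command(p, c(20, 0, 0), 30, side = -1)
  # consecutive lateral commands differ in sign
  expect_lt(sum(a_plus * a_minus), 0)
  expect_equal(sqrt(sum(a_plus^2)), 0.8 * 30)
  expect_equal(sum(a_plus * c(1, 0, 0)), 0, tolerance = 1e-12)
  # weight-supported form never exceeds the available cap
  ag <- erratic_command(p, c(20, 0, 0), 30, side = 1, g = 9.81)
  expect_lte(sqrt(sum(ag^2)), 0.8 * 30)
  expect_equal(sqrt(sum(ag^2)), sqrt((0.8 * 30)^2 - 9.81^2))
  # c3 = 0 commands straight flight
  expect_equal(
    erratic_command(erratic_params(c3 = 0), c(20, 0, 0), 30),
    c(0, 0, 0)
  )
  # switching intervals have the configured minimum and mean
  set.seed(7)
  iv <- erratic_interval(p, 20000)
  expect_gte(min(iv), p$c2)
  expect_equal(mean(iv), p$c1, tolerance = 0.02)
})

test_that("straight-flying prey are almost always caught", {
  for (g in list(c(50, 200), c(1500, 50))) {
    cfg <- engagement_config(
      dz = g[1], dx = g[2],
      erratic = erratic_params(c3 = 0)
    )
    oc <- run_engagements(male, starling, cfg, n = 15, seed = 13)
    expect_gte(mean(oc$category == "intercept"), 0.8)
  }
})

test_that("miss distance shrinks as the pursuer's load-factor cap grows", {
  # capped falcon vs a jinking capped target: non-increasing miss
  # distance in the available load factor (checked on batch medians)
  prey <- capped_agent(speed = 15, n_max = 2.5, rollacc_max = 3000)
  med_miss <- sapply(c(1, 3, 8), function(nmax) {
    fal <- capped_agent(speed = 40, n_max = nmax, rollacc_max = 5000)
    oc <- run_engagements(fal, prey, quick_cfg(dz = 100, dx = 150),
      n = 30, seed = 77
    )
    median(oc$min_distance)
  })
  expect_true(all(diff(med_miss) <= 1e-9))
})
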