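test_that("free fall and straight level flight integrate correctly", {
  # a bird with no commanded turn in glide at terminal-ish state: gravity
  # is always applied (check the vertical velocity change over one step)
  st <- bird_state(pos = c(0, 0, 1000), vel = c(30, 0, 0))
  out <- step_bird(st, c(0, 0, 0), dt = 0.005, male, aero)
  # commanded zero normal accel means lift cancels the perpendicular
  # gravity component: vertical accel ~ 0, not free fall
  expect_lt(abs(out$vel[3]), 0.01)

  # a bird flying straight holds altitude, and because agents always
  # race (maximum forward force), its speed converges onto the top
  # sustained level speed, the stable fixed point of the speed dynamics
  v0 <- max_range_speed(male, aero)
  st <- bird_state(pos = c(0, 0, 0), vel = c(v0, 0, 0))
  out <- step_bird(st, c(0, 0, 0), dt = 0.005, male, aero, n_steps = 12000)
  expect_equal(sqrt(sum(out$vel^2)), flight_speeds(male, aero)$v_top_level,
    tolerance = 0.01)
  expect_lt(abs(out$pos[3]), 5)
})

test_that("gliding never adds mechanical energy", {
  # hold a glide (zero command, speed above top level speed so the bird
  # cannot flap usefully): kinetic + potential energy must not increase
  st <- bird_state(pos = c(0, 0, 500), vel = c(45, 0, -5))
  e0 <- 0.5 * sum(st$vel^2) + aero$g * st$pos[3]
  for (i in 1:10) {
    st <- step_bird(st, c(0, 0, 0), dt = 0.005, male, aero, n_steps = 100)
    e1 <- 0.5 * sum(st$vel^2) + aero$g * st$pos[3]
    expect_lte(e1, e0 + 1e-6)
    e0 <- e1
  }
})

test_that("integrator converges under step halving", {
  run <- function(dt) {
    st <- bird_state(pos = c(0, 0, 1000), vel = c(20, 0, 0))
    # constant lateral command for 10 s
    step_bird(st, c(0, 3, 0), dt = dt, male, aero, n_steps = round(10 / dt))
  }
  a <- run(0.005)
  b <- run(0.0025)
  path <- 20 * 10
  expect_lt(sqrt(sum((a$pos - b$pos)^2)) / path, 0.001)
})

test_that("bang-bang roll control has its closed-form behaviour", {
  # at target with zero rate: no torque
  expect_equal(bang_bang_roll(0.3, 0, 0.3, 100), 0)
  # full torque toward the target at the start of a slew
  expect_equal(bang_bang_roll(0, 0, pi / 2, 100), 100)
  expect_equal(bang_bang_roll(0, 0, -pi / 2, 100), -100)
  # rest-to-rest slew time is 2 sqrt(theta / alpha)
  expect_equal(bang_bang_slew_time(1, 4), 1)
  expect_equal(
    bang_bang_slew_time(0.8, 2) / bang_bang_slew_time(0.8, 4),
    sqrt(2)
  )
  # simulate the double integrator under the rule: reaches the target
  # with no residual rate in ~ the closed-form time
  alpha <- 50
  th <- 1.2
  phi <- 0
  rate <- 0
  dt <- 1e-3
  t <- 0
  while ((abs(phi - th) > 1e-3 || abs(rate) > 0.05) && t < 1) {
    u <- bang_bang_roll(phi, rate, th, alpha, dt)
    phi <- phi + rate * dt + 0.5 * u * dt^2
    rate <- rate + u * dt
    t <- t + dt
  }
  expect_equal(t, 2 * sqrt(th / alpha), tolerance = 0.05)
})

test_that("flap-or-glide selection maximises forward force", {
  # slow level flight with lift = weight: flapping wins
  W <- male$m_b * aero$g
  sel <- select_flap_or_glide(male, 15, W, aero)
  expect_equal(sel$mode, "flap")
  # steep high-speed dive with tiny required lift: glide, high retraction
  sel2 <- select_flap_or_glide(male, 80, 0.05 * W, aero)
  expect_equal(sel2$mode, "glide")
  expect_gte(sel2$retraction, 0.75)
  # among glide retractions the returned one minimises drag
  drags <- sapply(seq(0, 1, by = 0.25), function(z) {
    .cpp_min_drag(unclass(male), 80, 0.05 * W, z, aero)
  })
  expect_equal(
    -sel2$forward_force, min(drags),
    tolerance = 1e-9
  )
})

test_that("commands saturate at the envelope with direction preserved", {
  v <- 30
  Lmax <- max_lift(male, v, 0, "flap", aero)
  ok <- saturate_command(c(0, 2, 0), male, v, aero)
  expect_false(ok$saturated)
  expect_equal(ok$lift, male$m_b * c(0, 2, 0))
  big <- saturate_command(c(0, 2 * Lmax / male$m_b, 0), male, v, aero)
  expect_true(big$saturated)
  expect_equal(sqrt(sum(big$lift^2)), Lmax)
  expect_equal(big$lift / sqrt(sum(big$lift^2)), c(0, 1, 0))
})

test_that("capped agents respect every cap at every step", {
  ag <- capped_agent(speed = 25, n_max = 10, rollacc_max = 2000)
  st <- list(pos = c(0, 0, 0), vel = c(25, 0, 0), psi = 0, psi_rate = 0)
  # commanded 20 g laterally with a 10 g cap -> realised 10 g
  out <- step_capped_agent(ag, st, c(0, 20 * 9.81, 0), dt = 0.005)
  expect_equal(out$lf, 10, tolerance = 1e-9)
  expect_equal(sqrt(sum(out$vel^2)), 25, tolerance = 1e-12)
  # speed renormalised after many steps of hard turning
  for (i in 1:200) {
    st <- step_capped_agent(ag, st, c(0, 200, 0), dt = 0.005)
  }
  expect_equal(sqrt(sum(st$vel^2)), 25, tolerance = 1e-9)
  # gravity is not applied: any vertical motion is the small transient
  # of the force direction rotating from its default (upward) pose
  expect_lt(abs(st$pos[3]), 2)

  # n_max = 0 gives straight-line motion
  ag0 <- capped_agent(speed = 10, n_max = 0, rollacc_max = 0)
  st0 <- list(pos = c(0, 0, 0), vel = c(10, 0, 0), psi = 0, psi_rate = 0)
  out0 <- step_capped_agent(ag0, st0, c(0, 50, 0), dt = 0.005, n_steps = 400)
  expect_equal(out0$pos, c(20, 0, 0), tolerance = 1e-9)
})
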