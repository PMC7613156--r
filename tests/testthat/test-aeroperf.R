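test_that("gliding stall-limited lift matches the closed form", {
  # pure glide, no retraction, in the stall-limited regime (muscle cap
  # lifted): L = 0.5 rho v^2 S_w CL_max exactly
  v <- 8
  a_free <- aero_params(k_musc = 1e9)
  expect_equal(
    max_lift(male, v, 0, "glide", a_free),
    0.5 * aero$rho * v^2 * male$S_w * aero$CL_max,
    tolerance = 1e-12
  )
  expect_equal(max_lift(male, 0, 0, "glide", aero), 0)
  # non-decreasing in airspeed
  L <- max_lift(male, seq(0, 80, by = 1), 0, "flap", aero)
  expect_true(all(diff(L) >= 0))
})

test_that("drag components behave as their closed forms dictate", {
  v <- 20
  d0 <- min_drag_at_lift(male, v, 0, 0, aero)
  q <- 0.5 * aero$rho * v^2
  Sb <- body_frontal_area(male$m_b, aero$k_Sb)
  expect_equal(d0, q * Sb * male$C_db + q * male$S_w * aero$Cd_pro0,
    tolerance = 1e-12
  )
  # the lift-dependent part quadruples when lift doubles
  d1 <- min_drag_at_lift(male, v, 2, 0, aero) - d0
  d2 <- min_drag_at_lift(male, v, 4, 0, aero) - d0
  expect_equal(d2 / d1, 4, tolerance = 1e-9)
  # strictly increasing in lift
  W <- male$m_b * aero$g
  dr <- min_drag_at_lift(male, 25, seq(0, W, length.out = 20), 0, aero)
  expect_true(all(diff(dr) > 0))
  expect_error(min_drag_at_lift(male, 5, 1e4), "exceeds")
})

test_that("low aspect ratio costs more thrust margin during maneuvers", {
  # a low aspect ratio (blue-tit-like, 4.48) loses a larger fraction of
  # its thrust margin than a high one (swift-like, 9.81) at equal speed
  # and load factor; isolated on synthetic twins that differ only in
  # span (the real tit/swift pair also differ in wing loading, which
  # confounds the aspect-ratio effect)
  mk_ar <- function(AR) {
    m <- unclass(starling)
    m$AR <- AR
    m$b <- sqrt(AR * m$S_w)
    m
  }
  lo <- mk_ar(4.48)
  hi <- mk_ar(9.81)
  v <- 14
  margin_frac <- function(m, n) {
    W <- m$m_b * aero$g
    t0 <- .cpp_max_thrust(m, v, W, aero)
    tn <- .cpp_max_thrust(m, v, n * W, aero)
    (t0 - tn) / .cpp_max_thrust(m, v, 0, aero)
  }
  expect_gt(margin_frac(lo, 2.5), margin_frac(hi, 2.5))
})

test_that("level top speed is the root of the level-acceleration curve", {
  sp <- flight_speeds(male, aero)
  env <- level_acceleration_envelope(male, v = seq(5, 40, by = 0.25), aero)
  # a(v) > 0 below the top speed, < 0 above
  expect_true(all(env$accel[env$v > 12 & env$v < sp$v_top_level - 0.3] > 0))
  expect_true(all(env$accel[env$v > sp$v_top_level + 0.3] < 0))
  # net thrust at (v_top, L = W) is zero by definition
  W <- male$m_b * aero$g
  expect_equal(max_thrust(male, sp$v_top_level, W, aero), 0, tolerance = 1e-4)
})

test_that("dive envelope matches its closed form and anchors", {
  env <- dive_acceleration_envelope(male, v = c(0, 50, 104), aero)
  expect_equal(env$accel[1], aero$g)
  sp <- flight_speeds(male, aero)
  expect_equal(
    sp$v_terminal,
    sqrt(2 * male$m_b * aero$g /
      (aero$rho * body_frontal_area(male$m_b, aero$k_Sb) * male$C_db))
  )
  # with the Pennycuick-style frontal-area coefficient the male's
  # terminal speed is ~99.7 m/s (closed form evaluated independently)
  ap <- aero_params(k_Sb = 8.13e-3)
  vt_expected <- sqrt(2 * 0.528 * 9.81 / (1.225 * 8.13e-3 * 0.528^0.68 * 0.16))
  expect_equal(flight_speeds(male, ap)$v_terminal, vt_expected)
  expect_equal(vt_expected, 99.7, tolerance = 0.02)
})

test_that("characteristic speeds are ordered v_range < v_top < v_terminal", {
  for (m in morphs) {
    sp <- flight_speeds(m, aero)
    expect_lt(sp$v_range, sp$v_top_level)
    expect_lt(sp$v_top_level, sp$v_terminal)
  }
})

test_that("maximum-range speed shifts down when body drag doubles", {
  v1 <- max_range_speed(male, aero)
  v2 <- max_range_speed(male, aero_params(k_Sb = 2 * aero$k_Sb))
  expect_lt(v2, v1)
})

test_that("load factor, roll acceleration and turn radius are consistent", {
  v <- seq(5, 110, by = 5)
  n <- max_load_factor(male, v, aero)
  L <- max_lift(male, v, 0, "flap", aero)
  expect_equal(n, L / (male$m_b * aero$g))
  # at the speed where max lift equals weight the load factor is 1
  W <- male$m_b * aero$g
  v1 <- uniroot(function(v) max_lift(male, v, 0, "flap", aero) - W, c(2, 30))$root
  expect_equal(max_load_factor(male, v1, aero), 1, tolerance = 1e-6)
  # r = v^2 m / L pointwise, and r = v^2 / a for the printed mallard row:
  # 21.5 m/s with a 26.3 m radius implies ~17.6 m/s^2 centripetal
  expect_equal(min_turn_radius(male, v, aero), v^2 * male$m_b / L)
  expect_equal(21.5^2 / 26.3, 17.6, tolerance = 0.01)
  expect_error(min_turn_radius(male, 0), "undefined")
  # male > female roll acceleration at every common airspeed
  vv <- seq(10, 100, by = 10)
  expect_true(all(max_roll_acceleration(male, vv, 0, aero) >
    max_roll_acceleration(female, vv, 0, aero)))
  # with the muscle caps lifted, roll acceleration tracks the
  # stall-limited lift exactly (same arm and inertia)
  a_free <- aero_params(k_musc = 1e9, k_roll = 1e9)
  r1 <- .cpp_roll_accel(unclass(male), 4, 0, a_free)
  r2 <- .cpp_roll_accel(unclass(male), 8, 0, a_free)
  L1 <- max_lift(male, 4, 0, "flap", a_free)
  L2 <- max_lift(male, 8, 0, "flap", a_free)
  expect_equal(r2 / r1, L2 / L1, tolerance = 1e-9)
})

test_that("envelope table is internally consistent", {
  pe <- performance_envelope(male, v = seq(2, 110, by = 2), aero)
  env <- pe$envelope
  W <- male$m_b * aero$g
  expect_equal(env$n_max * W, env$L_max)
  expect_equal(env$r_min, env$speeds^2 * male$m_b / env$L_max)
  expect_lt(pe$v_range, pe$v_top_level)
})

test_that("carry-load machinery behaves at its edges", {
  # zero prey mass is carriable whenever level flight is possible at all
  expect_true(.cpp_max_carry(unclass(male), 0.35, aero)$can_carry)
  cl <- max_carry_load(male, aero = aero)
  expect_true(cl$can_carry)
  expect_gt(cl$max_mass, 0.1)
  # heavier carrier carries more
  clf <- max_carry_load(female, aero = aero)
  expect_gt(clf$max_mass, cl$max_mass)
})

test_that("the blade-element quadrature converges to the closed form", {
  # the flap-averaged elementwise dynamic pressure equals
  # 0.5 rho (v^2 + u_tip^2 / 6) S_eff for a sinusoidal stroke on a
  # uniform-chord wing; the discrete sum must converge to it
  a_free <- aero_params(k_musc = 1e9)
  for (v in c(5, 12)) {
    for (z in c(0, 0.5)) {
      expect_equal(
        blade_element_lift(male, v, z, a_free),
        max_lift(male, v, z, "flap", a_free),
        tolerance = 1e-3
      )
    }
  }
  # more elements, closer agreement
  a20 <- aero_params(k_musc = 1e9, n_elements = 20)
  a200 <- aero_params(k_musc = 1e9, n_elements = 200)
  tgt <- max_lift(male, 10, 0, "flap", a20)
  expect_lt(
    abs(blade_element_lift(male, 10, 0, a200) - tgt),
    abs(blade_element_lift(male, 10, 0, aero_params(
      k_musc = 1e9,
      n_elements = 3
    )) - tgt) + 1e-12
  )
})
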