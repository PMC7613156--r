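test_that("the packaged table loads into SI units with printed values intact", {
  expect_length(morphs, 8)
  expect_equal(male$m_b, 0.528)
  expect_equal(male$b, 0.873)
  expect_equal(male$S_w, 0.0897)
  expect_equal(mallard$m_b, 0.995)
  # unit round-trip reproduces the printed numbers bit-for-bit
  back <- morphology_to_table(morphs)
  orig <- morphology_table()
  rownames(back) <- NULL
  expect_equal(back, orig)
})

test_that("aspect ratios are consistent with b^2 / S_w within 5%", {
  for (m in morphs) {
    expect_lt(abs(m$b^2 / m$S_w - m$AR) / m$AR, 0.05)
  }
  # male falcon: computed 8.50 vs printed 8.49
  expect_equal(male$b^2 / male$S_w, 8.50, tolerance = 0.001)
})

test_that("male body mass is about two-thirds of the female's", {
  expect_equal(male$m_b / female$m_b, 528 / 771)
  expect_lt(abs(male$m_b / female$m_b - 2 / 3), 0.04)
})

test_that("invalid rows are rejected with informative errors", {
  tmp <- tempfile(fileext = ".csv")
  tab <- morphology_table()
  tab$m_b[1] <- 0
  write.csv(tab, tmp, row.names = FALSE)
  expect_error(load_morphology_table(tmp), "positive")

  tab <- morphology_table()
  tab$AR[2] <- tab$AR[2] * 1.2 # breaks the 5% consistency check
  write.csv(tab, tmp, row.names = FALSE)
  expect_error(load_morphology_table(tmp), "inconsistent")

  tab <- morphology_table()[, -3] # drop a column
  write.csv(tab, tmp, row.names = FALSE)
  expect_error(load_morphology_table(tmp), "lacks column")

  expect_error(load_morphology_table("/nonexistent/file.csv"), "not found")
})

test_that("allometric body quantities follow their power laws", {
  # ratios are independent of the coefficient
  expect_equal(
    body_frontal_area(0.771) / body_frontal_area(0.528),
    (0.771 / 0.528)^0.68
  )
  expect_equal(body_frontal_area(0.771) / body_frontal_area(0.528),
    1.29,
    tolerance = 0.005
  )
  expect_equal(body_width(0.771) / body_width(0.528), (0.771 / 0.528)^0.35)
  expect_equal(body_width(0.771) / body_width(0.528), 1.14, tolerance = 0.005)
  expect_equal(body_width(2) / body_width(1), 2^0.35)
  expect_error(body_frontal_area(0), "positive")
  expect_error(body_width(-1), "positive")
  # monotone in mass
  ms <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(body_frontal_area(ms)) > 0))
  expect_true(all(diff(body_width(ms)) > 0))
})

test_that("weight and derived body quantities are exact and ordered", {
  d <- derived_body(male, aero)
  expect_equal(d$W, male$m_b * aero$g)
  expect_gt(derived_body(female, aero)$I_roll, d$I_roll)
})

test_that("roll inertia decreases with retraction and scales with span", {
  I0 <- roll_inertia(male, 0)
  I1 <- roll_inertia(male, 1)
  expect_lt(I1, I0)
  zs <- seq(0, 1, by = 0.1)
  Is <- vapply(zs, function(z) roll_inertia(male, z), numeric(1))
  expect_true(all(diff(Is) < 0))
  # full retraction with rho_ret = 0.6 shrinks the wing term by (1-0.6)^2
  wing0 <- male$m_w / 12 * male$b^2
  body <- I0 - wing0
  expect_equal(I1 - body, wing0 * 0.16, tolerance = 1e-10)
  # doubling the span quadruples the wing term
  m2 <- male
  m2$b <- male$b * 2
  m2$S_w <- male$S_w * 4 # keep AR consistent
  expect_equal(roll_inertia(m2, 0) - body, 4 * wing0, tolerance = 1e-10)
  expect_error(roll_inertia(male, 1.5), "retraction")
})
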