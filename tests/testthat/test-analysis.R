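test_that("Wilson intervals match their closed form", {
  ci <- catch_success_ci(0, 100)
  expect_equal(ci$estimate, 0)
  expect_equal(ci$lower, 0)
  # closed form: upper = (z^2/n) / (1 + z^2/n) at k = 0
  z <- qnorm(0.975)
  expect_equal(ci$upper, (z^2 / 100) / (1 + z^2 / 100), tolerance = 1e-9)
  expect_equal(ci$upper, 0.037, tolerance = 0.02)
  # symmetry under p -> 1 - p
  ci1 <- catch_success_ci(100, 100)
  expect_equal(ci1$lower, 1 - ci$upper)
  expect_equal(ci1$upper, 1)
  # large-n half-width approaches the Wald form 1.96 sqrt(p(1-p)/n)
  ci2 <- catch_success_ci(5e4, 1e5)
  expect_equal((ci2$upper - ci2$lower) / 2, 0.0031, tolerance = 0.01)
  expect_error(catch_success_ci(1, 0))
})

test_that("the penalized additive surface recovers a known logistic model", {
  set.seed(33)
  n <- 4000
  d <- data.frame(
    speed = runif(n, 0, 100),
    load_factor = runif(n, 0, 15),
    roll_accel = runif(n, 0, 8000)
  )
  truth <- function(d) {
    plogis(1.5 - 0.45 * d$load_factor + 0.015 * d$speed -
      0.00005 * d$roll_accel + 0.3 * sin(d$speed / 20))
  }
  p <- truth(d)
  d$caught <- runif(n) < p
  fit <- fit_success_surface(d)
  pe <- fit$predict_prob(d)
  expect_true(all(pe > 0 & pe < 1))
  expect_lt(mean(abs(pe - p)), 0.05)
  # partial effect of load factor is monotone decreasing for this truth
  eff <- partial_effect(fit, d, "load_factor")
  expect_lt(cor(eff$value, eff$prob, method = "spearman"), -0.95)
})

test_that("degenerate designs are handled explicitly", {
  set.seed(4)
  d <- data.frame(
    speed = runif(500, 0, 50), load_factor = 5,
    roll_accel = runif(500, 0, 1000),
    caught = runif(500) < 0.5
  )
  expect_warning(fit_success_surface(d), "constant covariate")
  expect_error(fit_success_surface(d[1:50, ]), "too few")
})

test_that("a flat outcome yields a flat surface", {
  set.seed(5)
  d <- data.frame(
    speed = runif(1500, 0, 50),
    load_factor = runif(1500, 0, 10),
    roll_accel = runif(1500, 0, 1000),
    caught = runif(1500) < 0.4 # independent of the covariates
  )
  fit <- fit_success_surface(d)
  pe <- fit$predict_prob(d)
  expect_lt(diff(range(pe)), 0.25)
  expect_equal(mean(pe), 0.4, tolerance = 0.1)
})

test_that("in the heavy-penalty limit the surface approaches a GLM", {
  set.seed(6)
  n <- 2000
  d <- data.frame(
    speed = runif(n, 0, 50), load_factor = runif(n, 0, 10),
    roll_accel = runif(n, 0, 1000)
  )
  p <- plogis(1 - 0.3 * d$load_factor + 0.02 * d$speed)
  d$caught <- runif(n) < p
  dd <- data.frame(S = d$speed, L = d$load_factor, R = d$roll_accel,
    C = as.integer(d$caught))
  heavy <- mgcv::gam(C ~ s(S, k = 10) + s(L, k = 10) + s(R, k = 10),
    family = stats::binomial(), data = dd,
    sp = c(1e8, 1e8, 1e8)
  )
  glmfit <- stats::glm(C ~ S + L + R, family = stats::binomial(), data = dd)
  expect_equal(as.numeric(predict(heavy, type = "response")),
    as.numeric(predict(glmfit, type = "response")),
    tolerance = 0.01
  )
})

test_that("mean sustained load factor is the time average of lift/weight", {
  expect_equal(mean_sustained_load_factor(rep(1, 100)), 1)
  expect_equal(mean_sustained_load_factor(c(1, 2, 3)), 2)
  oc <- data.frame(prey_mean_lf = c(1.5, 2.5))
  expect_equal(mean_sustained_load_factor(oc), 2)
  expect_error(mean_sustained_load_factor(numeric(0)), "telemetry")
})

test_that("intercept summaries average the right rows and drop empties", {
  oc <- data.frame(
    category = c("intercept", "near_miss", "intercept"),
    falcon_speed = c(100, 50, 104), falcon_lf = c(10, 2, 12),
    falcon_rollacc = c(5000, 100, 5200), falcon_radius = c(90, 10, 100),
    prey_speed = c(20, 10, 22), prey_lf = c(1.5, 1, 1.7),
    prey_rollacc = c(400, 0, 500), prey_radius = c(25, 1, 27)
  )
  s <- intercept_summary(oc)
  expect_equal(s$n_intercepts, 2)
  expect_equal(s$speed, 102)
  expect_equal(s$load_factor, 11)
  sp <- intercept_summary(oc, who = "prey")
  expect_equal(sp$speed, 21)
  empty <- data.frame(
    category = "near_miss", falcon_speed = 1, falcon_lf = 1,
    falcon_rollacc = 1, falcon_radius = 1, prey_speed = 1, prey_lf = 1,
    prey_rollacc = 1, prey_radius = 1
  )
  expect_message(out <- intercept_summary(list(a = oc, b = empty)), "omitted")
  expect_equal(nrow(out), 1)
})

test_that("Howland's inequality in acceleration form", {
  h <- howland_ratio(10, 5)
  expect_equal(h$a, 2)
  expect_true(h$escape_possible)
  # strict inequality at the boundary
  expect_false(howland_ratio(5, 5)$escape_possible)
  # equal speeds and radii: v = r, a = 1, escape impossible
  h2 <- howland_ratio(
    prey_a = 20^2 / 50, pred_a = 20^2 / 50,
    prey_v = 20, pred_v = 20, prey_r = 50, pred_r = 50
  )
  expect_equal(h2$v, 1)
  expect_equal(h2$r, 1)
  expect_equal(h2$a, 1)
  expect_false(h2$escape_possible)
  expect_error(howland_ratio(1, 0))
})
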