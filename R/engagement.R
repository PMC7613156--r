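#' Engagement configuration
#'
#' Geometry, termination rules and guidance settings for a single attack.
#' The prey starts at the origin with a random heading and flies alone for
#' `head_start` seconds; the falcon then starts `dx` metres away
#' horizontally and `dz` metres above, heading at the prey, and both birds
#' begin at their maximum-range speeds (full-physics agents) or their
#' fixed speeds (capped agents).
#'
#' @param dz falcon start altitude above the prey, m.
#' @param dx horizontal start distance, m.
#' @param dt integration step, s.
#' @param r_intercept intercept distance, m (< 0.2 m ends the attack as a
#'   catch).
#' @param r_nearmiss near-miss arming distance, m: once the falcon has
#'   been within this range, finding the prey inside its blind zone ends
#'   the attack as a miss.
#' @param blind_halfangle half-angle of the blind zone, rad: a spherical
#'   wedge pointing opposite to the falcon's heading (default pi/4, i.e. a
#'   90 degree wedge).
#' @param head_start prey head start, s.
#' @param timeout maximum chase duration after attack initiation, s
#'   (counted as a miss).
#' @param ppn falcon guidance, a [ppn_config()].
#' @param erratic prey guidance, an [erratic_params()].
#' @return list of class `stoopsim_engagement_config`.
#' @export
engagement_config <- function(dz = 1500, dx = 50, dt = 0.005,
                              r_intercept = 0.2, r_nearmiss = 5,
                              blind_halfangle = pi / 4, head_start = 10,
                              timeout = 60, ppn = ppn_config(),
                              erratic = erratic_params()) {
  stopifnot(r_intercept < r_nearmiss, dz >= 0, dx >= 0, dt > 0, timeout > 0)
  structure(
    list(
      dz = dz, dx = dx, dt = dt, r_intercept = r_intercept,
      r_nearmiss = r_nearmiss, blind_halfangle = blind_halfangle,
      head_start = head_start, timeout = timeout, ppn = ppn,
      erratic = erratic
    ),
    class = "stoopsim_engagement_config"
  )
}

agent_spec <- function(agent, aero) {
  if (inherits(agent, "stoopsim_morphology")) {
    list(type = "full", morph = unclass(agent))
  } else if (inherits(agent, "stoopsim_capped") ||
    (is.list(agent) && identical(agent$type, "capped"))) {
    unclass(agent)
  } else {
    stop("agent must be a stoopsim_morphology or a capped_agent()")
  }
}

cfg_for_cpp <- function(cfg, falcon, prey, aero) {
  v0f <- if (inherits(falcon, "stoopsim_morphology")) {
    max_range_speed(falcon, aero)
  } else {
    falcon$speed
  }
  v0p <- if (inherits(prey, "stoopsim_morphology")) {
    max_range_speed(prey, aero)
  } else {
    prey$speed
  }
  list(
    dz = cfg$dz, dx = cfg$dx, dt = cfg$dt, r_intercept = cfg$r_intercept,
    r_nearmiss = cfg$r_nearmiss, blind_halfangle = cfg$blind_halfangle,
    head_start = cfg$head_start, timeout = cfg$timeout,
    v0_falcon = v0f, v0_prey = v0p,
    N = cfg$ppn$N, delay = cfg$ppn$delay, sigma_v = cfg$ppn$sigma_v,
    guidance_dt = cfg$ppn$guidance_dt %||% 0.01,
    c1 = cfg$erratic$c1, c2 = cfg$erratic$c2, c3 = cfg$erratic$c3,
    c4 = cfg$erratic$c4
  )
}

#' Run a batch of engagements
#'
#' Simulates `n` independent attacks of a falcon (full-physics morphology
#' or capped agent) on a prey (ditto).  Each engagement `i` draws its
#' random stream deterministically from `(seed, start_index + i)`, so
#' batches can be sharded and reproduced exactly.
#'
#' Per engagement the falcon senses the prey with delay and visual noise,
#' steers by pure proportional navigation, saturates against its flight
#' envelope, and selects flapping or gliding; the prey jinks erratically
#' under its open-loop random guidance.  The attack ends at the first of:
#' intercept (distance below `r_intercept`), near-miss (having come within
#' `r_nearmiss`, the prey falls into the falcon's blind zone), or timeout.
#'
#' @param falcon,prey a `stoopsim_morphology` or a [capped_agent()].
#' @param cfg an [engagement_config()].
#' @param n number of engagements.
#' @param seed master seed (integer).
#' @param start_index first engagement index (for sharding).
#' @param aero model constants.
#' @return data.frame with one row per engagement: `category`
#'   (`"intercept"`, `"near_miss"`, `"timeout"`), `t_end`, `min_distance`,
#'   falcon and prey speed / load factor / roll acceleration / turn radius
#'   at the final instant, `prey_mean_lf` (the prey's mean sustained load
#'   factor over the chase), `prey_mean_speed` and the engagement `seed`
#'   index.
#' @export
#' @examples
#' \donttest{
#' m <- get_morphology("Peregrine falcon (male)")
#' p <- get_morphology("Common starling")
#' run_engagements(m, p, engagement_config(dz = 50, dx = 200), n = 2, seed = 1)
#' }
run_engagements <- function(falcon, prey, cfg = engagement_config(), n = 1,
                            seed = 1, start_index = 0,
                            aero = aero_params()) {
  fs <- agent_spec(falcon, aero)
  ps <- agent_spec(prey, aero)
  cc <- cfg_for_cpp(cfg, falcon, prey, aero)
  m <- .cpp_run_engagements(fs, ps, aero, cc, as.integer(n), seed,
    start_index)
  df <- as.data.frame(m)
  df$category <- c("intercept", "near_miss", "timeout", "aborted")[df$category + 1]
  df$seed_index <- start_index + seq_len(n) - 1
  df
}

#' Run a single engagement
#'
#' @inheritParams run_engagements
#' @param engagement_index index of the engagement stream to use.
#' @return one-row data.frame, see [run_engagements()].
#' @export
run_engagement <- function(falcon, prey, cfg = engagement_config(),
                           seed = 1, engagement_index = 0,
                           aero = aero_params()) {
  run_engagements(falcon, prey, cfg, n = 1, seed = seed,
    start_index = engagement_index, aero = aero)
}

#' Catch success over a batch of outcomes
#'
#' @param outcomes data.frame from [run_engagements()].
#' @return list with `k` intercepts, `n` trials, the success proportion
#'   and its Wilson 95% interval.
#' @export
catch_success <- function(outcomes) {
  k <- sum(outcomes$category == "intercept")
  n <- nrow(outcomes)
  c(list(k = k, n = n), catch_success_ci(k, n))
}

#' Summary of high-altitude stoop intercept speeds
#'
#' @param outcomes data.frame of outcomes from high-altitude (`dz` 1500 m)
#'   engagements.
#' @return list with the number of intercepts and the mean and quartiles
#'   of the falcon's speed at the moment of intercept.
#' @export
high_speed_stoop_profile <- function(outcomes) {
  if (!nrow(outcomes)) stop("no outcomes supplied")
  sp <- outcomes$falcon_speed[outcomes$category == "intercept"]
  list(
    n_intercepts = length(sp),
    mean_intercept_speed = mean(sp),
    quartiles = stats::quantile(sp, c(0.25, 0.5, 0.75), names = FALSE)
  )
}
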