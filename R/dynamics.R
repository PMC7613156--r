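#' Flight state of one bird
#'
#' @param pos position, 3-vector (m, z-up; gravity acts along -z).
#' @param vel velocity, 3-vector (m/s); must be non-zero.
#' @param roll bank angle about the velocity axis, rad, wrapped to
#'   (-pi, pi].
#' @param roll_rate roll rate, rad/s.
#' @param retraction wing retraction fraction in \[0, 1\].
#' @param mode `"flap"` or `"glide"`.
#' @param t time, s.
#' @return A `stoopsim_state` list.
#' @export
bird_state <- function(pos, vel, roll = 0, roll_rate = 0, retraction = 0,
                       mode = c("flap", "glide"), t = 0) {
  mode <- match.arg(mode)
  stopifnot(length(pos) == 3, length(vel) == 3)
  if (sqrt(sum(vel^2)) <= 0) stop("velocity must be non-zero")
  s <- list(
    t = t, pos = as.numeric(pos), vel = as.numeric(vel),
    roll = ((roll + pi) %% (2 * pi)) - pi, roll_rate = roll_rate,
    retraction = retraction, mode = mode
  )
  class(s) <- "stoopsim_state"
  s
}

#' Advance a full-physics bird under a commanded normal acceleration
#'
#' One (or several) fixed-step RK4 updates of position and velocity under
#' gravity and aerodynamic forces.  The guidance command is translated into
#' a required lift vector (gravity compensation included); the bird rolls
#' toward the required lift direction under bang-bang control, saturates
#' lift at the flight-envelope limit, and selects flapping or gliding (with
#' the drag-minimising wing retraction) to maximise its forward
#' acceleration.
#'
#' @param state a `stoopsim_state`.
#' @param acmd commanded acceleration normal to the velocity, 3-vector
#'   (m/s^2) in world coordinates.
#' @param dt time step, s.
#' @param morph a `stoopsim_morphology`.
#' @param aero model constants.
#' @param n_steps number of consecutive steps with the command held.
#' @return the updated `stoopsim_state`; attributes `lf` (realised load
#'   factor), `rollacc` (available roll acceleration) and `radius`
#'   (realised turn radius) carry per-step telemetry.
#' @export
step_bird <- function(state, acmd, dt, morph, aero = aero_params(),
                      n_steps = 1) {
  stopifnot(dt > 0, n_steps >= 1)
  out <- .cpp_step_full(unclass(morph), aero, unclass(state), as.numeric(acmd),
    dt, as.integer(n_steps))
  s <- bird_state(out$pos, out$vel, out$roll, out$roll_rate, out$retraction,
    out$mode, t = state$t + dt * n_steps)
  attr(s, "lf") <- out$lf
  attr(s, "rollacc") <- out$rollacc
  attr(s, "radius") <- out$radius
  s
}

#' Bang-bang roll command
#'
#' Minimum-time double-integrator control toward a target roll angle:
#' full positive or negative torque with a switch so the roll stops at the
#' target with zero residual rate; zero command at the target.
#'
#' @param roll,roll_rate current roll angle (rad) and rate (rad/s).
#' @param target_roll target roll angle, rad.
#' @param rollacc_max available roll acceleration magnitude, rad/s^2.
#' @param dt step used to resolve the switch, s.
#' @return commanded roll acceleration in `{-rollacc_max, 0, +rollacc_max}`.
#' @export
#' @examples
#' bang_bang_roll(0, 0, 0) # at target: 0
#' bang_bang_roll(0, 0, pi / 2, 100) # start of a slew: +100
bang_bang_roll <- function(roll, roll_rate, target_roll,
                           rollacc_max = 1, dt = 0.005) {
  stopifnot(rollacc_max >= 0)
  if (rollacc_max == 0) return(0)
  err <- ((target_roll - roll + pi) %% (2 * pi)) - pi
  if (abs(err) < 0.5 * rollacc_max * dt^2 && abs(roll_rate) < rollacc_max * dt) {
    return(0)
  }
  s <- if (err >= 0) 1 else -1
  e <- s * err
  r <- s * roll_rate
  u <- if (r < 0) 1 else if (r^2 / (2 * rollacc_max) >= e) -1 else 1
  s * u * rollacc_max
}

#' Minimum rest-to-rest bang-bang slew time
#'
#' Closed form `2 sqrt(theta / alpha)` for a slew through angle `theta` at
#' roll acceleration `alpha`.
#'
#' @param theta slew angle, rad.
#' @param alpha roll acceleration, rad/s^2.
#' @return time, s.
#' @export
bang_bang_slew_time <- function(theta, alpha) {
  stopifnot(theta >= 0, alpha > 0)
  2 * sqrt(theta / alpha)
}

#' Flap-or-glide selection
#'
#' Compares the best achievable forward force when flapping (at zero
#' retraction) against gliding over a retraction grid, at the required
#' lift; ties are broken toward gliding, and among glide retractions the
#' one minimising total drag at the required lift is returned.
#'
#' @param morph a `stoopsim_morphology`.
#' @param v airspeed, m/s.
#' @param required_lift lift demand, N.
#' @param aero model constants.
#' @param retraction_grid candidate glide retractions.
#' @return list with `mode` (`"flap"` or `"glide"`), `retraction` and
#'   `forward_force` (N, negative when gliding).
#' @export
select_flap_or_glide <- function(morph, v, required_lift,
                                 aero = aero_params(),
                                 retraction_grid = seq(0, 1, by = 0.25)) {
  stopifnot(v > 0, required_lift >= 0)
  Lmax_f <- max_lift(morph, v, 0, "flap", aero)
  flap_ok <- required_lift <= Lmax_f + 1e-9
  fwd_flap <- if (flap_ok) {
    .cpp_max_thrust(unclass(morph), v, min(required_lift, Lmax_f), aero)
  } else {
    -Inf
  }
  best <- list(fwd = -Inf, zeta = 0)
  for (z in retraction_grid) {
    Lmax_g <- max_lift(morph, v, z, "glide", aero)
    if (required_lift > Lmax_g + 1e-9) next
    fwd <- -.cpp_min_drag(unclass(morph), v, required_lift, z, aero)
    if (fwd > best$fwd + 1e-12) best <- list(fwd = fwd, zeta = z)
  }
  if (!flap_ok && !is.finite(best$fwd)) {
    stop("required lift infeasible in every mode (saturation)")
  }
  if (best$fwd >= fwd_flap) {
    list(mode = "glide", retraction = best$zeta, forward_force = best$fwd)
  } else {
    list(mode = "flap", retraction = 0, forward_force = fwd_flap)
  }
}

#' Saturate a commanded normal acceleration against the flight envelope
#'
#' If the command is within the available envelope it is applied
#' unchanged; otherwise the bird exerts the maximum lift it can in the
#' commanded direction and the corresponding minimum drag.
#'
#' @param commanded_accel commanded acceleration normal to the velocity,
#'   3-vector, m/s^2 (interpreted as the required specific lift force).
#' @param morph a `stoopsim_morphology`.
#' @param v airspeed, m/s.
#' @param aero model constants.
#' @return list with `lift` (applied lift vector, N), `saturated` flag
#'   and `drag` (minimum drag at the applied lift, N).
#' @export
saturate_command <- function(commanded_accel, morph, v,
                             aero = aero_params()) {
  L_req <- morph$m_b * as.numeric(commanded_accel)
  Lr <- sqrt(sum(L_req^2))
  Lmax <- max_lift(morph, v, 0, "flap", aero)
  if (Lr <= Lmax) {
    list(lift = L_req, saturated = FALSE,
      drag = .cpp_min_drag(unclass(morph), v, Lr, 0, aero))
  } else {
    dir <- L_req / Lr
    list(lift = Lmax * dir, saturated = TRUE,
      drag = .cpp_min_drag(unclass(morph), v, Lmax, 0, aero))
  }
}

#' Constant-speed capped agent
#'
#' A purely kinematic performance probe: constant airspeed, a fixed cap on
#' load factor, and a fixed cap on the roll (force-reorientation)
#' acceleration; gravity is not applied.
#'
#' @param speed constant airspeed, m/s (> 0).
#' @param n_max maximum load factor (>= 0).
#' @param rollacc_max maximum reorientation acceleration, rad/s^2 (>= 0).
#' @return A `stoopsim_capped` list (with `type = "capped"` for the
#'   engagement runner).
#' @export
capped_agent <- function(speed, n_max, rollacc_max) {
  stopifnot(speed > 0, n_max >= 0, rollacc_max >= 0)
  a <- list(type = "capped", speed = speed, n_max = n_max,
    rollacc_max = rollacc_max)
  class(a) <- "stoopsim_capped"
  a
}

#' Advance a capped agent one or more steps
#'
#' The commanded normal acceleration is clipped to `n_max * g`; the force
#' direction reorients under the same bang-bang rule as a rolling bird,
#' limited by `rollacc_max`; speed is renormalised every step and gravity
#' is ignored.
#'
#' @param agent a `stoopsim_capped`.
#' @param state list with `pos`, `vel`, `psi` (force-direction angle) and
#'   `psi_rate`.
#' @param acmd commanded normal acceleration, 3-vector, m/s^2.
#' @param dt time step, s.
#' @param n_steps number of steps with the command held.
#' @return updated state list (plus realised `lf`).
#' @export
step_capped_agent <- function(agent, state, acmd, dt, n_steps = 1) {
  stopifnot(dt > 0)
  .cpp_step_capped(unclass(agent), state, as.numeric(acmd), dt,
    as.integer(n_steps))
}
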