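#' Maximum lift at a given airspeed
#'
#' Wingbeat-averaged maximum lift normal to the velocity vector, the
#' smaller of the stall-limited blade-element lift (with flapping adding
#' elementwise velocity in flap mode) and the muscle/mechanical force cap.
#'
#' @param morph a `stoopsim_morphology`.
#' @param v airspeed, m/s (vectorised).
#' @param retraction wing retraction fraction in \[0, 1\].
#' @param mode `"flap"` or `"glide"`.
#' @param aero model constants, see [aero_params()].
#' @return lift, N; non-decreasing in `v` at fixed retraction.
#' @export
#' @examples
#' m <- get_morphology("Peregrine falcon (male)")
#' max_lift(m, 20, mode = "glide")
max_lift <- function(morph, v, retraction = 0, mode = c("flap", "glide"),
                     aero = aero_params()) {
  mode <- match.arg(mode)
  stopifnot(all(v >= 0), retraction >= 0, retraction <= 1)
  .cpp_max_lift(unclass(morph), as.numeric(v), retraction, mode == "flap", aero)
}

#' Minimum drag at a given lift
#'
#' Body parasite drag plus wing profile drag plus lift-induced drag
#' (expressed through the effective span); strictly increasing in `L`.
#'
#' @inheritParams max_lift
#' @param L lift, N (recycled against `v`).
#' @return drag, N.
#' @export
min_drag_at_lift <- function(morph, v, L, retraction = 0,
                             aero = aero_params()) {
  stopifnot(all(v >= 0), all(L >= 0))
  n <- max(length(v), length(L))
  v <- rep_len(as.numeric(v), n)
  L <- rep_len(as.numeric(L), n)
  Lmax <- max_lift(morph, v, retraction, "flap", aero)
  if (any(L > Lmax + 1e-9)) {
    stop("requested lift exceeds the maximum available at this airspeed")
  }
  .cpp_min_drag(unclass(morph), v, L, retraction, aero)
}

#' Maximum net forward force while flapping at a given lift
#'
#' Wingbeat-averaged flapping thrust net of the minimum drag at that lift;
#' may be negative at high airspeed, where drag exceeds the available
#' flapping thrust.
#'
#' @inheritParams min_drag_at_lift
#' @return net forward force, N.
#' @export
max_thrust <- function(morph, v, L, aero = aero_params()) {
  stopifnot(all(v >= 0), all(L >= 0))
  n <- max(length(v), length(L))
  v <- rep_len(as.numeric(v), n)
  L <- rep_len(as.numeric(L), n)
  Lmax <- max_lift(morph, v, 0, "flap", aero)
  if (any(L > Lmax + 1e-9)) {
    stop("requested lift exceeds the maximum available at this airspeed")
  }
  .cpp_max_thrust(unclass(morph), v, L, aero)
}

#' Maximum level acceleration versus airspeed
#'
#' `a(v) = max_thrust(v, L = W) / m_b`, assuming lift balances weight; the
#' root of `a(v) = 0` is the top sustained level speed.
#'
#' @inheritParams max_lift
#' @return data.frame with columns `v` and `accel` (m/s^2).
#' @export
level_acceleration_envelope <- function(morph, v = seq(1, 60, by = 0.5),
                                        aero = aero_params()) {
  data.frame(v = v, accel = .cpp_level_accel(unclass(morph), as.numeric(v), aero))
}

#' Maximum vertical acceleration in a dive versus airspeed
#'
#' Vertical dive with fully retracted wings, wing drag neglected:
#' `a(v) = g - 0.5 rho v^2 S_b C_db / m_b`; the root is the terminal
#' speed.
#'
#' @inheritParams max_lift
#' @return data.frame with columns `v` and `accel` (m/s^2).
#' @export
dive_acceleration_envelope <- function(morph, v = seq(0, 130, by = 1),
                                       aero = aero_params()) {
  data.frame(v = v, accel = .cpp_dive_accel(unclass(morph), as.numeric(v), aero))
}

#' Characteristic flight speeds
#'
#' @inheritParams max_lift
#' @return list with `v_top_level` (top sustained level speed, m/s),
#'   `v_terminal` (terminal dive speed, m/s) and `v_range`
#'   (maximum-range speed minimising mechanical cost of transport, m/s).
#'   Always `v_range < v_top_level < v_terminal`.
#' @export
#' @examples
#' flight_speeds(get_morphology("Peregrine falcon (male)"))
flight_speeds <- function(morph, aero = aero_params()) {
  .cpp_speeds(unclass(morph), aero)
}

#' Maximum-range speed
#'
#' The airspeed minimising mechanical cost of transport `P/v` (equal to
#' drag at lift = weight), used as the initial speed of both predator and
#' prey in every engagement.
#'
#' @inheritParams max_lift
#' @return speed, m/s.
#' @export
max_range_speed <- function(morph, aero = aero_params()) {
  flight_speeds(morph, aero)$v_range
}

#' Maximum load factor versus airspeed
#'
#' Lift divided by weight, `max_lift(v) / (m_b g)`.
#'
#' @inheritParams max_lift
#' @return dimensionless load factor (vectorised over `v`).
#' @export
max_load_factor <- function(morph, v, aero = aero_params()) {
  max_lift(morph, v, 0, "flap", aero) / (morph$m_b * aero$g)
}

#' Maximum roll acceleration versus airspeed
#'
#' The sustainable lift asymmetry between the wings acting at a quarter of
#' the effective span, divided by the roll moment of inertia.
#'
#' @inheritParams max_lift
#' @return roll acceleration, rad s^-2.
#' @export
max_roll_acceleration <- function(morph, v, retraction = 0,
                                  aero = aero_params()) {
  stopifnot(retraction >= 0, retraction <= 1)
  .cpp_roll_accel(unclass(morph), as.numeric(v), retraction, aero)
}

#' Minimum turn radius versus airspeed
#'
#' Gravity-free turn radius with all lift devoted to turning:
#' `v^2 * m_b / max_lift(v)`.
#'
#' @inheritParams max_lift
#' @return radius, m.
#' @export
min_turn_radius <- function(morph, v, aero = aero_params()) {
  if (any(v <= 0)) stop("turn radius undefined at zero airspeed")
  v^2 * morph$m_b / max_lift(morph, v, 0, "flap", aero)
}

#' Full performance envelope over a speed grid
#'
#' @inheritParams max_lift
#' @param v airspeed grid, m/s.
#' @return list with the envelope data.frame (`speeds`, `L_max`, `T_max`
#'   at lift = weight, `D_min` at lift = weight, `n_max`, `rollacc_max`,
#'   `r_min`) and the scalar speeds `v_top_level`, `v_terminal`,
#'   `v_range`.
#' @export
performance_envelope <- function(morph, v = seq(1, 120, by = 0.5),
                                 aero = aero_params()) {
  W <- morph$m_b * aero$g
  Lmax <- max_lift(morph, v, 0, "flap", aero)
  Lw <- pmin(W, Lmax)
  sp <- flight_speeds(morph, aero)
  env <- data.frame(
    speeds = v,
    L_max = Lmax,
    T_max = .cpp_max_thrust(unclass(morph), as.numeric(v), Lw, aero),
    D_min = .cpp_min_drag(unclass(morph), as.numeric(v), Lw, 0, aero),
    n_max = Lmax / W,
    rollacc_max = max_roll_acceleration(morph, v, 0, aero),
    r_min = v^2 * morph$m_b / Lmax
  )
  c(list(envelope = env), sp)
}

#' Maximum carriable prey mass
#'
#' The carried prey adds its weight to the required lift and the parasite
#' drag of its body (frontal area from the `m^0.68` allometry) to the drag
#' budget; the carrier must still find an airspeed at which level flight
#' can be sustained.  The maximum mass is found by bisection.
#'
#' @param morph carrier (falcon) morphology.
#' @param prey_C_db body drag coefficient of the carried prey.
#' @param aero model constants.
#' @return list with `can_carry` (any positive mass at all) and
#'   `max_mass` (kg).
#' @export
#' @examples
#' \donttest{
#' max_carry_load(get_morphology("Peregrine falcon (male)"))$max_mass # ~0.5
#' }
max_carry_load <- function(morph, prey_C_db = 0.35, aero = aero_params()) {
  stopifnot(prey_C_db > 0)
  .cpp_max_carry(unclass(morph), prey_C_db, aero)
}

#' Numerical blade-element check of the flap-averaged lift
#'
#' Discretises each wing into `n_elements` spanwise strips and the
#' wingbeat into phase steps, sums the stall-limited elementwise lift
#' over a sinusoidal stroke, and averages over the beat.  The package's
#' closed-form stall lift is the analytic limit of this quadrature (the
#' flap augmentation factor 1/6 on the squared tip speed); this function
#' exists to verify that correspondence and for envelope experiments
#' with other stroke shapes.
#'
#' @inheritParams max_lift
#' @param n_phase wingbeat phase steps.
#' @return stall-limited lift, N (muscle cap not applied).
#' @export
blade_element_lift <- function(morph, v, retraction = 0,
                               aero = aero_params(), n_phase = 64) {
  ne <- aero$n_elements
  be <- morph$b * (1 - aero$rho_ret * retraction)
  Se <- morph$S_w * (1 - aero$rho_ret * retraction)
  chord <- Se / be
  # element midpoints along one wing, 0..b_eff/2
  r <- (seq_len(ne) - 0.5) / ne * (be / 2)
  dr <- (be / 2) / ne
  om0 <- 2 * pi * morph$f * aero$stroke_amplitude
  phases <- (seq_len(n_phase) - 0.5) / n_phase * 2 * pi
  q_sum <- 0
  for (ph in phases) {
    u <- om0 * cos(ph) * r
    q_sum <- q_sum + sum(0.5 * aero$rho * (v^2 + u^2) * chord * dr)
  }
  2 * aero$CL_max * q_sum / n_phase # both wings
}
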