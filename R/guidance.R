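#' Pure proportional navigation configuration
#'
#' @param N navigation constant (dimensionless gain; > 0).  Around 3 is
#'   optimal against most prey; lower values favour the least maneuverable
#'   targets.
#' @param delay visual response delay, s.
#' @param sigma_v visual angular error SD, rad.
#' @param guidance_dt interval between guidance updates, s; the
#'   line-of-sight rate is estimated by finite differences of consecutive
#'   (delayed, noisy) sightings at this cadence and the command is held
#'   in between.
#' @return list of class `stoopsim_ppn`.
#' @export
ppn_config <- function(N = 3, delay = 0.03, sigma_v = 2e-4,
                       guidance_dt = 0.01) {
  stopifnot(N > 0, delay >= 0, sigma_v >= 0, guidance_dt > 0)
  structure(list(N = N, delay = delay, sigma_v = sigma_v,
    guidance_dt = guidance_dt), class = "stoopsim_ppn")
}

#' Erratic (jinking) evasion parameters
#'
#' Piecewise-constant lateral acceleration commands with alternating sign:
#' each command is held for `c2 + Exponential(mean = c1 - c2)` seconds, has
#' the prey banks `c3` of its currently available maximum lift to
#' alternating sides while keeping the vertical lift component equal to
#' its weight (a coordinated, level jink), so the commanded lateral
#' acceleration is `sqrt((c3 a_max)^2 - g^2)`; the jink plane is tilted
#' out of the horizontal by the bias angle `c4`.
#'
#' @param c1 mean switching interval, s (>= c2).
#' @param c2 minimum switching interval, s (>= 0).
#' @param c3 commanded fraction of the available maximum acceleration
#'   in \[0, 1\].
#' @param c4 directional bias angle out of the horizontal, rad.
#' @return list of class `stoopsim_erratic`.
#' @export
erratic_params <- function(c1 = 0.6, c2 = 0.15, c3 = 0.9, c4 = 0.05) {
  stopifnot(c1 >= c2, c2 >= 0, c3 >= 0, c3 <= 1)
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4),
    class = "stoopsim_erratic")
}

unit3 <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-300) stop("zero vector has no direction")
  x / n
}

#' Apparent line of sight with delay and visual noise
#'
#' Returns the line-of-sight direction as it was `delay` seconds ago
#' (earliest sample if the history is shorter), rotated by a Gaussian
#' angular error about a uniformly random axis perpendicular to the line
#' of sight.
#'
#' @param observer_history matrix (k x 3) of observer positions, one row
#'   per step, oldest first.
#' @param target_history matrix (k x 3) of target positions.
#' @param dt step between history rows, s.
#' @param delay response delay, s.
#' @param sigma_v visual angular error SD, rad.
#' @return unit 3-vector: apparent line-of-sight direction at the current
#'   time.
#' @export
sense_los <- function(observer_history, target_history, dt, delay = 0,
                      sigma_v = 0) {
  k <- nrow(observer_history)
  i <- max(1, k - round(delay / dt))
  los <- unit3(target_history[i, ] - observer_history[i, ])
  if (sigma_v > 0) {
    ang <- rnorm(1, 0, sigma_v)
    az <- runif(1, 0, 2 * pi)
    ez <- c(0, 0, 1)
    u0 <- ez - sum(ez * los) * los
    if (sqrt(sum(u0^2)) < 1e-9) u0 <- c(1, 0, 0) - los[1] * los
    u0 <- unit3(u0)
    w0 <- c(
      los[2] * u0[3] - los[3] * u0[2],
      los[3] * u0[1] - los[1] * u0[3],
      los[1] * u0[2] - los[2] * u0[1]
    )
    axis <- cos(az) * u0 + sin(az) * w0
    los <- unit3(cos(ang) * los + sin(ang) * c(
      axis[2] * los[3] - axis[3] * los[2],
      axis[3] * los[1] - axis[1] * los[3],
      axis[1] * los[2] - axis[2] * los[1]
    ))
  }
  los
}

#' Line-of-sight rotation rate
#'
#' Finite-difference rotation rate of the unit line-of-sight vector; the
#' result is perpendicular to the line of sight.
#'
#' @param los_prev,los_cur consecutive apparent line-of-sight unit
#'   vectors.
#' @param dt time between the samples, s.
#' @return angular rate 3-vector, rad/s.
#' @export
los_rate <- function(los_prev, los_cur, dt) {
  stopifnot(dt > 0)
  u <- unit3(los_prev)
  w <- unit3(los_cur)
  cross <- c(
    u[2] * w[3] - u[3] * w[2],
    u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1]
  )
  cross / dt
}

#' Pure proportional navigation acceleration command
#'
#' `a = N (omega x v)`, with any component along the velocity removed:
#' the commanded angular rate of change of the pursuer's velocity is
#' proportional to the angular rate of the line of sight.
#'
#' @param cfg a [ppn_config()].
#' @param vel pursuer velocity, 3-vector, m/s.
#' @param los_rate line-of-sight angular rate, 3-vector, rad/s.
#' @return commanded acceleration normal to the velocity, m/s^2.
#' @export
#' @examples
#' a <- ppn_command(ppn_config(N = 3), c(30, 0, 0), c(0, 0, 0.2))
#' sqrt(sum(a^2)) # 18
ppn_command <- function(cfg, vel, los_rate) {
  v <- sqrt(sum(vel^2))
  stopifnot(v > 0)
  om <- los_rate
  a <- cfg$N * c(
    om[2] * vel[3] - om[3] * vel[2],
    om[3] * vel[1] - om[1] * vel[3],
    om[1] * vel[2] - om[2] * vel[1]
  )
  ev <- vel / v
  a - sum(a * ev) * ev
}

#' One draw of the erratic evasion command
#'
#' Left/right alternating lateral acceleration, magnitude `c3` times the
#' available maximum, tilted out of the horizontal by `c4`; the command
#' direction is projected back onto the plane normal to the velocity.
#'
#' @param params an [erratic_params()].
#' @param vel prey velocity, 3-vector, m/s.
#' @param available_max_accel available normal acceleration, m/s^2.
#' @param side +1 or -1: the current jink side.
#' @param g gravitational acceleration to support (0 for capped agents,
#'   which ignore gravity).
#' @return commanded acceleration normal to the velocity, m/s^2.
#' @export
erratic_command <- function(params, vel, available_max_accel, side = 1,
                            g = 0) {
  stopifnot(available_max_accel >= 0, side %in% c(-1, 1))
  ev <- unit3(vel)
  ez <- c(0, 0, 1)
  h <- c(
    ez[2] * ev[3] - ez[3] * ev[2],
    ez[3] * ev[1] - ez[1] * ev[3],
    ez[1] * ev[2] - ez[2] * ev[1]
  )
  nh <- sqrt(sum(h^2))
  hs <- if (nh > 1e-9) h / nh else unit3(c(1, 0, 0) - ev[1] * ev)
  dir <- cos(params$c4) * (side * hs) + sin(params$c4) * ez
  dir <- dir - sum(dir * ev) * ev
  mag <- params$c3 * available_max_accel
  if (g > 0) mag <- sqrt(max(mag^2 - g^2, 0))
  mag * unit3(dir)
}

#' Draw the duration of one erratic command
#'
#' @param params an [erratic_params()].
#' @param n number of draws.
#' @return durations, s: `c2 + Exponential(mean = c1 - c2)`.
#' @export
erratic_interval <- function(params, n = 1) {
  params$c2 + stats::rexp(n, rate = 1 / max(params$c1 - params$c2, 1e-6))
}

#' Evolved guidance defaults
#'
#' Per-species erratic-evasion parameters and falcon navigation constants
#' obtained by running the genetic algorithm shipped in this package
#' (evasion fitness: mean sustained centripetal acceleration of the prey
#' flying alone; pursuit fitness: catch success against the evolved prey),
#' then frozen as defaults.  `optimize_guidance()` re-derives them.
#'
#' @param species prey species label.
#' @return list with `erratic` (an [erratic_params()]) and `N` (the
#'   falcon's navigation constant against that species).
#' @export
#' @examples
#' default_guidance("Mallard")$N
default_guidance <- function(species) {
  tab <- .evolved_guidance
  if (!species %in% names(tab)) {
    stop("no evolved guidance defaults for species '", species, "'")
  }
  tab[[species]]
}

# Filled in by the development-time GA runs (see optimize_guidance());
# medians of repeated runs from different initialisations; the falcon's N
# is evolved against the evolved prey (catch success fitness).
.evolved_guidance <- list(
  "Eurasian blue tit" = list(erratic = list(c1 = 0.844, c2 = 0.139, c3 = 1.0, c4 = 0.0124), N = 6.95),
  "Common chaffinch" = list(erratic = list(c1 = 0.948, c2 = 0.148, c3 = 1.0, c4 = 0.0088), N = 6.67),
  "Common swift" = list(erratic = list(c1 = 0.645, c2 = 0.200, c3 = 1.0, c4 = 0.0288), N = 5.77),
  "Common starling" = list(erratic = list(c1 = 0.863, c2 = 0.165, c3 = 1.0, c4 = 0.0162), N = 6.33),
  "Rock dove" = list(erratic = list(c1 = 1.065, c2 = 0.265, c3 = 1.0, c4 = 0.0113), N = 6.84),
  "Mallard" = list(erratic = list(c1 = 0.939, c2 = 0.139, c3 = 1.0, c4 = 0.0256), N = 4.56)
)
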