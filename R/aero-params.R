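#' Aerodynamic and mechanical model constants
#'
#' Global constants of the quasi-steady, wingbeat-averaged blade-element
#' performance model.  Most entries are physical constants or conventional
#' aerodynamic coefficients; the entries marked *calibrated* were fitted
#' once, jointly, on the two peregrine falcon rows of the morphology table
#' so that the model reproduces the falcons' printed flight anchors (top
#' sustained level speeds 28.1 / 29.2 m/s, terminal dive speeds
#' 104 / 111 m/s, and maximum carry loads 0.50 / 0.76 kg), and were then
#' frozen for every prey species.  See `calibrate_aero()` for the protocol.
#'
#' @param ... named overrides for individual constants.
#'
#' @return A named list of model constants:
#' \describe{
#'   \item{rho}{air density, kg m^-3 (1.225).}
#'   \item{g}{gravitational acceleration, m s^-2 (9.81).}
#'   \item{CL_max}{maximum (stall-limited) lift coefficient.}
#'   \item{Cd_pro0}{zero-lift profile drag coefficient of the wing.}
#'   \item{k_ind}{induced drag factor.}
#'   \item{stroke_amplitude}{wingbeat amplitude, rad.}
#'   \item{c_q}{flap dynamic-pressure augmentation factor applied to the
#'     squared peak flap tip speed (1/6 for a sinusoidal stroke of a
#'     uniform-chord wing).}
#'   \item{Cd_pro2}{*calibrated* lift-dependence of the wing profile drag,
#'     `Cd_pro = Cd_pro0 + Cd_pro2 * CL^2` (the drag side of the
#'     parabolic blade-element polar; this is what makes maneuvering
#'     slow a bird down).}
#'   \item{k_G}{*calibrated* gross flapping-thrust coefficient; the
#'     wingbeat-averaged propulsive force is
#'     `k_G * (f b)^a_u * (S_w m_w)^a_G * f^a_fG`.}
#'   \item{a_u}{flap-tip-speed exponent of the thrust factor (2: thrust
#'     follows the flap-speed dynamic pressure).}
#'   \item{a_G}{*calibrated* wing size-mass exponent of the thrust
#'     factor.}
#'   \item{a_fG}{*calibrated* additional wingbeat-frequency exponent of
#'     the thrust factor.}
#'   \item{k_musc}{*calibrated* muscle normal-force coefficient; the
#'     wingbeat-averaged normal force the flight muscles can hold is
#'     `k_musc * m_w^a_mw * v`.}
#'   \item{a_mw}{wing(-muscle) mass exponent of the muscle factor.}
#'   \item{tau_frac}{maximum lift-asymmetry fraction sustaining roll
#'     torque.}
#'   \item{k_roll}{*calibrated* muscle lift-asymmetry coefficient of the
#'     roll channel: the asymmetric lift available for rolling is
#'     `min(max_lift, k_roll * m_w^a_rm * v)`.}
#'   \item{a_rm}{wing-mass exponent of the roll-asymmetry cap.}
#'   \item{k_Sb}{*calibrated* body frontal area coefficient,
#'     S_b = k_Sb * m_b^0.68 (anchored to the male falcon's terminal
#'     speed).}
#'   \item{k_wb}{body width coefficient, w_b = k_wb * m_b^0.35.}
#'   \item{rho_ret}{fractional span/area reduction at full wing
#'     retraction.}
#'   \item{n_elements}{blade elements per wing used by the numerical
#'     quadrature [blade_element_lift()]; the default envelope closures
#'     use its analytic limit.}
#' }
#' @export
#' @examples
#' p <- aero_params()
#' p$rho
#' aero_params(CL_max = 1.8)$CL_max
aero_params <- function(...) {
  p <- list(
    rho = 1.225,
    g = 9.81,
    CL_max = 1.6,
    Cd_pro0 = 0.02,
    k_ind = 1.1,
    stroke_amplitude = 1.05,
    c_q = 1 / 6,
    Cd_pro2 = 0.047443,
    k_G = 0.635725,
    a_u = 2.07178,
    a_G = 0.36482,
    a_fG = -0.10256,
    k_musc = 6.215705916,
    a_mw = 0.7,
    tau_frac = 0.9,
    k_roll = 17.92174096,
    a_rm = 1.08,
    k_Sb = 0.007544302753,
    k_wb = 0.07,
    rho_ret = 0.6,
    n_elements = 20
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown aero parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p
}
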