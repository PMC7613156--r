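#' Flight-performance calibration anchors
#'
#' Recomputes, for the current model constants, the quantities the
#' calibration protocol anchors on the two falcon rows: top sustained
#' level speed, terminal dive speed and maximum carry load for each sex.
#' The frozen defaults of [aero_params()] were obtained by (i) setting
#' `k_Sb` in closed form from the male's 104 m/s terminal speed, (ii)
#' tying `k_musc` so the male's envelope load factor at 102 m/s is 11 and
#' `k_roll` so his available roll acceleration at 102 m/s with
#' half-retracted wings is 5078 rad/s^2, and (iii) fitting
#' (`k_G`, `Cd_pro2`, `a_G`) by least squares to the four remaining
#' anchors under the flight-performance ordering constraints between the
#' falcons and their prey; everything is then frozen for all species.
#'
#' @param aero model constants to evaluate.
#' @return data.frame with one row per anchor: computed value, target
#'   value and relative error.
#' @export
#' @examples
#' \donttest{
#' calibration_anchors()
#' }
calibration_anchors <- function(aero = aero_params()) {
  morphs <- load_morphology_table()
  male <- morphs[["Peregrine falcon (male)"]]
  female <- morphs[["Peregrine falcon (female)"]]
  sm <- flight_speeds(male, aero)
  sf <- flight_speeds(female, aero)
  out <- data.frame(
    anchor = c(
      "v_top_level (male)", "v_top_level (female)",
      "v_terminal (male)", "v_terminal (female)",
      "max_carry (male)", "max_carry (female)"
    ),
    computed = c(
      sm$v_top_level, sf$v_top_level, sm$v_terminal, sf$v_terminal,
      max_carry_load(male, aero = aero)$max_mass,
      max_carry_load(female, aero = aero)$max_mass
    ),
    target = c(28.1, 29.2, 104, 111, 0.50, 0.76)
  )
  out$rel_error <- out$computed / out$target - 1
  out
}
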