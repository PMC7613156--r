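#' Morphological parameters of falcons and prey species
#'
#' The packaged morphology table: wingbeat frequency `f` (Hz), wingspan `b`
#' (cm), body mass `m_b` (g), wing mass `m_w` (g, both wings), wing area
#' `S_w` (dm^2), aspect ratio `AR` and body drag coefficient `C_db` for both
#' sexes of peregrine falcon and six of their prey species, spanning two
#' orders of magnitude in body mass.
#'
#' @return A data.frame in the table's original units (cm, g, dm^2).
#' @seealso [load_morphology_table()] for the SI-normalised form.
#' @export
#' @examples
#' morphology_table()
morphology_table <- function() {
  data.frame(
    species = c(
      "Peregrine falcon (male)", "Peregrine falcon (female)",
      "Eurasian blue tit", "Common chaffinch", "Common swift",
      "Common starling", "Rock dove", "Mallard"
    ),
    f = c(5.1, 4.7, 14.0, 15.5, 8.3, 10.5, 6.7, 6.2),
    b = c(87.3, 98.4, 20.0, 25.0, 39.2, 39.0, 80.0, 86.2),
    m_b = c(528, 771, 9.5, 19.9, 42, 70, 293, 995),
    m_w = c(32, 49, 0.48, 1.1, 2.1, 3.7, 22.5, 70),
    S_w = c(8.97, 11.83, 0.89, 0.87, 1.57, 2.41, 7.75, 9.27),
    AR = c(8.49, 8.18, 4.48, 7.13, 9.81, 6.30, 8.25, 8.01),
    C_db = c(0.16, 0.16, 0.43, 0.43, 0.35, 0.41, 0.35, 0.35),
    stringsAsFactors = FALSE
  )
}

#' Names of the six prey species in the packaged morphology table
#' @return Character vector of prey species labels.
#' @export
prey_species <- function() {
  c(
    "Eurasian blue tit", "Common chaffinch", "Common swift",
    "Common starling", "Rock dove", "Mallard"
  )
}

validate_morphology <- function(m) {
  num <- c("f", "b", "m_b", "m_w", "S_w", "AR", "C_db")
  for (fld in num) {
    v <- m[[fld]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf(
        "morphology '%s': field '%s' must be a single positive number",
        m$species, fld
      ), call. = FALSE)
    }
  }
  ar <- m$b^2 / m$S_w
  if (abs(ar - m$AR) / m$AR >= 0.05) {
    stop(sprintf(
      "morphology '%s': aspect ratio %.3f inconsistent with b^2/S_w = %.3f",
      m$species, m$AR, ar
    ), call. = FALSE)
  }
  if (m$m_w >= m$m_b) {
    stop(sprintf("morphology '%s': wing mass must be below body mass", m$species),
      call. = FALSE
    )
  }
  invisible(m)
}

new_morphology <- function(species, f, b, m_b, m_w, S_w, AR, C_db) {
  m <- list(
    species = species, f = f, b = b, m_b = m_b, m_w = m_w,
    S_w = S_w, AR = AR, C_db = C_db
  )
  class(m) <- "stoopsim_morphology"
  validate_morphology(m)
}

#' Load and normalise a morphology table
#'
#' Reads a delimited morphology table with the columns of
#' [morphology_table()] in its original units (wingspan cm, masses g, wing
#' area dm^2) and converts to SI (m, kg, m^2).  Each row is validated:
#' all quantities strictly positive, wing mass below body mass, and the
#' printed aspect ratio within 5% of `b^2/S_w`.
#'
#' @param path path to a CSV file; if `NULL`, the packaged table is used.
#' @return A list of `stoopsim_morphology` objects (row order preserved),
#'   each with fields `species`, `f` (Hz), `b` (m), `m_b` (kg), `m_w` (kg,
#'   both wings), `S_w` (m^2), `AR`, `C_db`.
#' @export
#' @examples
#' morphs <- load_morphology_table()
#' morphs[["Peregrine falcon (male)"]]$m_b # 0.528 kg
load_morphology_table <- function(path = NULL) {
  tab <- if (is.null(path)) {
    morphology_table()
  } else {
    if (!file.exists(path)) stop("morphology file not found: ", path)
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  need <- c("species", "f", "b", "m_b", "m_w", "S_w", "AR", "C_db")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("morphology table lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    new_morphology(
      species = tab$species[i],
      f = tab$f[i],
      b = tab$b[i] / 100, # cm -> m
      m_b = tab$m_b[i] / 1000, # g -> kg
      m_w = tab$m_w[i] / 1000,
      S_w = tab$S_w[i] / 100, # dm^2 -> m^2
      AR = tab$AR[i],
      C_db = tab$C_db[i]
    )
  })
  names(out) <- tab$species
  out
}

#' Fetch one species' morphology in SI units
#'
#' @param species species label as in [morphology_table()] (partial
#'   matching via `grepl` is not attempted; the label must match exactly).
#' @param path optional CSV to load instead of the packaged table.
#' @return A `stoopsim_morphology` object.
#' @export
#' @examples
#' get_morphology("Mallard")$m_b # 0.995 kg
get_morphology <- function(species, path = NULL) {
  morphs <- load_morphology_table(path)
  if (!species %in% names(morphs)) {
    stop(
      "unknown species '", species, "'; available: ",
      paste(names(morphs), collapse = ", ")
    )
  }
  morphs[[species]]
}

#' @export
format.stoopsim_morphology <- function(x, ...) {
  sprintf(
    "<morphology: %s | f=%.1f Hz b=%.3f m m_b=%.4f kg S_w=%.4f m^2 AR=%.2f C_db=%.2f>",
    x$species, x$f, x$b, x$m_b, x$S_w, x$AR, x$C_db
  )
}

#' @export
print.stoopsim_morphology <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.data.frame.stoopsim_morphology <- function(x, ...) {
  data.frame(
    species = x$species, f = x$f, b = x$b, m_b = x$m_b, m_w = x$m_w,
    S_w = x$S_w, AR = x$AR, C_db = x$C_db, stringsAsFactors = FALSE
  )
}

#' Re-emit a list of morphologies in the original table units
#'
#' Inverse of [load_morphology_table()]; used for unit round-trip checks
#' and provenance echoes.
#'
#' @param morphs list of `stoopsim_morphology`.
#' @return data.frame in cm / g / dm^2 units.
#' @export
morphology_to_table <- function(morphs) {
  do.call(rbind, lapply(morphs, function(m) {
    data.frame(
      species = m$species, f = m$f, b = m$b * 100, m_b = m$m_b * 1000,
      m_w = m$m_w * 1000, S_w = m$S_w * 100, AR = m$AR, C_db = m$C_db,
      stringsAsFactors = FALSE
    )
  }))
}

#' Allometric body frontal area
#'
#' Parasite drag on the body scales with body frontal area, which scales
#' with body mass as `S_b = k_Sb * m_b^0.68`.  The default coefficient is
#' calibrated so the male peregrine's terminal dive speed is 104 m/s; a
#' Pennycuick-style alternative is `8.13e-3 * m_b^0.666`.
#'
#' @param m_b body mass, kg (vectorised).
#' @param k_Sb coefficient, m^2 kg^-0.68.
#' @return frontal area, m^2.
#' @export
#' @examples
#' body_frontal_area(0.771) / body_frontal_area(0.528) # ~1.29
body_frontal_area <- function(m_b, k_Sb = aero_params()$k_Sb) {
  if (any(!is.finite(m_b)) || any(m_b <= 0)) stop("body mass must be positive")
  k_Sb * m_b^0.68
}

#' Allometric body width
#'
#' Body width scales with body mass as `w_b = k_wb * m_b^0.35`.
#'
#' @param m_b body mass, kg (vectorised).
#' @param k_wb coefficient, m kg^-0.35.
#' @return body width, m.
#' @export
body_width <- function(m_b, k_wb = aero_params()$k_wb) {
  if (any(!is.finite(m_b)) || any(m_b <= 0)) stop("body mass must be positive")
  k_wb * m_b^0.35
}

#' Roll moment of inertia
#'
#' Uniform-rod model for the wing pair plus a cylindrical body term:
#' `I = (m_w/12) b_eff^2 + (m_b/8) w_b^2`, with the effective span
#' shrinking linearly under wing retraction,
#' `b_eff = b (1 - rho_ret * retraction)`.
#'
#' @param morph a `stoopsim_morphology`.
#' @param retraction wing retraction fraction in \[0, 1\].
#' @param aero model constants, see [aero_params()].
#' @return inertia, kg m^2; strictly decreasing in `retraction`.
#' @export
#' @examples
#' m <- get_morphology("Peregrine falcon (male)")
#' roll_inertia(m, 0) > roll_inertia(m, 1)
roll_inertia <- function(morph, retraction = 0, aero = aero_params()) {
  if (!is.finite(retraction) || retraction < 0 || retraction > 1) {
    stop("retraction must be in [0, 1]")
  }
  .cpp_roll_inertia(unclass(morph), retraction, aero)
}

#' Weight and allometrically derived body quantities
#'
#' @param morph a `stoopsim_morphology`.
#' @param aero model constants.
#' @return list with `W` (weight, N), `S_b` (frontal area, m^2), `w_b`
#'   (body width, m) and `I_roll` (roll inertia at zero retraction,
#'   kg m^2).
#' @export
derived_body <- function(morph, aero = aero_params()) {
  list(
    W = morph$m_b * aero$g,
    S_b = body_frontal_area(morph$m_b, aero$k_Sb),
    w_b = body_width(morph$m_b, aero$k_wb),
    I_roll = roll_inertia(morph, 0, aero)
  )
}
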