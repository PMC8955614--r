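#' Mono-energetic beam specification
#'
#' A beam is described by its ion symbol, charge `Z`, kinetic energy in
#' MeV per nucleon and unrestricted LET in water in keV/um.  The six
#' high-energy reference beams used throughout the package (H 1000 MeV to
#' Fe 1000 MeV/n, LET 0.22 to 149.2 keV/um) are available from
#' [reference_beams()].
#'
#' @param ion ion symbol, e.g. `"H"`, `"Fe"`.
#' @param Z atomic number (positive integer).
#' @param energy kinetic energy in MeV per nucleon.
#' @param LET linear energy transfer in keV/um; must be positive.
#' @return An object of class `beam_spec`.
#' @examples
#' b <- beam_spec("H", 1, 1000, 0.22)
#' fluence_for_dose(b$LET, 1)
#' @export
beam_spec <- function(ion, Z, energy, LET) {
  stopifnot(is.character(ion), length(ion) == 1L)
  Z <- as.integer(Z)
  if (is.na(Z) || Z < 1L) stop("Z must be a positive integer")
  if (!is.finite(energy) || energy <= 0) stop("energy must be positive")
  if (!is.finite(LET) || LET <= 0) stop("LET must be positive")
  structure(list(ion = ion, Z = Z, energy = energy, LET = LET),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> %s (Z=%d), %g MeV/n, LET %g keV/um\n",
              x$ion, x$Z, x$energy, x$LET))
  invisible(x)
}

#' Packaged reference beams
#'
#' The six mono-energetic ion beams the package ships with: H 1000 MeV,
#' He 250 MeV/n, C 290 MeV/n, O 325 MeV/n, Si 300 MeV/n and Fe 1000 MeV/n,
#' with LET from 0.22 to 149.2 keV/um and ranges in water from SRIM-style
#' tabulations.
#'
#' @return A data.frame with columns `ion`, `Z`, `energy_MeV_n`,
#'   `LET_keV_um`, `range_cm`.
#' @examples
#' reference_beams()
#' @export
reference_beams <- function() {
  read.csv(system.file("extdata", "beams.csv", package = "microca"),
           stringsAsFactors = FALSE)
}

#' @rdname reference_beams
#' @param ion ion symbol of one packaged beam.
#' @return `reference_beam()` returns a single [beam_spec()].
#' @export
reference_beam <- function(ion) {
  tab <- reference_beams()
  i <- match(ion, tab$ion)
  if (is.na(i)) stop("unknown reference beam: ", ion)
  beam_spec(tab$ion[i], tab$Z[i], tab$energy_MeV_n[i], tab$LET_keV_um[i])
}

#' Fluence delivering a dose for a given LET
#'
#' Uses the standard conversion `D[Gy] = 0.1602 * LET[keV/um] * Phi[um^-2]`.
#'
#' @param LET linear energy transfer, keV/um (> 0).
#' @param dose absorbed dose, Gy (>= 0).
#' @return Fluence in particles per um^2.
#' @examples
#' fluence_for_dose(0.22, 1)   # ~28.37 tracks/um^2
#' @export
fluence_for_dose <- function(LET, dose) {
  if (any(!is.finite(LET)) || any(LET <= 0)) stop("LET must be positive")
  if (any(dose < 0)) stop("dose must be non-negative")
  dose / (.GY_PER_KEV_UM2 * LET)
}

#' Expected number of nucleus-crossing tracks
#'
#' For fluence `Phi` the mean number of primary tracks whose chord crosses a
#' spherical nucleus of radius `R_T` is `Phi * pi * R_T^2`; sampling in the
#' simulator is Poisson around this mean.
#'
#' @param fluence fluence per um^2 (>= 0).
#' @param R_T nucleus radius, um (> 0).
#' @return A list with `mean` (real) and `rounded` (nearest integer).
#' @examples
#' expected_direct_tracks(fluence_for_dose(0.22, 1), 4)$rounded  # 1426
#' @export
expected_direct_tracks <- function(fluence, R_T = 4) {
  if (any(fluence < 0)) stop("fluence must be non-negative")
  if (R_T <= 0) stop("R_T must be positive")
  m <- fluence * pi * R_T^2
  list(mean = m, rounded = as.integer(round(m)))
}

#' Kinematic maximum delta-electron energy
#'
#' `T_max = 2 m_e c^2 (gamma^2 - 1)` with `gamma = 1 + E / 931.5` (the
#' atomic mass unit is used uniformly for all ions, protons included).
#'
#' @param energy ion kinetic energy, MeV per nucleon.
#' @return Maximum delta-electron kinetic energy, eV.
#' @examples
#' delta_tmax(1000) / 1e6  # ~3.37 MeV
#' @export
delta_tmax <- function(energy) {
  gam <- 1 + energy / 931.5
  2 * 0.5109989e6 * (gam^2 - 1)
}

#' Sample delta-electron initial energies
#'
#' Draws from the surrogate knock-on spectrum `dN/dT ~ 1/T^2` truncated to
#' `[T_cut, T_max]`, with `T_max` from [delta_tmax()].
#'
#' @param n number of draws.
#' @param beam a [beam_spec()].
#' @param params a [track_model_params()].
#' @return Vector of energies in eV, all within `[T_cut, T_max]`.
#' @export
sample_delta_energy <- function(n, beam, params = track_model_params()) {
  tmax <- delta_tmax(beam$energy)
  tcut <- params$T_cut
  if (tcut >= tmax) stop("degenerate delta spectrum: T_cut >= T_max")
  u <- stats::runif(n)
  1 / (1 / tcut - u * (1 / tcut - 1 / tmax))
}
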