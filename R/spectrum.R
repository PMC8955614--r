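#' Poly-energetic fluence spectra
#'
#' A fluence spectrum is a table of ion components, each with charge `Z`,
#' kinetic energy in MeV/n, LET in keV/um and fluence per um^2, normalized
#' so that `sum(0.1602 * LET * fluence)` equals the normalization dose.
#' Such spectra represent the mixed radiation field behind tissue: a
#' surviving primary peak plus projectile and target fragments.
#'
#' @param Z integer vector of atomic numbers.
#' @param energy kinetic energies, MeV/n.
#' @param fluence fluences, per um^2 (>= 0).
#' @param LET optional LET values, keV/um; looked up with [let_for_ion()]
#'   when missing.
#' @param dose normalization dose in Gy; when given, fluences are rescaled
#'   so the spectrum delivers exactly this dose.
#' @return An object of class `fluence_spectrum`: a data.frame with columns
#'   `Z`, `energy_MeV_n`, `LET_keV_um`, `fluence_um2` and attribute `dose`.
#' @export
fluence_spectrum <- function(Z, energy, fluence, LET = NULL, dose = NULL) {
  Z <- as.integer(Z)
  if (any(is.na(Z)) || any(Z < 1L)) stop("Z must be positive integers")
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("energies must be positive")
  if (any(!is.finite(fluence)) || any(fluence < 0))
    stop("fluences must be non-negative")
  if (is.null(LET)) LET <- let_for_ion(Z, energy)
  if (any(LET <= 0)) stop("LET values must be positive")
  sp <- data.frame(Z = Z, energy_MeV_n = energy, LET_keV_um = LET,
                   fluence_um2 = fluence)
  d0 <- sum(.GY_PER_KEV_UM2 * sp$LET_keV_um * sp$fluence_um2)
  if (!is.null(dose)) {
    if (d0 <= 0) stop("cannot renormalize a zero-fluence spectrum")
    sp$fluence_um2 <- sp$fluence_um2 * dose / d0
    d0 <- dose
  }
  structure(sp, dose = d0, class = c("fluence_spectrum", "data.frame"))
}

#' @export
print.fluence_spectrum <- function(x, ...) {
  cat(sprintf("<fluence_spectrum> %d components, dose %.4g Gy\n",
              nrow(x), attr(x, "dose")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Approximate LET of an ion in water
#'
#' Bethe-like fallback: scales the known LET of the packaged H 1000 MeV
#' beam by `Z^2 / beta^2`.  Exact packaged values are returned for the six
#' reference beams.  Intended for secondary-fragment bookkeeping, where
#' tabulated LET values are themselves uncertain; callers may always supply
#' their own LET column.
#'
#' @param Z atomic number(s).
#' @param energy kinetic energy, MeV/n.
#' @return LET in keV/um.
#' @export
let_for_ion <- function(Z, energy) {
  stopifnot(length(Z) == length(energy))
  beta2 <- function(E) { g <- 1 + E / 931.5; 1 - 1 / g^2 }
  ref <- reference_beams()
  out <- 0.22 * Z^2 * beta2(1000) / beta2(energy)
  for (i in seq_len(nrow(ref))) {
    hit <- Z == ref$Z[i] & abs(energy - ref$energy_MeV_n[i]) < 1e-6
    out[hit] <- ref$LET_keV_um[i]
  }
  out
}

#' Read / write fluence spectrum files
#'
#' Delimited text (comma or whitespace), one header line, columns `Z`,
#' `E_MeV_per_n`, `fluence_um2` and optionally `LET_keV_um`; lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @param dose dose to renormalize to, Gy (default 1).
#' @return A [fluence_spectrum()].
#' @export
load_fluence_spectrum <- function(path, dose = 1) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) < 2) stop("spectrum file has no data rows: ", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- tryCatch(
    read.table(con, header = TRUE, sep = sep, strip.white = TRUE),
    error = function(e) stop("malformed spectrum file: ", conditionMessage(e)))
  need <- c("Z", "E_MeV_per_n", "fluence_um2")
  if (!all(need %in% names(tab)))
    stop("spectrum file must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(tab$fluence_um2) | tab$fluence_um2 < 0)
  if (length(bad))
    stop("negative or non-numeric fluence at data line ", bad[1])
  fluence_spectrum(tab$Z, tab$E_MeV_per_n, tab$fluence_um2,
                   LET = if ("LET_keV_um" %in% names(tab)) tab$LET_keV_um,
                   dose = dose)
}

#' @rdname load_fluence_spectrum
#' @param spectrum a [fluence_spectrum()] to write.
#' @export
write_fluence_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  tab <- data.frame(Z = spectrum$Z, E_MeV_per_n = spectrum$energy_MeV_n,
                    fluence_um2 = spectrum$fluence_um2,
                    LET_keV_um = spectrum$LET_keV_um)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthesize a tissue-transported fluence spectrum
#'
#' Emulates the structure of a beam transported through centimeters of
#' tissue: the surviving primary peak dominates, one to two orders of
#' magnitude above a broad spectrum of secondary H and He ions, plus (for
#' `Z > 2` contributions) low-energy heavy target/projectile fragments with
#' charges up to the primary's.
#'
#' @param primary a [beam_spec()] for the primary beam.
#' @param secondary_ratio total secondary-to-primary fluence ratio
#'   (default 0.2, spread over many bins so per-bin fluence sits 1-2 orders
#'   of magnitude below the peak).
#' @param heavy_ratio fluence ratio of low-energy heavy fragments
#'   (Z from 3 to the primary Z) to the primary.
#' @param n_bins energy bins per secondary component.
#' @param dose normalization dose, Gy.
#' @return A [fluence_spectrum()].
#' @export
synth_fluence_spectrum <- function(primary, secondary_ratio = 0.2,
                                   heavy_ratio = 0.02, n_bins = 12,
                                   dose = 1) {
  stopifnot(inherits(primary, "beam_spec"))
  Z <- primary$Z; E0 <- primary$energy
  comp_Z <- integer(); comp_E <- double(); comp_phi <- double()
  # primary peak
  comp_Z <- c(comp_Z, Z); comp_E <- c(comp_E, E0); comp_phi <- c(comp_phi, 1)
  # broad H and He secondaries, log-spaced from 10 MeV/n to ~2 E0
  eg <- exp(seq(log(10), log(2 * E0), length.out = n_bins))
  wts <- exp(-0.5 * ((log(eg) - log(E0 / 2)) / 1.2)^2)  # broad log bump
  wts <- wts / sum(wts)
  for (zs in c(1L, 2L)) {
    share <- if (zs == 1L) 0.7 else 0.3
    comp_Z <- c(comp_Z, rep(zs, n_bins))
    comp_E <- c(comp_E, eg)
    comp_phi <- c(comp_phi, secondary_ratio * share * wts)
  }
  # low-energy heavy fragments (target fragmentation), Z up to the primary's
  if (heavy_ratio > 0) {
    zh <- seq(3L, max(3L, Z))
    el <- exp(seq(log(5), log(50), length.out = 4))
    for (z in zh) {
      comp_Z <- c(comp_Z, rep(z, length(el)))
      comp_E <- c(comp_E, el)
      comp_phi <- c(comp_phi, rep(heavy_ratio / (length(zh) * length(el)),
                                  length(el)))
    }
  }
  fluence_spectrum(comp_Z, comp_E, comp_phi, dose = dose)
}

#' Coerce a mono-energetic beam to a one-component spectrum
#' @param beam a [beam_spec()].
#' @param dose normalization dose, Gy.
#' @return A single-row [fluence_spectrum()], which behaves identically to
#'   the beam it was built from.
#' @export
as_fluence_spectrum <- function(beam, dose = 1) {
  stopifnot(inherits(beam, "beam_spec"))
  fluence_spectrum(beam$Z, beam$energy, fluence_for_dose(beam$LET, dose),
                   LET = beam$LET, dose = dose)
}
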