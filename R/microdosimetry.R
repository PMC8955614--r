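#' Per-track imparted energy
#'
#' Sums, for each track, the energy of its deposition events that lie
#' inside the nucleus sphere (`|position| <= R_T`).  Tracks that impart no
#' energy to the nucleus are dropped, matching the convention used for
#' single-ion spectra.
#'
#' @param irr result of [sample_irradiation()]; when it carries an
#'   `events` table the sum is recomputed from the events, otherwise the
#'   kernel-accumulated per-track energies are used.
#' @param R_T nucleus radius, um.
#' @return data.frame with `track`, `category`, `eps_eV` for tracks with
#'   `eps_eV > 0`.
#' @export
per_track_energy <- function(irr, R_T = irr$geometry$R_T) {
  if (!is.null(irr$events)) {
    ev <- irr$events
    inside <- ev$x^2 + ev$y^2 + ev$z^2 <= R_T^2
    eps <- tapply(ev$energy[inside], factor(ev$track[inside],
                  levels = irr$tracks$track), sum, default = 0)
    out <- data.frame(track = irr$tracks$track,
                      category = irr$tracks$category,
                      eps_eV = as.numeric(eps))
  } else {
    out <- irr$tracks[, c("track", "category", "eps_eV")]
  }
  out[out$eps_eV > 0, , drop = FALSE]
}

#' Default log-spaced bin edges for single-ion spectra
#' @param n number of bins (default 60).
#' @param lo,hi bin range in eV.
#' @return Vector of `n + 1` edges.
#' @export
spectrum_bins <- function(n = 60, lo = 1e1, hi = 1e7) {
  exp(seq(log(lo), log(hi), length.out = n + 1))
}

#' Single-ion energy-deposition spectrum f(eps)
#'
#' Histogram of per-track imparted energies for one contribution,
#' normalized to the delivered dose.  Imparted energies outside the bin
#' range are counted in overflow bins with a warning.
#'
#' @param eps vector of per-track imparted energies, eV (only positive
#'   entries are binned).
#' @param contribution `"tot"`, `"dir"` or `"ind"`.
#' @param edges bin edges in eV (default [spectrum_bins()]).
#' @param dose normalization dose, Gy.
#' @return An object of class `single_ion_spectrum`: data.frame with
#'   `bin_lo_eV`, `bin_hi_eV`, `count`, `density` (per-track probability
#'   density in 1/eV), and attributes `dose`, `contribution`, `n_tracks`.
#' @export
build_spectrum <- function(eps, contribution = "tot",
                           edges = spectrum_bins(), dose = 1) {
  stopifnot(contribution %in% c("tot", "dir", "ind"))
  eps <- eps[eps > 0]
  n_under <- sum(eps < edges[1])
  n_over <- sum(eps > edges[length(edges)])
  if (n_under + n_over > 0)
    warning(sprintf("%d track energies outside bin range (overflow bins)",
                    n_under + n_over))
  cts <- tabulate(findInterval(eps, edges,
                               rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = length(edges) - 1)
  wid <- diff(edges)
  dens <- if (length(eps)) cts / (sum(cts) * wid) else rep(0, length(cts))
  structure(data.frame(bin_lo_eV = edges[-length(edges)],
                       bin_hi_eV = edges[-1],
                       count = cts, density = dens),
            dose = dose, contribution = contribution,
            n_tracks = length(eps), n_overflow = n_under + n_over,
            class = c("single_ion_spectrum", "data.frame"))
}

#' Direct / indirect dose fractions
#'
#' Percentages of the nucleus-imparted energy carried by direct
#' (nucleus-crossing) and indirect (delta electrons of distant tracks)
#' contributions; they sum to 100 exactly.
#'
#' @param pte per-track energy table from [per_track_energy()], or a
#'   [sample_irradiation()] result.
#' @return list with `D_dir` and `D_ind` in percent.
#' @export
dose_fractions <- function(pte) {
  if (is.list(pte) && !is.data.frame(pte) && !is.null(pte$tracks))
    pte <- per_track_energy(pte)
  tot <- sum(pte$eps_eV)
  if (tot <= 0) stop("no energy imparted to the nucleus")
  dir <- sum(pte$eps_eV[pte$category == "direct"])
  list(D_dir = 100 * dir / tot, D_ind = 100 * (tot - dir) / tot)
}

#' Write spectra for the three contributions as CSV
#'
#' Columns `bin_lo_eV`, `bin_hi_eV`, `count_tot`, `count_dir`, `count_ind`.
#' When run metadata is supplied, a JSON sidecar (`<path>.json`) records it
#' together with the per-contribution track counts and the dose.
#'
#' @param tot,dir,ind `single_ion_spectrum` objects on the same bins.
#' @param path output file.
#' @param meta optional named list of run metadata (beam, seed, params...)
#'   for the JSON sidecar.
#' @export
write_spectrum_csv <- function(tot, dir, ind, path, meta = NULL) {
  stopifnot(all(tot$bin_lo_eV == dir$bin_lo_eV),
            all(tot$bin_lo_eV == ind$bin_lo_eV))
  write.csv(data.frame(bin_lo_eV = tot$bin_lo_eV,
                       bin_hi_eV = tot$bin_hi_eV,
                       count_tot = tot$count, count_dir = dir$count,
                       count_ind = ind$count),
            path, row.names = FALSE)
  if (!is.null(meta)) {
    side <- c(meta, list(dose_Gy = attr(tot, "dose"),
                         n_tracks = list(tot = attr(tot, "n_tracks"),
                                         dir = attr(dir, "n_tracks"),
                                         ind = attr(ind, "n_tracks"))))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
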