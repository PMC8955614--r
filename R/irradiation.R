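#' Transport a delta electron
#'
#' Condensed random walk: per step the electron loses a fixed fraction of
#' its remaining energy, spread along the corresponding decrement of the
#' residual range `R(E) = a E^p`, then scatters isotropically; positions
#' wrap across the box faces under periodic boundary conditions.  The walk
#' ends with a point deposition of the residual energy once it falls below
#' `2 T_cut`, so the deposited energies sum exactly to the initial energy.
#'
#' @param origin numeric length-3, starting position (um, nucleus-centered).
#' @param direction numeric length-3 initial direction (normalized
#'   internally).
#' @param energy initial kinetic energy, eV (must be >= `T_cut`).
#' @param geometry an [irradiation_geometry()].
#' @param params a [track_model_params()].
#' @return data.frame of deposition events (`x`, `y`, `z`, `energy`).
#' @export
transport_electron <- function(origin, direction, energy,
                               geometry = irradiation_geometry(),
                               params = track_model_params()) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  if (energy < params$T_cut) stop("energy below transport cutoff T_cut")
  ev <- cpp_transport_electron(as.numeric(origin), as.numeric(direction),
                               energy, geometry$R_T, geometry$L,
                               geometry$voxel, params$T_cut,
                               params$step_frac, params$range_a,
                               params$range_p, params$cluster_frac,
                               params$cluster_lo, params$cluster_hi,
                               geometry$pbc, FALSE)
  as.data.frame(ev)
}

# Build kernel bin vectors from a beam or spectrum at the requested dose.
.source_bins <- function(source, dose) {
  if (inherits(source, "beam_spec")) {
    data.frame(Z = source$Z, energy = source$energy, LET = source$LET,
               phi = fluence_for_dose(source$LET, dose))
  } else if (inherits(source, "fluence_spectrum")) {
    if (nrow(source) == 0 || sum(source$fluence_um2) <= 0)
      stop("empty spectrum")
    d0 <- attr(source, "dose")
    data.frame(Z = source$Z, energy = source$energy_MeV_n,
               LET = source$LET_keV_um,
               phi = source$fluence_um2 * dose / d0)
  } else stop("source must be a beam_spec or fluence_spectrum")
}

# Low-level driver shared by the module surface and the pipeline.
.kernel_run <- function(source, dose, geometry, params,
                        contribution = c("tot", "dir", "ind"),
                        occupancy = NULL, break_params = NULL,
                        keep_events = FALSE, sphere_only = TRUE,
                        prune = TRUE, want_voxels = FALSE,
                        want_breaks = FALSE) {
  contribution <- match.arg(contribution)
  if (dose <= 0) stop("dose must be positive")
  bins <- .source_bins(source, dose)
  tmax <- delta_tmax(bins$energy)
  if (any(params$T_cut >= tmax))
    stop("T_cut exceeds the kinematic maximum for a spectrum component")
  mode <- match(contribution, c("tot", "dir", "ind")) - 1L
  occ <- occupancy
  if (is.null(occ))
    occ <- list(key = numeric(), offset = integer(),
                fiber = integer(), segment = integer())
  kb <- if (is.null(break_params)) 0 else break_params$k
  eth <- if (is.null(break_params)) 500 else break_params$threshold
  cpp_simulate_run(bins$phi, bins$LET, tmax,
                   geometry$R_T, geometry$L, geometry$voxel,
                   params$f_local, params$T_cut, params$w0,
                   params$step_frac, params$range_a, params$range_p,
                   params$cluster_frac, params$cluster_lo,
                   params$cluster_hi,
                   mode, geometry$axis == "z", geometry$pbc, prune,
                   sphere_only, keep_events,
                   occ$key, occ$offset, occ$fiber, occ$segment,
                   kb, eth, want_breaks, want_voxels)
}

#' Sample one irradiation history
#'
#' Simulates the primary chords of one Monte Carlo history through the
#' periodic box: the number of chords is Poisson with mean
#' `Phi_total * L^2`; for spectra each chord's ion is drawn with
#' probability proportional to its fluence.  Each chord deposits
#' `f_local * LET` as core events along its path and emits delta electrons
#' carrying the remaining LET fraction in expectation.  A track is direct
#' when its chord crosses the nucleus and indirect otherwise.
#'
#' @param source a [beam_spec()] or [fluence_spectrum()].
#' @param dose absorbed dose, Gy (> 0).
#' @param geometry an [irradiation_geometry()].
#' @param params a [track_model_params()].
#' @param contribution which tracks to simulate: `"tot"` (all), `"dir"`
#'   (nucleus-crossing only) or `"ind"` (the rest).
#' @param keep_events record every energy-deposition event (slower; meant
#'   for small runs and diagnostics).  Without it only in-nucleus voxel
#'   deposits and per-track imparted energies are kept.
#' @return A list with `tracks` (data.frame `track`, `category`, `eps_eV`,
#'   the per-track energy imparted to the nucleus) and, when requested,
#'   `events` (data.frame `track`, `x`, `y`, `z`, `energy`, `origin`).
#' @export
sample_irradiation <- function(source, dose,
                               geometry = irradiation_geometry(),
                               params = track_model_params(),
                               contribution = "tot",
                               keep_events = FALSE) {
  out <- .kernel_run(source, dose, geometry, params, contribution,
                     keep_events = keep_events,
                     sphere_only = !keep_events, prune = !keep_events,
                     want_voxels = TRUE)
  tracks <- data.frame(track = seq_along(out$track_cat),
                       category = ifelse(out$track_cat == 0,
                                         "direct", "indirect"),
                       bin = out$track_bin,
                       eps_eV = out$track_eps)
  res <- list(tracks = tracks,
              voxels = data.frame(key = out$voxels$key,
                                  energy_eV = out$voxels$energy),
              e_dir = out$e_dir, e_ind = out$e_ind,
              geometry = geometry)
  if (keep_events) {
    ev <- as.data.frame(out$events)
    ev$track <- ev$track + 1L
    ev$origin <- ifelse(ev$origin == 0, "ion-core", "delta-electron")
    res$events <- ev
  }
  res
}
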