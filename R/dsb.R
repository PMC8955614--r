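#' Induce double-strand breaks
#'
#' Voxels are eligible when they hold both deposited energy and at least
#' one chromatin segment.  Per eligible voxel the number of breaks is
#' Poisson with mean `k * E_voxel`; each break is assigned to a uniformly
#' chosen resident segment, positioned at the voxel center, and classed
#' complex when the voxel energy exceeds the 500 eV threshold, simple
#' otherwise.
#'
#' @param vmap a [score_events()] voxel map.
#' @param intersections a [fiber_voxel_intersections()] table on the same
#'   grid.
#' @param params a [break_model_params()].
#' @return data.frame of breaks: `id`, `fiber`, `segment`, `x`, `y`, `z`
#'   (voxel center, um), `complex` (logical), `key`.
#' @export
induce_breaks <- function(vmap, intersections,
                          params = break_model_params()) {
  voxel <- attr(vmap, "voxel"); R_T <- attr(vmap, "R_T")
  vm <- data.table::as.data.table(vmap)[, c("key", "energy_eV")]
  it <- data.table::as.data.table(intersections)
  hit <- vm[it, on = "key", nomatch = NULL]
  if (nrow(hit) == 0) return(.empty_breaks())
  # one Poisson draw per eligible voxel, then uniform segment assignment
  vox <- hit[, list(energy_eV = energy_eV[1], n_seg = .N), by = "key"]
  vox[, n_break := rpois(.N, params$k * energy_eV)]
  vox <- vox[n_break > 0]
  if (nrow(vox) == 0) return(.empty_breaks())
  picks <- hit[vox, on = "key"][, {
    j <- sample.int(.N, n_break[1], replace = TRUE)
    list(fiber = fiber[j], segment = segment[j],
         energy_eV = energy_eV[1], ix = ix[j], iy = iy[j], iz = iz[j])
  }, by = "key"]
  data.frame(id = seq_len(nrow(picks)),
             fiber = picks$fiber, segment = picks$segment,
             x = (picks$ix + 0.5) * voxel - R_T,
             y = (picks$iy + 0.5) * voxel - R_T,
             z = (picks$iz + 0.5) * voxel - R_T,
             complex = picks$energy_eV > params$threshold,
             key = picks$key)
}

.empty_breaks <- function() {
  data.frame(id = integer(), fiber = integer(), segment = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             complex = logical(), key = numeric())
}

#' Calibrate the DSB intensity k
#'
#' Sets the Poisson scale `k` (breaks per eV of eligible voxel energy) so
#' that the mean number of DSB per cell at 1 Gy for a reference low-LET
#' beam equals the target yield of 35.  Because the break count is exactly
#' linear in `k`, the calibration is a single Monte Carlo estimate of the
#' mean eligible energy per history; no iterative search is needed.
#'
#' @param beam reference beam (default the packaged H 1000 MeV beam).
#' @param histories number of calibration histories (>= 200 recommended).
#' @param target target DSB yield per cell per Gy (default 35).
#' @param geometry,params,pool geometry, track surrogate parameters and
#'   chromatin pool (built with defaults when omitted).
#' @return list with `k`, `target`, `mean_elig_eV` (mean eligible energy
#'   per history), `se_elig_eV`, `histories`.
#' @export
calibrate_k <- function(beam = reference_beam("H"), histories = 200,
                        target = 35,
                        geometry = irradiation_geometry(),
                        params = track_model_params(),
                        pool = NULL) {
  if (histories < 2) stop("need at least 2 calibration histories")
  if (is.null(pool)) pool <- chromatin_pool()
  elig <- vapply(seq_len(histories), function(h) {
    occ <- pool[[(h - 1L) %% length(pool) + 1L]]
    out <- .kernel_run(beam, 1, geometry, params, "tot",
                       occupancy = occ, want_breaks = FALSE)
    out$elig_energy
  }, numeric(1))
  m <- mean(elig)
  if (m <= 0)
    stop("calibration failed: no eligible voxel energy observed; ",
         "check chromatin density and track parameters")
  list(k = target / m, target = target, mean_elig_eV = m,
       se_elig_eV = sd(elig) / sqrt(histories), histories = histories)
}
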