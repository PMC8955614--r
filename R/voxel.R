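#' Score events onto the sparse 20 nm voxel grid
#'
#' Accumulates event energies into 20 x 20 x 20 nm^3 voxels covering the
#' bounding cube of the nucleus.  Voxel indices are
#' `floor((position + R_T) / voxel)` per axis (half-open voxels, 0-based;
#' an event exactly on a boundary belongs to the higher-index voxel).
#' Events outside the nucleus sphere are ignored, and only voxels with
#' positive energy are stored.
#'
#' @param events data.frame with columns `x`, `y`, `z` (um) and `energy`
#'   (eV).
#' @param voxel voxel edge, um (default 0.02).
#' @param R_T nucleus radius, um.
#' @return An object of class `voxel_map`: data.table with `key` (packed
#'   voxel index), `ix`, `iy`, `iz`, `energy_eV`, and attributes `voxel`,
#'   `R_T`, `n_axis`.
#' @export
score_events <- function(events, voxel = 0.02, R_T = 4) {
  if (voxel <= 0) stop("voxel size must be positive")
  n_axis <- as.integer(round(2 * R_T / voxel))
  inside <- events$x^2 + events$y^2 + events$z^2 <= R_T^2
  ev <- events[inside & events$energy > 0, , drop = FALSE]
  idx <- function(p) pmin(n_axis - 1L, pmax(0L,
            as.integer(floor((p + R_T) / voxel))))
  dt <- data.table::setDT(list(
    key = (as.numeric(idx(ev$x)) * n_axis + idx(ev$y)) * n_axis +
      idx(ev$z),
    energy_eV = ev$energy))
  dt <- dt[, list(energy_eV = sum(energy_eV)), by = "key"]
  data.table::setorderv(dt, "key")
  kk <- dt$key
  iz <- kk %% n_axis; kk <- (kk - iz) / n_axis
  iy <- kk %% n_axis; ix <- (kk - iy) / n_axis
  dt[, c("ix", "iy", "iz") := list(as.integer(ix), as.integer(iy),
                                   as.integer(iz))]
  structure(dt, voxel = voxel, R_T = R_T, n_axis = n_axis,
            class = c("voxel_map", class(dt)))
}

#' Merge voxel maps voxelwise
#' @param ... `voxel_map` objects on the same grid.
#' @return A `voxel_map` whose per-voxel energies are the sums.
#' @export
merge_voxel_maps <- function(...) {
  maps <- list(...)
  stopifnot(length(maps) >= 1)
  va <- attr(maps[[1]], "voxel"); ra <- attr(maps[[1]], "R_T")
  for (m in maps)
    stopifnot(inherits(m, "voxel_map"), attr(m, "voxel") == va,
              attr(m, "R_T") == ra)
  all <- data.table::rbindlist(lapply(maps, function(m)
    data.table::as.data.table(m)[, c("key", "energy_eV")]))
  dt <- all[, list(energy_eV = sum(energy_eV)), by = "key"]
  data.table::setorderv(dt, "key")
  n_axis <- attr(maps[[1]], "n_axis")
  kk <- dt$key
  iz <- kk %% n_axis; kk <- (kk - iz) / n_axis
  iy <- kk %% n_axis; ix <- (kk - iy) / n_axis
  dt[, c("ix", "iy", "iz") := list(as.integer(ix), as.integer(iy),
                                   as.integer(iz))]
  structure(dt, voxel = va, R_T = ra, n_axis = n_axis,
            class = c("voxel_map", class(dt)))
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf(
    "<voxel_map> %d occupied voxels (%g nm), total %.4g eV\n",
    nrow(x), attr(x, "voxel") * 1000, sum(x$energy_eV)))
  invisible(x)
}

#' Dump a voxel map as delimited text
#' @param vmap a `voxel_map`.
#' @param path output file; columns `ix`, `iy`, `iz`, `energy_eV`.
#' @export
write_voxel_map <- function(vmap, path) {
  write.csv(as.data.frame(vmap)[, c("ix", "iy", "iz", "energy_eV")],
            path, row.names = FALSE)
  invisible(path)
}
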