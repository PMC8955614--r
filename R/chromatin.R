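#' Diploid human genome table
#'
#' 46 chromosome copies (22 autosome pairs plus XX) with lengths in Mbp
#' from the standard reference assembly and approximate centromere
#' positions.  This is the bookkeeping table behind the interphase
#' chromatin model; supply your own table for other karyotypes.
#'
#' @return data.frame with 46 rows: `fiber` (1-46), `chrom`, `length_Mbp`,
#'   `centromere_Mbp`.
#' @export
genome_table <- function() {
  hap <- read.csv(system.file("extdata", "genome_human.csv",
                              package = "microca"),
                  stringsAsFactors = FALSE)
  dip <- rbind(hap, hap)
  dip <- dip[order(match(dip$chrom, hap$chrom)), ]
  data.frame(fiber = seq_len(nrow(dip)), dip, row.names = NULL)
}

#' Generate interphase chromatin fibers
#'
#' Models the 3D distribution of the 46 interphase chromatin fibers as
#' independent fixed-step random walks confined to the nucleus sphere:
#' uniformly random step directions, uniform start points, and radial
#' reflection at the boundary (so fiber length is exact).  The number of
#' segments per fiber is proportional to its chromosome length in Mbp.
#'
#' @param genome genome table as from [genome_table()].
#' @param R_T nucleus radius, um.
#' @param step segment length, um (default 0.02 = one voxel).
#' @param segments_per_Mbp walk resolution (default 250, i.e. ~4 kbp per
#'   20 nm segment; see the vignette for the density rationale).
#' @return An object of class `chromatin_fibers`: data.frame of vertices
#'   (`fiber`, `x`, `y`, `z`) with attributes `genome`, `step`,
#'   `segments_per_Mbp`, `R_T`.
#' @export
generate_chromatin <- function(genome = genome_table(), R_T = 4,
                               step = 0.02, segments_per_Mbp = 250) {
  if (step <= 0 || segments_per_Mbp <= 0)
    stop("step and segments_per_Mbp must be positive")
  nseg <- pmax(1L, as.integer(round(genome$length_Mbp * segments_per_Mbp)))
  out <- cpp_generate_chromatin(nseg, R_T, step)
  structure(as.data.frame(out),
            genome = genome, step = step,
            segments_per_Mbp = segments_per_Mbp, R_T = R_T,
            class = c("chromatin_fibers", "data.frame"))
}

#' @export
print.chromatin_fibers <- function(x, ...) {
  cat(sprintf(
    "<chromatin_fibers> %d fibers, %d vertices, step %g nm, R_T %g um\n",
    length(unique(x$fiber)), nrow(x), attr(x, "step") * 1000,
    attr(x, "R_T")))
  invisible(x)
}

#' Fiber-voxel intersections
#'
#' Rasterizes every fiber segment onto the voxel grid (3D digital
#' differential analyzer): a voxel lists every segment passing through it.
#'
#' @param fibers a [generate_chromatin()] result.
#' @param voxel voxel edge, um.
#' @param R_T nucleus radius, um.
#' @return data.frame with `key` (packed voxel index), `ix`, `iy`, `iz`,
#'   `fiber`, `segment`, sorted by `key`.
#' @export
fiber_voxel_intersections <- function(fibers, voxel = 0.02,
                                      R_T = attr(fibers, "R_T")) {
  if (nrow(fibers) == 0)
    return(data.frame(key = numeric(), ix = integer(), iy = integer(),
                      iz = integer(), fiber = integer(),
                      segment = integer()))
  rows <- cpp_fiber_voxel_rows(fibers$x, fibers$y, fibers$z, fibers$fiber,
                               R_T, voxel)
  n <- rows$n_axis
  kk <- rows$key
  iz <- kk %% n; kk <- (kk - iz) / n
  iy <- kk %% n; ix <- (kk - iy) / n
  data.frame(key = rows$key, ix = as.integer(ix), iy = as.integer(iy),
             iz = as.integer(iz), fiber = rows$fiber,
             segment = rows$segment)
}

# CSR occupancy index used by the fused simulation kernel.
.chromatin_index <- function(fibers, voxel = 0.02,
                             R_T = attr(fibers, "R_T")) {
  rows <- cpp_fiber_voxel_rows(fibers$x, fibers$y, fibers$z, fibers$fiber,
                               R_T, voxel)
  idx <- cpp_occupancy_index(rows$key, rows$fiber, rows$segment)
  idx$genome <- attr(fibers, "genome")
  idx$n_axis <- rows$n_axis
  idx
}

#' Build a pool of chromatin configurations
#'
#' Full per-history regeneration of the chromatin walk is expensive at the
#' packaged resolution; runs instead cycle over a small pool of
#' independently generated configurations (see the vignette).
#'
#' @param n_configs pool size.
#' @inheritParams generate_chromatin
#' @param voxel voxel edge, um.
#' @return list of occupancy indexes (internal structure).
#' @export
chromatin_pool <- function(n_configs = 4, genome = genome_table(),
                           R_T = 4, step = 0.02, segments_per_Mbp = 250,
                           voxel = 0.02) {
  lapply(seq_len(n_configs), function(i) {
    fib <- generate_chromatin(genome, R_T, step, segments_per_Mbp)
    .chromatin_index(fib, voxel, R_T)
  })
}
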