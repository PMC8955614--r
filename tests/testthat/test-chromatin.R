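test_that("chromatin model produces 46 confined fibers with Mbp scaling", {
  set.seed(8)
  gen <- genome_table()
  expect_equal(nrow(gen), 46L)
  fib <- generate_chromatin(gen, segments_per_Mbp = 5)
  expect_equal(length(unique(fib$fiber)), 46L)
  expect_true(all(fib$x^2 + fib$y^2 + fib$z^2 <= 4^2 + 1e-9))
  # segment counts proportional to Mbp (2:1 genome -> 2:1 segments)
  toy <- data.frame(fiber = 1:2, chrom = c("a", "b"),
                    length_Mbp = c(100, 50), centromere_Mbp = c(10, 5))
  f2 <- generate_chromatin(toy, segments_per_Mbp = 10)
  ns <- table(f2$fiber) - 1L
  expect_equal(unname(ns[1] / ns[2]), 2)
})

test_that("segment rasterization agrees with a 1 nm point-sampling oracle", {
  set.seed(9)
  vox <- 0.02; R_T <- 4
  for (rep in 1:100) {
    p0 <- runif(3, -1, 1); d <- rnorm(3)
    d <- d / sqrt(sum(d^2)) * runif(1, 0.001, 0.08)
    p1 <- p0 + d
    fib <- structure(data.frame(fiber = c(1L, 1L),
                                x = c(p0[1], p1[1]), y = c(p0[2], p1[2]),
                                z = c(p0[3], p1[3])),
                     R_T = R_T)
    got <- fiber_voxel_intersections(fib, vox, R_T)
    # oracle: sample the segment every 1 nm and collect voxel ids
    tt <- seq(0, 1, length.out = max(2, ceiling(sqrt(sum(d^2)) / 0.001)))
    px <- p0[1] + tt * d[1]; py <- p0[2] + tt * d[2]; pz <- p0[3] + tt * d[3]
    ii <- floor((cbind(px, py, pz) + R_T) / vox)
    keys <- unique((ii[, 1] * 400 + ii[, 2]) * 400 + ii[, 3])
    expect_true(all(keys %in% got$key),
                info = sprintf("rep %d: oracle voxel missed", rep))
  }
})

test_that("rasterization edge cases", {
  # segment fully inside one voxel
  fib <- structure(data.frame(fiber = c(1L, 1L), x = c(0.001, 0.004),
                              y = c(0.001, 0.002), z = c(0.001, 0.003)),
                   R_T = 4)
  got <- fiber_voxel_intersections(fib, 0.02, 4)
  expect_equal(nrow(got), 1L)
  expect_equal(got[, c("ix", "iy", "iz")],
               data.frame(ix = 200L, iy = 200L, iz = 200L))
  # axis-aligned segment of length 3 voxels -> 3-4 voxels
  fib2 <- structure(data.frame(fiber = c(1L, 1L), x = c(0.005, 0.065),
                               y = c(0.01, 0.01), z = c(0.01, 0.01)),
                    R_T = 4)
  got2 <- fiber_voxel_intersections(fib2, 0.02, 4)
  expect_true(nrow(got2) %in% 3:4)
  # empty fiber set
  empty <- structure(data.frame(fiber = integer(), x = numeric(),
                                y = numeric(), z = numeric()), R_T = 4)
  expect_equal(nrow(fiber_voxel_intersections(empty, 0.02, 4)), 0L)
})

test_that("chromatin occupancy is stable across seeds (regression guard)", {
  occ <- sapply(1:2, function(s) {
    set.seed(100 + s)
    fib <- generate_chromatin(segments_per_Mbp = 20)
    idx <- microca:::.chromatin_index(fib)
    length(idx$key)
  })
  expect_lt(max(occ) / min(occ), 2)
})
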