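make_vmap <- function(df) score_events(df, voxel = 0.02, R_T = 4)

test_that("breaks need both energy and chromatin; 500 eV sets the class", {
  # voxel at origin with 600 eV, chromatin segment resident
  vm <- make_vmap(data.frame(x = 0.01, y = 0.01, z = 0.01, energy = 600))
  it <- data.frame(key = vm$key, ix = vm$ix, iy = vm$iy, iz = vm$iz,
                   fiber = 3L, segment = 17L)
  set.seed(10)
  br <- induce_breaks(vm, it, break_model_params(k = 5))
  expect_gt(nrow(br), 0)
  expect_true(all(br$complex))
  expect_true(all(br$fiber == 3L & br$segment == 17L))
  # sub-threshold voxel -> simple breaks
  vm2 <- make_vmap(data.frame(x = 0.01, y = 0.01, z = 0.01, energy = 400))
  br2 <- induce_breaks(vm2, it, break_model_params(k = 5))
  expect_true(all(!br2$complex))
  # chromatin elsewhere -> no breaks
  it3 <- data.frame(key = 0, ix = 0L, iy = 0L, iz = 0L,
                    fiber = 1L, segment = 1L)
  expect_equal(nrow(induce_breaks(vm, it3, break_model_params(k = 5))), 0L)
})

test_that("break counts are Poisson with mean k * E_voxel", {
  set.seed(11)
  n <- 8000
  # n independent eligible voxels (at voxel centers), lambda = 0.3 each
  xs <- ((seq_len(n) %% 180) + 0.5) * 0.02 - 1.8
  ys <- rep(0.01, n)
  zs <- ((seq_len(n) %/% 180) + 0.5) * 0.02 - 1.5
  vm <- make_vmap(data.frame(x = xs, y = ys, z = zs, energy = 100))
  it <- data.frame(key = vm$key, ix = vm$ix, iy = vm$iy, iz = vm$iz,
                   fiber = 1L, segment = seq_len(nrow(vm)))
  br <- induce_breaks(vm, it, break_model_params(k = 0.003))
  lam <- 0.3
  se <- sqrt(lam / nrow(vm))
  expect_lt(abs(nrow(br) / nrow(vm) - lam), 3 * se)
})

test_that("DSB yield is linear in k and in dose", {
  set.seed(12)
  pool <- test_pool_coarse()
  g <- irradiation_geometry(); tp <- track_model_params()
  tot_breaks <- function(k, dose, nh) {
    bp <- break_model_params(k = k)
    sum(vapply(seq_len(nh), function(h) {
      o <- microca:::.kernel_run(reference_beam("C"), dose, g, tp, "tot",
                                 occupancy = pool[[1]], break_params = bp,
                                 want_breaks = TRUE)
      length(o$breaks$fiber)
    }, numeric(1)))
  }
  n1 <- tot_breaks(0.002, 1, 60)
  n2 <- tot_breaks(0.004, 1, 60)
  expect_gt(n1, 100)
  expect_equal(n2 / n1, 2, tolerance = 0.25)
  nh2 <- tot_breaks(0.004, 0.5, 60)
  expect_equal(nh2 / n2, 0.5, tolerance = 0.25)
})

test_that("calibration hits the 35 DSB/cell/Gy target by construction", {
  set.seed(13)
  pool <- test_pool()
  cal <- calibrate_k(histories = 60, pool = pool)
  expect_equal(cal$k * cal$mean_elig_eV, 35, tolerance = 1e-9)
  expect_gt(cal$k, 0)
  # sanity: relative SE of the calibration mean is small
  expect_lt(cal$se_elig_eV / cal$mean_elig_eV, 0.1)
})
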