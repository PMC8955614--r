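test_that("fluence-dose conversion matches the 0.1602 rule", {
  expect_equal(fluence_for_dose(0.22, 1), 1 / (0.1602 * 0.22),
               tolerance = 1e-12)
  expect_equal(round(fluence_for_dose(0.22, 1), 2), 28.37)
  expect_equal(round(fluence_for_dose(149.2, 1), 5), 0.04184)
  expect_identical(fluence_for_dose(12.9, 0), 0)
  expect_error(fluence_for_dose(0, 1), "LET")
  expect_error(fluence_for_dose(-3, 1), "LET")
})

test_that("expected nucleus traversals follow Phi * pi * R_T^2", {
  expect_equal(expected_direct_tracks(28.37, 4)$rounded, 1426L)
  expect_equal(expected_direct_tracks(4.006, 4)$rounded, 201L)
  expect_identical(expected_direct_tracks(0, 4)$rounded, 0L)
  m <- expected_direct_tracks(1.3, 2)
  expect_equal(m$mean, 1.3 * pi * 4)
})

test_that("packaged beams carry the documented properties", {
  tab <- reference_beams()
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$LET_keV_um > 0))
  expect_true(all(tab$energy_MeV_n >= 250))
  b <- reference_beam("Fe")
  expect_s3_class(b, "beam_spec")
  expect_equal(b$LET, 149.2)
  expect_error(reference_beam("Xx"), "unknown")
})

test_that("delta kinematics: T_max follows 2 m_e c^2 (gamma^2 - 1)", {
  gam <- 1 + 1000 / 931.5
  expect_equal(delta_tmax(1000), 2 * 0.5109989e6 * (gam^2 - 1),
               tolerance = 1e-12)
  expect_equal(delta_tmax(1000) / 1e6, 3.37, tolerance = 0.01)
  expect_equal(delta_tmax(250) / 1e6, 0.62, tolerance = 0.01)
})

test_that("delta energy draws follow the truncated 1/T^2 spectrum", {
  set.seed(1)
  b <- reference_beam("H")
  p <- track_model_params()
  x <- sample_delta_energy(20000, b, p)
  tmax <- delta_tmax(b$energy)
  expect_true(all(x >= p$T_cut & x <= tmax))
  # closed-form median of the truncated spectrum
  med <- 1 / (1 / p$T_cut - 0.5 * (1 / p$T_cut - 1 / tmax))
  expect_equal(median(x), med, tolerance = 0.05)
  # degenerate interval
  expect_error(sample_delta_energy(1, b, track_model_params(T_cut = 1e7)),
               "degenerate|exceeds")
})

test_that("track categorization agrees with the chord geometry oracle", {
  set.seed(301)
  irr <- sample_irradiation(reference_beam("C"), 0.3, keep_events = TRUE)
  ev <- irr$events[irr$events$origin == "ion-core", ]
  # core events sit on the (z-axis) chord, so any one carries its (x, y)
  first <- ev[!duplicated(ev$track), ]
  oracle <- ifelse(first$x^2 + first$y^2 <= 4^2, "direct", "indirect")
  got <- irr$tracks$category[first$track]
  expect_identical(got, oracle)
  # both categories are represented and events stay inside the box
  expect_setequal(unique(irr$tracks$category), c("direct", "indirect"))
  expect_true(all(abs(irr$events[, c("x", "y", "z")]) <= 5 + 1e-9))
})

test_that("PBC at L matches an enlarged open box for short-range electrons", {
  set.seed(302)
  b <- beam_spec("X", 6, 5, 10)   # 5 MeV/n: T_max ~11 keV, ranges < 3 um
  tp <- track_model_params(T_cut = 1000)
  d_ind <- function(geom, nh) {
    e <- c(0, 0)
    for (h in seq_len(nh)) {
      o <- microca:::.kernel_run(b, 1, geom, tp, "tot")
      e <- e + c(o$e_dir, o$e_ind)
    }
    100 * e[2] / sum(e)
  }
  v_pbc <- d_ind(irradiation_geometry(L = 10, pbc = TRUE), 250)
  v_open <- d_ind(irradiation_geometry(L = 40, pbc = FALSE), 250)
  expect_lt(abs(v_pbc - v_open) / v_pbc, 0.3)
})

test_that("electron transport conserves energy and honors PBC wrapping", {
  set.seed(303)
  g <- irradiation_geometry()
  p <- track_model_params()
  for (E in c(5e3, 5e4, 1e6)) {
    ev <- transport_electron(c(1, 2, 3), c(1, 1, 0), E, g, p)
    expect_equal(sum(ev$energy), E, tolerance = 1e-9)
    expect_true(all(abs(ev[, c("x", "y", "z")]) <= g$L / 2 + 1e-9))
  }
  # below 2 T_cut: single local deposition of the full energy
  ev1 <- transport_electron(c(0, 0, 0), c(0, 0, 1), 2 * p$T_cut - 1, g, p)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$energy, 2 * p$T_cut - 1)
  expect_error(transport_electron(c(0, 0, 0), c(0, 0, 1), 10, g, p),
               "cutoff")
})

test_that("mean nucleus energy matches dose x mass over many histories", {
  set.seed(304)
  b <- reference_beam("He")
  g <- irradiation_geometry(); p <- track_model_params()
  e <- 0
  nh <- 1000
  for (h in seq_len(nh)) {
    o <- microca:::.kernel_run(b, 0.5, g, p, "tot")
    e <- e + o$e_dir + o$e_ind
  }
  mass_kg <- 4 / 3 * pi * (4e-6)^3 * 1000      # water sphere
  target <- 0.5 * mass_kg / 1.602176634e-19    # eV at 0.5 Gy
  expect_gt(e / nh / target, 0.97)
  expect_lt(e / nh / target, 1.03)
})
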