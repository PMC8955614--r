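test_that("spectra renormalize to the requested dose", {
  sp <- fluence_spectrum(c(1, 2), c(500, 100), c(5, 1), dose = 1)
  d <- sum(0.1602 * sp$LET_keV_um * sp$fluence_um2)
  expect_equal(d, 1, tolerance = 1e-3)
  expect_error(fluence_spectrum(1, 100, -1), "non-negative")
})

test_that("spectrum files round-trip and malformed input is rejected", {
  sp <- synth_fluence_spectrum(reference_beam("C"), dose = 1)
  f <- tempfile(fileext = ".csv")
  write_fluence_spectrum(sp, f)
  sp2 <- load_fluence_spectrum(f, dose = 1)
  expect_equal(sp2$Z, sp$Z)
  expect_equal(sp2$fluence_um2, sp$fluence_um2, tolerance = 1e-9)
  expect_equal(sp2$LET_keV_um, sp$LET_keV_um, tolerance = 1e-9)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("Z,E_MeV_per_n,fluence_um2", "1,100,0.5", "2,50,-0.1"), bad)
  expect_error(load_fluence_spectrum(bad), "negative")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(load_fluence_spectrum(bad), "columns")
})

test_that("comment lines and whitespace delimiters are tolerated", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# synthetic fixture", "Z E_MeV_per_n fluence_um2",
               "1 1000 28.4", "# trailing comment", "2 250 0.3"), f)
  sp <- load_fluence_spectrum(f, dose = 1)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$Z, c(1L, 2L))
})

test_that("synthetic spectra have the tissue-transport structure", {
  sp <- synth_fluence_spectrum(reference_beam("He"), dose = 1)
  prim <- sp$fluence_um2[sp$Z == 2 & sp$energy_MeV_n == 250]
  sec <- sp$fluence_um2[!(sp$Z == 2 & sp$energy_MeV_n == 250)]
  # primary peak one to two orders of magnitude above any secondary bin
  expect_gte(prim / max(sec), 10)
  expect_true(any(sp$Z == 1) && any(sp$Z == 2))
  # low-energy heavy fragments with LET above the primary's
  heavy <- sp[sp$Z > 2, ]
  expect_gt(nrow(heavy), 0)
  expect_gt(max(heavy$LET_keV_um), 1.56)
  expect_lt(max(heavy$energy_MeV_n), 100)
})

test_that("a single-bin spectrum reduces to the mono-energetic beam", {
  b <- reference_beam("O")
  sp <- as_fluence_spectrum(b, dose = 1)
  expect_equal(nrow(sp), 1L)
  bins_b <- microca:::.source_bins(b, 0.5)
  bins_s <- microca:::.source_bins(sp, 0.5)
  expect_equal(bins_b$phi, bins_s$phi, tolerance = 1e-12)
  expect_equal(bins_b$LET, bins_s$LET)
})

test_that("LET fallback scales as Z^2/beta^2 and honors packaged beams", {
  expect_equal(let_for_ion(1L, 1000), 0.22)
  expect_equal(let_for_ion(26L, 1000), 149.2)
  l1 <- let_for_ion(1L, 100)
  l2 <- let_for_ion(2L, 100)
  expect_equal(l2 / l1, 4, tolerance = 1e-9)
  expect_gt(let_for_ion(1L, 50), let_for_ion(1L, 500))
})
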