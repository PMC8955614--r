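mk_graph <- function(breaks, edges) {
  structure(list(edges = edges, breaks = breaks,
                 open_ends = rep(0L, nrow(breaks))),
            class = "rejoin_graph")
}

bk <- function(fibers) {
  n <- length(fibers)
  data.frame(id = seq_len(n), fiber = fibers, segment = 1L,
             x = 0, y = 0, z = 0, complex = TRUE)
}

ed <- function(a, b, type = "mis") {
  data.frame(break_a = a, break_b = b, type = type, t_h = 1)
}

test_that("exchange classification follows the 2-break/2-chromosome rule", {
  # one mis edge between chromosomes 1 and 5 -> one simple exchange
  ev <- classify_exchanges(mk_graph(bk(c(1L, 5L)), ed(1L, 2L)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$class, "simple")
  # chain of 3 breaks on 2 chromosomes -> one complex exchange
  ev2 <- classify_exchanges(mk_graph(bk(c(1L, 2L, 1L)),
                                     ed(c(1L, 2L), c(2L, 3L))))
  expect_equal(ev2$class, "complex")
  expect_equal(ev2$n_breaks, 3L)
  # proper edges only -> no exchanges
  ev3 <- classify_exchanges(mk_graph(bk(c(1L, 2L)),
                                     ed(c(1L, 2L), c(1L, 2L), "proper")))
  expect_equal(nrow(ev3), 0L)
  # single-chromosome component -> intra, excluded from both classes
  ev4 <- classify_exchanges(mk_graph(bk(c(7L, 7L)), ed(1L, 2L)))
  expect_equal(ev4$class, "intra")
})

test_that("two forced pairings on distinct chromosomes give one simple", {
  # combinatorial oracle: any mis pairing of exactly two breaks sitting on
  # two chromosomes yields simple = 1, complex = 0
  for (fibs in list(c(1L, 2L), c(3L, 40L), c(12L, 13L))) {
    ev <- classify_exchanges(mk_graph(bk(fibs), ed(1L, 2L)))
    expect_equal(sum(ev$class == "simple"), 1L)
    expect_equal(sum(ev$class == "complex"), 0L)
  }
})

test_that("each break lands in at most one exchange event", {
  set.seed(20)
  for (r in 1:20) {
    n <- 12
    br <- bk(sample(1:6, n, replace = TRUE))
    m <- matrix(sample(n, 10, replace = TRUE), ncol = 2)
    m <- m[m[, 1] != m[, 2], , drop = FALSE]
    ev <- classify_exchanges(mk_graph(br, ed(m[, 1], m[, 2])))
    expect_lte(sum(ev$n_breaks), n)
  }
})

test_that("tallies report mean and standard error over histories", {
  evs <- list(
    data.frame(event = integer(), n_breaks = integer(),
               n_chromosomes = integer(), class = character()),
    data.frame(event = integer(), n_breaks = integer(),
               n_chromosomes = integer(), class = character()),
    data.frame(event = 1L, n_breaks = 2L, n_chromosomes = 2L,
               class = "simple"),
    data.frame(event = 1L, n_breaks = 2L, n_chromosomes = 2L,
               class = "simple"))
  tal <- tally_exchanges(evs, dose = 1, contribution = "tot")
  s <- tal[tal$endpoint == "simple", ]
  expect_equal(s$mean, 0.5)
  expect_equal(s$se, sd(c(0, 0, 1, 1)) / 2, tolerance = 1e-12)
  expect_equal(round(s$se, 3), 0.289)
  z <- tally_exchanges(evs[1:2], dose = 1)
  expect_equal(z$mean, rep(0, 3))
  expect_equal(z$se, rep(0, 3))
  expect_error(tally_exchanges(evs[1]), "histories")
})

test_that("optional dicentric/translocation subtyping follows joined ends", {
  ed2 <- data.frame(break_a = 1L, break_b = 2L, type = "mis", t_h = 1,
                    end_a = 1L, end_b = 1L)
  ev <- classify_exchanges(mk_graph(bk(c(1L, 2L)), ed2), subtype = TRUE)
  expect_equal(ev$subtype, "dicentric")
  ed3 <- ed2; ed3$end_b <- 2L
  ev3 <- classify_exchanges(mk_graph(bk(c(1L, 2L)), ed3), subtype = TRUE)
  expect_equal(ev3$subtype, "translocation")
  # complex and intra events carry no subtype
  ev4 <- classify_exchanges(mk_graph(bk(c(7L, 7L)), ed2), subtype = TRUE)
  expect_true(is.na(ev4$subtype))
  # default output has no subtype column
  expect_false("subtype" %in%
                 names(classify_exchanges(mk_graph(bk(c(1L, 2L)), ed2))))
})

test_that("spectrum sidecar records metadata next to the CSV", {
  e <- c(100, 2000, 5e4)
  tot <- build_spectrum(e); dir <- build_spectrum(e[1:2], "dir")
  ind <- build_spectrum(e[3], "ind")
  f <- tempfile(fileext = ".csv")
  write_spectrum_csv(tot, dir, ind, f, meta = list(beam = "H", seed = 1))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$beam, "H")
  expect_equal(side$n_tracks$tot, 3L)
})
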