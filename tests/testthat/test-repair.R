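wide_breaks <- function(n, complex, spacing = 50) {
  # breaks so far apart that the misrepair kernel vanishes
  data.frame(id = seq_len(n), fiber = seq_len(n), segment = 1L,
             x = spacing * seq_len(n), y = 0, z = 0,
             complex = rep(complex, n))
}

test_that("simple-break survival matches exp(-t/tau) at t = tau", {
  set.seed(14)
  br <- wide_breaks(3000, complex = FALSE)
  g <- simulate_repair(br, repair_params(duration = 1.7))
  frac_open <- mean(g$open_ends == 2L)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 3000)
  expect_lt(abs(frac_open - exp(-1)), 3 * se)
  # KS check of the join-time distribution against truncated Exp(1.7 h);
  # de-discretize the 1 s step times with in-step jitter
  tj <- g$edges$t_h[g$edges$type == "proper"] - runif(n_proper <-
          sum(g$edges$type == "proper")) / 3600
  ks <- suppressWarnings(ks.test(tj, function(q)
    (1 - exp(-q / 1.7)) / (1 - exp(-1))))
  expect_gt(ks$p.value, 0.01)
})

test_that("isolated complex breaks survive as exp(-24/23.7)", {
  set.seed(15)
  br <- wide_breaks(2000, complex = TRUE)
  g <- simulate_repair(br, repair_params())
  p <- exp(-24 / 23.7)
  frac_open <- mean(g$open_ends == 2L)
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(frac_open - p), 3 * se)
  expect_equal(sum(g$edges$type == "mis"), 0L)
})

test_that("sigma_int -> 0 turns off misrepair even for co-located breaks", {
  set.seed(16)
  br <- data.frame(id = 1:40, fiber = 1:40, segment = 1L,
                   x = 0, y = 0, z = 0, complex = TRUE)
  g <- simulate_repair(br, repair_params(sigma_int = 0))
  expect_equal(sum(g$edges$type == "mis"), 0L)
})

test_that("every break end is in exactly one state", {
  set.seed(17)
  br <- data.frame(id = 1:60, fiber = rep(1:20, 3), segment = 1L,
                   x = rnorm(60, sd = 0.5), y = rnorm(60, sd = 0.5),
                   z = rnorm(60, sd = 0.5),
                   complex = rep(c(TRUE, TRUE, FALSE), 20))
  g <- simulate_repair(br, repair_params())
  n_proper <- sum(g$edges$type == "proper")
  n_mis <- sum(g$edges$type == "mis")
  expect_equal(sum(g$open_ends) + 2L * n_proper + 2L * n_mis, 2L * 60L)
  # proper edges connect a break to itself, mis edges two distinct complex
  pr <- g$edges[g$edges$type == "proper", ]
  expect_true(all(pr$break_a == pr$break_b))
  mi <- g$edges[g$edges$type == "mis", ]
  expect_true(all(mi$break_a != mi$break_b))
  expect_true(all(br$complex[c(mi$break_a, mi$break_b)]))
})

test_that("results are insensitive to dt (first-order hazard)", {
  set.seed(18)
  mis_rate <- function(dt, reps) {
    mean(vapply(seq_len(reps), function(r) {
      br <- data.frame(id = 1:10, fiber = 1:10, segment = 1L,
                       x = rnorm(10, sd = 0.4), y = rnorm(10, sd = 0.4),
                       z = rnorm(10, sd = 0.4), complex = TRUE)
      g <- simulate_repair(br, repair_params(dt = dt))
      sum(g$edges$type == "mis")
    }, numeric(1)))
  }
  m05 <- mis_rate(0.5, 150); m1 <- mis_rate(1, 150); m2 <- mis_rate(2, 150)
  expect_gt(m1, 0.3)
  expect_lt(abs(m05 - m1) / m1, 0.35)
  expect_lt(abs(m2 - m1) / m1, 0.35)
})

test_that("misrepair increases with break density", {
  set.seed(19)
  count_mis <- function(sd_um, reps = 120) {
    sum(vapply(seq_len(reps), function(r) {
      br <- data.frame(id = 1:8, fiber = 1:8, segment = 1L,
                       x = rnorm(8, sd = sd_um), y = rnorm(8, sd = sd_um),
                       z = rnorm(8, sd = sd_um), complex = TRUE)
      g <- simulate_repair(br, repair_params())
      sum(g$edges$type == "mis")
    }, numeric(1)))
  }
  dense <- count_mis(0.3)
  sparse <- count_mis(3)
  expect_gt(dense, sparse)
})
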