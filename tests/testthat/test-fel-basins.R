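test_that("histogram free energy follows Boltzmann inversion of counts", {
  # uniform counts: flat surface at zero
  set.seed(1)
  x <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  f <- estimate_fel(x, bins = list(seq(0, 1, by = 0.1)), equil_frac = 0)
  expect_true(all(abs(f$values) < 1e-12))
  # two bins with counts (100, 37): dF = -kT log(0.37)
  y <- c(rep(0.25, 100), rep(0.75, 37))
  f2 <- estimate_fel(y, bins = list(c(0, 0.5, 1)), equil_frac = 0,
                     temperature = 300)
  expect_equal(f2$values[1], 0)
  expect_equal(f2$values[2], -kB * 300 * log(0.37), tolerance = 1e-12)
  # duplicating the samples leaves the surface unchanged
  f3 <- estimate_fel(c(y, y), bins = list(c(0, 0.5, 1)), equil_frac = 0)
  expect_equal(f3$values, f2$values)
  expect_error(estimate_fel(numeric(0)), "sample")
})

test_that("empty bins are masked and excluded", {
  x <- c(rep(0.1, 5), rep(0.9, 5))
  f <- estimate_fel(x, bins = list(seq(0, 1, by = 0.2)), equil_frac = 0)
  expect_equal(sum(f$mask), 2)
  expect_true(all(is.na(f$values[!f$mask])))
})

test_that("unbiased double-well sampling reproduces the analytic profile", {
  land <- make_analytic_landscape("double_well", list(h = 5))
  tr <- run_langevin(land, x0 = 1, n_steps = 2e5, dt = 2e-4,
                     output_stride = 20, friction = 0.2, seed = 8)
  edges <- seq(-1.6, 1.6, length.out = 25)
  f <- estimate_fel(tr[, 1], bins = list(edges), equil_frac = 0.1,
                    min_count = 10)
  beta <- 1 / (kB * 300)
  pb <- vapply(seq_len(length(edges) - 1), function(i)
    integrate(function(u) exp(-beta * land$energy(matrix(u))),
              edges[i], edges[i + 1])$value, numeric(1))
  fa <- -log(pb / max(pb)) / beta
  sup <- f$mask
  rms <- sqrt(mean(((f$values - min(f$values[sup])) -
                      (fa - min(fa[sup])))[sup]^2))
  expect_lt(rms, 0.5 * kB * 300)
})

test_that("FEL RMS difference aligns minima and needs matching bins", {
  x <- rnorm(500)
  f1 <- estimate_fel(x, bins = list(seq(-3, 3, by = 0.5)), equil_frac = 0)
  expect_equal(fel_rms_difference(f1, f1), 0)
  f2 <- f1
  f2$values <- f2$values + 3.7   # constant offset: identical after alignment
  expect_equal(fel_rms_difference(f1, f2), 0)
  f3 <- estimate_fel(x, bins = list(seq(-3, 3, by = 1)), equil_frac = 0)
  expect_error(fel_rms_difference(f1, f3), "mismatch")
})

test_that("independent run halves give closely matching surfaces", {
  land <- make_analytic_landscape("double_well", list(h = 5))
  tr <- run_langevin(land, x0 = 1, n_steps = 2e5, dt = 2e-4,
                     output_stride = 20, friction = 0.2, seed = 21)
  x <- tr[, 1]
  n <- length(x)
  edges <- list(seq(-1.6, 1.6, length.out = 17))
  fa <- estimate_fel(x[1:(n / 2)], bins = edges, equil_frac = 0,
                     min_count = 5)
  fb <- estimate_fel(x[(n / 2 + 1):n], bins = edges, equil_frac = 0,
                     min_count = 5)
  expect_lt(fel_rms_difference(fa, fb), 0.5 * kB * 300)
})

test_that("basin identification: bowls, wells, merging and shift invariance", {
  # single-minimum bowl
  g <- seq(-1, 1, length.out = 20)   # even count: symmetric about zero
  bowl <- fel("x", list(seq(-1.05, 1.05, length.out = 21)), g^2 * 10)
  expect_equal(identify_basins(bowl)$n_basins, 1)
  # symmetric double well, barrier 6 kJ/mol > 1 kT
  dwv <- 6 * (g^2 - 0.49)^2 / 0.2401
  dw <- fel("x", list(seq(-1.05, 1.05, length.out = 21)), dwv)
  ba <- identify_basins(dw, min_barrier = kB * 300)
  expect_equal(ba$n_basins, 2)
  expect_equal(sum(ba$labels == 1, na.rm = TRUE),
               sum(ba$labels == 2, na.rm = TRUE))
  # same wells, barrier below the merge threshold: single basin
  ba2 <- identify_basins(dw, min_barrier = 7)
  expect_equal(ba2$n_basins, 1)
  # adding a constant changes nothing
  dw_shift <- dw; dw_shift$values <- dw_shift$values + 5
  ba3 <- identify_basins(dw_shift, min_barrier = kB * 300)
  expect_equal(ba3$labels, ba$labels)
  # basins numbered by ascending minimum value
  tilt <- dwv + 0.5 * g
  ft <- fel("x", list(seq(-1.05, 1.05, length.out = 21)), tilt)
  bt <- identify_basins(ft, min_barrier = kB * 300)
  expect_lt(bt$minima$value[1], bt$minima$value[2])
})

test_that("frames are assigned to basins through their bins", {
  g <- seq(-1, 1, length.out = 21)
  dwv <- 6 * (g^2 - 0.49)^2 / 0.2401
  dw <- fel("x", list(seq(-1.05, 1.05, length.out = 22)), dwv)
  ba <- identify_basins(dw, min_barrier = kB * 300)
  lab_minus <- assign_frames(-0.7, ba)
  lab_plus <- assign_frames(0.7, ba)
  expect_true(lab_minus != lab_plus)
  expect_true(is.na(assign_frames(3.0, ba)))
  # frames drawn inside known basin boxes get the right label
  set.seed(4)
  xs <- c(runif(50, -0.8, -0.6), runif(50, 0.6, 0.8))
  labs <- assign_frames(xs, ba)
  expect_equal(labs, rep(c(lab_minus, lab_plus), each = 50))
})

test_that("basin populations recover planted mixture weights", {
  set.seed(6)
  w <- 0.7
  n <- 2000
  comp <- stats::rbinom(n, 1, 1 - w)
  x <- ifelse(comp == 0, rnorm(n, -1, 0.18), rnorm(n, 1, 0.18))
  f <- estimate_fel(x, bins = 24, equil_frac = 0, min_count = 3)
  ba <- identify_basins(f, min_barrier = kB * 300)
  expect_equal(ba$n_basins, 2)
  labs <- assign_frames(x, ba)
  p1 <- mean(labs == ba$labels[which.min(abs(f$centers[[1]] + 1))],
             na.rm = TRUE)
  expect_lt(abs(p1 - w), 3 * sqrt(w * (1 - w) / n) + 0.02)
})
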