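test_that("overdamped step: fixed point at zero force and geometric contraction", {
  set.seed(1)
  expect_equal(langevin_step(c(1, 2), c(0, 0), dt = 0.01, temperature = 0),
               c(1, 2))
  # harmonic force F = -k x at T = 0 contracts by (1 - k dt / gamma)
  k <- 5; dt <- 0.01; gamma <- 1
  x <- 1
  for (i in 1:50) x <- langevin_step(x, -k * x, dt, temperature = 0,
                                     friction = gamma)
  expect_equal(x, (1 - k * dt / gamma)^50, tolerance = 1e-12)
  expect_error(langevin_step(1, NaN, 0.01), "non-finite")
  expect_error(langevin_step(1, 0, -0.1), "dt")
})

test_that("harmonic sampling satisfies equipartition", {
  # the y coordinate of the two-basin landscape is harmonic with ky = 10
  land <- make_analytic_landscape("two_basin_2d", list(h = 5, ky = 10))
  tr <- run_langevin(land, x0 = c(1, 0), n_steps = 2e5, dt = 5e-4,
                     output_stride = 10, seed = 2)
  expect_equal(var(tr[, 2]), kB * 300 / 10, tolerance = 0.05)
})

test_that("exchange with empty biases is always accepted; planted bias follows Metropolis", {
  ra <- replica_state(c(0, 0))
  rb <- replica_state(c(1, 1))
  out <- attempt_exchange(ra, rb, t = 1)
  expect_true(out$accepted)
  expect_equal(out$replica_a$coordinates, c(1, 1))
  expect_equal(out$replica_b$coordinates, c(0, 0))
  expect_equal(nrow(out$replica_a$exchange_log), 1)
  rc <- replica_state(0, temperature = 350)
  expect_error(attempt_exchange(ra, rc), "temperature")
})

test_that("empirical exchange acceptance matches exp(delta/kT) for a planted delta", {
  kT <- kB * 300
  b <- gaussian_bias(cv_id = "x", sigma = 1, height = kT, tau_g = 1)
  b <- deposit_kernel(b, 0, t = 0)
  # replica a biased on x with a kernel at 0; its walker sits far away, the
  # partner's walker sits at the kernel: delta = -kT exactly
  ra <- replica_state(50, bias = b, cv_fun = function(x) x)
  rb <- replica_state(0)
  expect_equal(attempt_exchange(ra, rb)$delta, -kT)
  set.seed(99)
  n <- 1e4
  acc <- logical(n)
  for (i in seq_len(n)) acc[i] <- attempt_exchange(ra, rb)$accepted
  p <- exp(-1)
  expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("run_bemd validates schedules and is deterministic", {
  land <- make_analytic_landscape("two_basin_2d")
  sched <- list(dt = 1e-4, tau_g = 0.05, exchange_stride = 0.01,
                total_time = 1, output_stride = 50)
  expect_error(run_bemd(land, cv_dims = 1, n_neutral = 0, sched),
               "replica")
  expect_error(run_bemd(land, cv_dims = 3, n_neutral = 1, sched),
               "dimension")
  expect_error(run_bemd(land, cv_dims = 1, n_neutral = 1,
                        utils::modifyList(sched, list(tau_g = 0.000033))),
               "multiple of dt")
  b1 <- run_bemd(land, cv_dims = c(1, 2), n_neutral = 1, sched, seed = 7)
  b2 <- run_bemd(land, cv_dims = c(1, 2), n_neutral = 1, sched, seed = 7)
  expect_identical(b1$traces, b2$traces)
  expect_identical(b1$exchange_log, b2$exchange_log)
  # zero total time: no stepping, no exchanges
  b0 <- run_bemd(land, cv_dims = 1, n_neutral = 1,
                 utils::modifyList(sched, list(total_time = 0)), seed = 1)
  expect_equal(nrow(b0$traces[[1]]), 0)
  expect_equal(nrow(b0$exchange_log), 0)
  # exchange stride beyond the run: zero attempts logged
  b3 <- run_bemd(land, cv_dims = 1, n_neutral = 1,
                 utils::modifyList(sched, list(exchange_stride = 5)),
                 seed = 1)
  expect_equal(nrow(b3$exchange_log), 0)
})

test_that("accumulated bias is non-negative and non-decreasing in time", {
  land <- make_analytic_landscape("double_well")
  r <- run_metad(land, max_time = 5, average_time = 0, seed = 3)
  grid <- seq(-2, 2, length.out = 81)
  ts <- seq(0.5, 5, by = 0.5)
  prev <- rep(0, length(grid))
  for (tt in ts) {
    v <- bias_energy(r$bias, grid, t = tt)
    expect_true(all(v >= 0))
    expect_true(all(v - prev >= -1e-12))
    prev <- v
  }
})

test_that("metadynamics recovers the double-well barrier", {
  land <- make_analytic_landscape("double_well", list(h = 5))
  grid <- seq(-1.5, 1.5, length.out = 301)
  r <- run_metad(land, seed = 1)
  expect_true(r$flat)
  f <- metad_fel_average(r$bias, grid)
  expect_lt(abs(fel_barrier_height(f) - 5), 1)
})
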