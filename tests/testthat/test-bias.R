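test_that("bias energy sums Gaussian kernels deposited up to t", {
  b <- gaussian_bias(cv_id = "q", sigma = 0.5, height = 1, tau_g = 1)
  expect_equal(bias_energy(b, 0.3), 0)
  b <- deposit_kernel(b, current_cv = 2, t = 0)
  expect_equal(bias_energy(b, 2), 1)
  expect_equal(bias_energy(b, 2.5), exp(-0.5), tolerance = 1e-12)
  # kernels in the future do not count
  b <- deposit_kernel(b, current_cv = 2, t = 5)
  expect_equal(bias_energy(b, 2, t = 1), 1)
  expect_equal(bias_energy(b, 2, t = 5), 2)
})

test_that("deposits respect the stride and grow the bias pointwise", {
  b <- gaussian_bias(sigma = 0.5, height = 0.3, tau_g = 1)
  b <- deposit_kernel(b, 1, t = 0)
  expect_error(deposit_kernel(b, 1, t = 0.5), "out-of-order")
  s_grid <- seq(-3, 3, by = 0.1)
  v1 <- bias_energy(b, s_grid)
  b <- deposit_kernel(b, -1, t = 1)
  v2 <- bias_energy(b, s_grid)
  expect_true(all(v2 >= v1))
  expect_true(all(v1 >= 0))
  expect_equal(nrow(b$kernels), 2)
  # alternating centers at +-1, sigma 0.5: value at 0 is the 2-kernel sum
  expect_equal(bias_energy(b, 0), 2 * 0.3 * exp(-1 / (2 * 0.25)),
               tolerance = 1e-12)
  # deposit at a point raises the bias there by exactly the height
  v0 <- bias_energy(b, 0.7)
  b <- deposit_kernel(b, 0.7, t = 2)
  expect_equal(bias_energy(b, 0.7), v0 + 0.3, tolerance = 1e-12)
})

test_that("free-energy readout inverts and shifts the bias", {
  b <- gaussian_bias(sigma = 0.4, height = 2, tau_g = 1)
  grid <- seq(-3, 3, length.out = 121)
  f0 <- bias_to_free_energy(b, grid)
  expect_true(all(f0$values == 0))
  b <- deposit_kernel(b, 0, t = 0)
  f <- bias_to_free_energy(b, grid)
  # F(center) = 0 after the shift; far field sits at the kernel height
  expect_equal(f$values[which.min(abs(grid))], 0)
  expect_equal(f$values[1], 2, tolerance = 1e-5)
  expect_error(bias_to_free_energy(b, numeric(0)), "empty")
  expect_error(bias_to_free_energy(b, c(1, 0)), "sorted")
})

test_that("analytic landscapes expose closed-form energies and exact gradients", {
  dw <- make_analytic_landscape("double_well", list(h = 5))
  expect_equal(dw$energy(matrix(c(-1, 1), 2, 1)), c(0, 0))
  expect_equal(dw$energy(matrix(0)), 5)
  tb <- make_analytic_landscape("two_basin_2d")
  expect_equal(unname(tb$minima), matrix(c(-1, 0, 1, 0), 2, 2,
                                         byrow = TRUE))
  expect_equal(tb$energy(tb$minima), c(0, 0))
  mb <- make_analytic_landscape("multi_basin_2d")
  expect_error(make_analytic_landscape("bogus"))
  # gradient vs central finite differences, and R vs compiled evaluation
  set.seed(1)
  for (land in list(dw, tb, mb)) {
    X <- matrix(runif(100 * land$dimension, -2, 2), 100)
    G <- land$gradient(X)
    h <- 1e-5
    for (j in seq_len(land$dimension)) {
      Xp <- X; Xp[, j] <- Xp[, j] + h
      Xm <- X; Xm[, j] <- Xm[, j] - h
      fd <- (land$energy(Xp) - land$energy(Xm)) / (2 * h)
      expect_equal(G[, j], fd, tolerance = 1e-6)
    }
    expect_equal(land$energy(X),
                 quadfold:::landscape_energy_cpp(land$id, land$par, X),
                 tolerance = 1e-12)
    expect_equal(unname(G),
                 unname(quadfold:::landscape_gradient_cpp(land$id,
                                                          land$par, X)),
                 tolerance = 1e-12)
  }
})
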