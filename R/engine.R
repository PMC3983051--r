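#' One overdamped Langevin step
#'
#' Euler-Maruyama update `x' = x + (dt/gamma) F + sqrt(2 kB T dt/gamma) xi`
#' with `xi` standard normal per dimension. Velocities are not propagated:
#' the toy dynamics is overdamped throughout.
#'
#' @param coordinates current position (numeric vector).
#' @param force total force `-grad(U + V_G)` at the current position,
#'   kJ/mol/nm.
#' @param dt time step, ns.
#' @param temperature K.
#' @param friction friction coefficient gamma, kJ/mol ns / nm^2.
#' @return the new coordinate vector. Uses R's RNG (seed with `set.seed`).
#' @export
langevin_step <- function(coordinates, force, dt, temperature = 300,
                          friction = 1) {
  if (dt <= 0) stopf("dt must be positive")
  if (friction <= 0) stopf("friction must be positive")
  if (!all(is.finite(force))) stopf("non-finite force")
  coordinates + (dt / friction) * force +
    sqrt(2 * kB * temperature * dt / friction) * rnorm(length(coordinates))
}

#' Unbiased Langevin trajectory on an analytic landscape
#'
#' @param landscape a [make_analytic_landscape()] object.
#' @param x0 starting point.
#' @param n_steps number of steps.
#' @param dt time step, ns.
#' @param output_stride record every this many steps.
#' @param temperature,friction see [langevin_step()].
#' @param seed RNG seed (required for reproducibility).
#' @return matrix of sampled positions (`n_steps / output_stride` rows).
#' @export
run_langevin <- function(landscape, x0 = NULL, n_steps = 1e5, dt = 1e-3,
                         output_stride = 10, temperature = 300, friction = 1,
                         seed = NULL) {
  if (is.null(x0)) x0 <- landscape$minima[1, ]
  if (length(x0) != landscape$dimension) stopf("x0 has wrong dimension")
  with_seed(seed,
    run_langevin_cpp(landscape$id, landscape$par, as.numeric(x0), dt,
                     as.integer(n_steps), as.integer(output_stride),
                     temperature, friction))
}

#' 1D metadynamics with a flatness stopping rule
#'
#' Runs overdamped Langevin dynamics on a 1D landscape while depositing
#' repulsive Gaussians every `tau_g`, until the bias grows uniformly over the
#' region of interest: every `check_time` the growth of the bias over the
#' window is compared to a uniform rise, and deposition stops once the
#' relative RMS deviation falls below `flat_tol` for `n_consec` consecutive
#' windows (or at `max_time`).
#'
#' @param landscape 1D [make_analytic_landscape()].
#' @param x0 starting position (default the first minimum).
#' @param sigma Gaussian width (nm or CV units).
#' @param height Gaussian height, kJ/mol.
#' @param tau_g deposition stride, ns.
#' @param dt integration step, ns.
#' @param max_time hard cap on simulated time, ns.
#' @param temperature,friction see [langevin_step()].
#' @param flat_region range over which flatness is assessed (default the
#'   inter-minima region padded to the barrier).
#' @param check_time window length for the flatness test, ns.
#' @param flat_tol relative RMS threshold (default 0.2).
#' @param n_consec consecutive flat windows required (default 2).
#' @param average_time additional deposition time after the flatness rule
#'   fires, ns; the free-energy readout averages the instantaneous estimate
#'   over this window (see [metad_fel_average()]).
#' @param output_stride trace recording stride, steps.
#' @param seed RNG seed.
#' @return list with `bias` (a [gaussian_bias()] holding all kernels),
#'   `trace`, `n_steps`, `flat` (whether the stopping rule fired).
#' @export
run_metad <- function(landscape, x0 = NULL, sigma = 0.1, height = 0.1,
                      tau_g = 0.05, dt = 1e-4, max_time = 1000,
                      temperature = 300, friction = 1,
                      flat_region = c(-1.3, 1.3), check_time = 20,
                      flat_tol = 0.2, n_consec = 2, average_time = 300,
                      output_stride = 100, seed = NULL) {
  if (landscape$dimension != 1) stopf("run_metad needs a 1D landscape")
  if (is.null(x0)) x0 <- landscape$minima[1, 1]
  tau_steps <- stride_steps(tau_g, dt, "tau_g")
  check_steps <- stride_steps(check_time, dt, "check_time")
  max_steps <- stride_steps(max_time, dt, "max_time")
  extra_steps <- stride_steps(average_time, dt, "average_time")
  res <- with_seed(seed,
    run_metad_cpp(landscape$id, landscape$par, x0, dt, tau_steps, max_steps,
                  as.integer(output_stride), sigma, height, temperature,
                  friction, landscape$range[1, 1], landscape$range[2, 1],
                  2001L, check_steps, flat_tol, flat_region[1],
                  flat_region[2], as.integer(n_consec), extra_steps))
  bias <- bias_from_kernels(res$centers, res$times, sigma, height,
                            cv_id = "x", tau_g = tau_g)
  list(bias = bias, trace = res$trace, n_steps = res$n_steps,
       flat = res$flat, dt = dt, output_stride = output_stride)
}

stride_steps <- function(time, dt, what) {
  k <- time / dt
  if (abs(k - round(k)) > 1e-6) stopf("%s must be a multiple of dt", what)
  k <- as.integer(round(k))
  if (k < 0) stopf("%s must be non-negative", what)
  k
}

#' Replica state for bias exchange
#'
#' @param coordinates current position in the dynamics space.
#' @param bias the replica's [gaussian_bias()] (empty for a neutral replica).
#' @param temperature K.
#' @param cv_fun function mapping coordinates to this replica's biased CV
#'   value; `NULL` for a neutral replica.
#' @return object of class `g4_replica` with an empty `exchange_log`.
#' @export
replica_state <- function(coordinates, bias = gaussian_bias(),
                          temperature = 300, cv_fun = NULL) {
  if (temperature <= 0) stopf("temperature must be positive")
  structure(list(coordinates = as.numeric(coordinates), bias = bias,
                 temperature = temperature, cv_fun = cv_fun,
                 exchange_log = data.frame(time = numeric(0),
                                           partner = integer(0),
                                           accepted = logical(0))),
            class = "g4_replica")
}

replica_bias_at <- function(replica, coordinates) {
  if (is.null(replica$cv_fun) || nrow(replica$bias$kernels) == 0) return(0)
  bias_energy(replica$bias, replica$cv_fun(coordinates))
}

#' Attempt a bias exchange between two replicas
#'
#' Metropolis-like criterion on the walkers' bias energies: the swap of
#' coordinates between replicas a and b is accepted with probability
#' `min(1, exp((Va(xa) + Vb(xb) - Va(xb) - Vb(xa)) / kB T))`, where `Va(xb)`
#' is replica a's accumulated bias evaluated at its own CV computed on b's
#' coordinates. On acceptance the coordinates swap while each bias stays
#' with its replica; both exchange logs are appended either way. Two
#' bias-free (neutral) replicas therefore always exchange.
#'
#' @param replica_a,replica_b [replica_state()] objects at the same
#'   temperature.
#' @param t attempt time, ns (logged).
#' @param partner_ids optional integer ids logged as partners (default 2 and
#'   1).
#' @return list with updated `replica_a`, `replica_b`, `accepted`, `delta`
#'   (the log-acceptance argument, kJ/mol scaled by 1/kBT already applied to
#'   the probability, reported in kJ/mol).
#' @export
attempt_exchange <- function(replica_a, replica_b, t = 0,
                             partner_ids = c(2L, 1L)) {
  if (replica_a$temperature != replica_b$temperature)
    stopf("replicas must be at the same temperature for exchange")
  kT <- kB * replica_a$temperature
  delta <- replica_bias_at(replica_a, replica_a$coordinates) +
    replica_bias_at(replica_b, replica_b$coordinates) -
    replica_bias_at(replica_a, replica_b$coordinates) -
    replica_bias_at(replica_b, replica_a$coordinates)
  p <- min(1, exp(delta / kT))
  accepted <- if (p >= 1) TRUE else runif(1) < p
  if (accepted) {
    tmp <- replica_a$coordinates
    replica_a$coordinates <- replica_b$coordinates
    replica_b$coordinates <- tmp
  }
  replica_a$exchange_log <- rbind(replica_a$exchange_log,
    data.frame(time = t, partner = partner_ids[1], accepted = accepted))
  replica_b$exchange_log <- rbind(replica_b$exchange_log,
    data.frame(time = t, partner = partner_ids[2], accepted = accepted))
  list(replica_a = replica_a, replica_b = replica_b, accepted = accepted,
       delta = delta)
}

#' Run bias-exchange metadynamics on an analytic landscape
#'
#' Several replicas evolve under overdamped Langevin dynamics on the same
#' landscape; each biased replica deposits Gaussians along its own CV (a
#' coordinate projection on these toy landscapes) while neutral replicas
#' carry no bias and sample the corrected ensemble. At every exchange time a
#' uniformly chosen replica pair attempts a coordinate swap under the
#' Metropolis-like criterion of [attempt_exchange()].
#'
#' @param landscape a [make_analytic_landscape()].
#' @param cv_dims integer vector: the coordinate each biased replica biases
#'   (one entry per biased replica; values in `1:dimension`).
#' @param n_neutral number of unbiased replicas (>= 1).
#' @param schedule list with `dt`, `tau_g`, `exchange_stride`, `total_time`,
#'   `output_stride` (all ns except `output_stride`, in steps).
#' @param widths Gaussian width per biased replica (recycled).
#' @param height Gaussian height, kJ/mol.
#' @param temperature,friction see [langevin_step()].
#' @param x0 optional matrix of starting points (replicas x dimension);
#'   default: all replicas at the first landscape minimum except the last
#'   neutral one, which starts at the last minimum (an "unfolded" start).
#' @param seed RNG seed; runs are bit-reproducible given the seed.
#' @return object of class `g4_bemd`: `traces` (list of position matrices
#'   with a `times` attribute), `biases` (list of [gaussian_bias()]),
#'   `exchange_log` (data.frame time, a, b, accepted), `roles`, `schedule`.
#' @export
run_bemd <- function(landscape, cv_dims = 1L, n_neutral = 1L,
                     schedule = list(dt = 1e-4, tau_g = 0.05,
                                     exchange_stride = 0.01, total_time = 10,
                                     output_stride = 100),
                     widths = 0.1, height = 0.2, temperature = 300,
                     friction = 1, x0 = NULL, seed = NULL) {
  n_biased <- length(cv_dims)
  if (n_biased < 1 || n_neutral < 1)
    stopf("need at least 1 biased and 1 neutral replica")
  if (any(cv_dims < 1 | cv_dims > landscape$dimension))
    stopf("cv_dims outside the landscape dimension")
  s <- utils::modifyList(list(dt = 1e-4, tau_g = 0.05, exchange_stride = 0.01,
                              total_time = 10, output_stride = 100), schedule)
  if (s$dt <= 0) stopf("invalid schedule: dt must be positive")
  if (s$total_time < 0) stopf("invalid schedule: negative total_time")
  tau_steps <- stride_steps(s$tau_g, s$dt, "tau_g")
  exch_steps <- stride_steps(s$exchange_stride, s$dt, "exchange_stride")
  total_steps <- stride_steps(s$total_time, s$dt, "total_time")
  if (tau_steps == 0 || exch_steps == 0)
    stopf("invalid schedule: zero stride")
  nrep <- n_biased + n_neutral
  d <- landscape$dimension
  if (is.null(x0)) {
    x0 <- matrix(rep(landscape$minima[1, ], each = nrep), nrep, d)
    x0[nrep, ] <- landscape$minima[nrow(landscape$minima), ]
  }
  x0 <- as.matrix(x0)
  if (nrow(x0) != nrep || ncol(x0) != d) stopf("x0 must be %d x %d", nrep, d)
  widths <- rep_len(widths, n_biased)
  bias_dim <- c(cv_dims - 1L, rep(-1L, n_neutral))
  sig <- c(widths, rep(0.1, n_neutral))
  glo <- ghi <- numeric(nrep)
  for (r in seq_len(nrep)) {
    dd <- if (bias_dim[r] >= 0) bias_dim[r] + 1L else 1L
    glo[r] <- landscape$range[1, dd]; ghi[r] <- landscape$range[2, dd]
  }
  res <- with_seed(seed,
    run_bemd_cpp(landscape$id, landscape$par, x0, as.integer(bias_dim), sig,
                 height, s$dt, tau_steps, exch_steps, total_steps,
                 as.integer(s$output_stride), temperature, friction,
                 glo, ghi, 2001L))
  times <- seq_len(total_steps %/% s$output_stride) * s$dt * s$output_stride
  traces <- lapply(res$traces, function(m) { attr(m, "times") <- times; m })
  biases <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    if (bias_dim[r] >= 0) {
      biases[[r]] <- bias_from_kernels(res$kernels[[r]]$centers,
                                       res$kernels[[r]]$times, sig[r], height,
                                       cv_id = sprintf("x%d", bias_dim[r] + 1),
                                       tau_g = s$tau_g)
    } else biases[[r]] <- gaussian_bias(tau_g = s$tau_g)
  }
  ex <- as.data.frame(res$exchange)
  ex$accepted <- as.logical(ex$accepted)
  structure(list(traces = traces, biases = biases, exchange_log = ex,
                 roles = c(rep("biased", n_biased), rep("neutral", n_neutral)),
                 schedule = s, landscape = landscape$name,
                 temperature = temperature),
            class = "g4_bemd")
}

#' @export
print.g4_bemd <- function(x, ...) {
  cat(sprintf("g4_bemd: %d replicas (%d biased, %d neutral), %d exchange attempts (%.1f%% accepted)\n",
              length(x$traces), sum(x$roles == "biased"),
              sum(x$roles == "neutral"), nrow(x$exchange_log),
              100 * mean(x$exchange_log$accepted)))
  invisible(x)
}

#' Time-averaged free-energy profile from a metadynamics bias
#'
#' The instantaneous estimate `F(s) = -V_G(s, t)` fluctuates by roughly one
#' hill height around the converged profile; averaging the estimate over the
#' late part of the deposition history removes most of that ripple. Profiles
#' are aligned (min 0) before averaging.
#'
#' @param bias a [gaussian_bias()] with deposited kernels.
#' @param grid sorted CV grid.
#' @param window fraction of the deposition history to average over, taken
#'   from the end (default the last half).
#' @param n_snapshots number of evenly spaced snapshot times in the window.
#' @return a 1D [fel()] object over `grid`.
#' @export
metad_fel_average <- function(bias, grid, window = 0.5, n_snapshots = 20) {
  k <- bias$kernels
  if (nrow(k) == 0) return(bias_to_free_energy(bias, grid))
  tend <- max(k$time)
  ts <- seq((1 - window) * tend, tend, length.out = n_snapshots)
  acc <- rep(0, length(grid))
  for (tt in ts) {
    f <- bias_to_free_energy(bias, grid, tt)
    acc <- acc + f$values
  }
  fel_1d(grid, acc / n_snapshots - min(acc / n_snapshots),
         axis = bias$cv_id)
}

#' Barrier height of a 1D free-energy profile
#'
#' Free energy at the barrier position minus the mean free energy at the
#' stated minima positions. Evaluating the wells at their known positions
#' (rather than minimising over a window) keeps the estimate unbiased in the
#' presence of the hill-scale ripple of a metadynamics profile.
#'
#' @param fel 1D [fel()] object.
#' @param barrier_at CV value of the barrier top (default 0).
#' @param minima CV values of the well minima (default `c(-1, 1)`).
#' @export
fel_barrier_height <- function(fel, barrier_at = 0, minima = c(-1, 1)) {
  g <- fel$centers[[1]]
  fb <- fel$values[which.min(abs(g - barrier_at))]
  fw <- mean(vapply(minima, function(w)
    fel$values[which.min(abs(g - w))], numeric(1)))
  fb - fw
}
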