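#' Metadynamics Gaussian bias
#'
#' Container for the history-dependent bias potential `V_G(s, t)`: an ordered
#' list of deposited Gaussian kernels, each with a centre in CV space, a
#' width sigma, a height w (kJ/mol) and its deposition time (ns), plus the
#' deposition stride `tau_g`.
#'
#' @param cv_id name of the CV this bias acts on (or `NA` for a neutral
#'   replica's empty bias).
#' @param sigma default Gaussian width (CV units).
#' @param height default Gaussian height, kJ/mol.
#' @param tau_g deposition stride, ns.
#' @return object of class `g4_bias` with an empty kernel table.
#' @export
gaussian_bias <- function(cv_id = NA_character_, sigma = 0.1, height = 0.2,
                          tau_g = 0.05) {
  if (sigma <= 0) stopf("sigma must be positive")
  if (height < 0) stopf("height must be non-negative")
  if (tau_g <= 0) stopf("tau_g must be positive")
  structure(list(cv_id = cv_id,
                 kernels = data.frame(center = numeric(0), sigma = numeric(0),
                                      height = numeric(0), time = numeric(0)),
                 sigma = sigma, height = height, tau_g = tau_g),
            class = "g4_bias")
}

#' @export
print.g4_bias <- function(x, ...) {
  cat(sprintf("g4_bias on '%s': %d kernels (sigma = %g, height = %g kJ/mol, tau_g = %g ns)\n",
              x$cv_id, nrow(x$kernels), x$sigma, x$height, x$tau_g))
  invisible(x)
}

#' Evaluate the accumulated bias potential
#'
#' Sum over all kernels deposited up to time `t` of
#' `w * exp(-(s - center)^2 / (2 sigma^2))`; zero when no kernels qualify.
#'
#' @param bias a [gaussian_bias()].
#' @param s CV value(s) at which to evaluate.
#' @param t time in ns (default `Inf`, i.e. all kernels).
#' @return bias energy in kJ/mol (vectorised over `s`).
#' @export
bias_energy <- function(bias, s, t = Inf) {
  k <- bias$kernels
  k <- k[k$time <= t, , drop = FALSE]
  if (nrow(k) == 0) return(rep(0, length(s)))
  v <- vapply(s, function(si)
    sum(k$height * exp(-(si - k$center)^2 / (2 * k$sigma^2))), numeric(1))
  v
}

#' Deposit a Gaussian kernel
#'
#' Appends one repulsive kernel at the current CV value. Deposit times must
#' be non-decreasing and respect the stride (`t >= last + tau_g`, up to a
#' small numerical slack); the scheduler in the engine enforces the stride,
#' this checks it.
#'
#' @param bias a [gaussian_bias()].
#' @param current_cv CV value at which to centre the kernel.
#' @param t deposition time, ns.
#' @param sigma,height optional per-kernel overrides.
#' @return the updated bias.
#' @export
deposit_kernel <- function(bias, current_cv, t, sigma = bias$sigma,
                           height = bias$height) {
  k <- bias$kernels
  if (nrow(k) > 0 && t < k$time[nrow(k)] + bias$tau_g - 1e-9)
    stopf("out-of-order deposit: t = %g before last + tau_g = %g",
          t, k$time[nrow(k)] + bias$tau_g)
  bias$kernels <- rbind(k, data.frame(center = current_cv, sigma = sigma,
                                      height = height, time = t))
  bias
}

#' Free-energy estimate from an accumulated bias
#'
#' The central metadynamics identity: after sufficiently long deposition the
#' accumulated bias compensates the underlying free energy, so
#' `F(s) = -V_G(s, t_final)`, reported shifted so that the minimum over the
#' grid is zero.
#'
#' @param bias a [gaussian_bias()].
#' @param grid sorted numeric vector of CV values.
#' @param t_final time up to which kernels count (default all).
#' @return a 1D [fel()] object over `grid`.
#' @export
bias_to_free_energy <- function(bias, grid, t_final = Inf) {
  if (length(grid) == 0) stopf("empty grid")
  if (is.unsorted(grid)) stopf("grid must be sorted")
  v <- bias_energy(bias, grid, t_final)
  f <- -v
  f <- f - min(f)
  fel_1d(grid, f, axis = if (is.na(bias$cv_id)) "s" else bias$cv_id)
}

# rebuild a g4_bias from an engine kernel record (equal sigma/height)
bias_from_kernels <- function(centers, times, sigma, height, cv_id = "s",
                              tau_g = 0.05) {
  b <- gaussian_bias(cv_id = cv_id, sigma = sigma, height = height,
                     tau_g = tau_g)
  n <- length(centers)
  b$kernels <- data.frame(center = as.numeric(centers),
                          sigma = rep_len(sigma, n),
                          height = rep_len(height, n),
                          time = as.numeric(times))
  b
}
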