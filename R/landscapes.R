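#' Analytic test landscapes
#'
#' Closed-form potential-energy surfaces used as stand-ins for the molecular
#' system when exercising the sampling engine. Each landscape carries its
#' energy `U(x)` (kJ/mol), analytic gradient, documented minima and a
#' recommended coordinate range.
#'
#' Available landscapes:
#' * `double_well` (1D): `U(x) = h (x^2 - 1)^2`; minima at x = -1, +1 with
#'   U = 0 and a barrier of height `h` at x = 0. Params: `h` (kJ/mol,
#'   default 5).
#' * `two_basin_2d`: `U(x, y) = h (x^2 - 1)^2 + ky/2 y^2`; minima at
#'   (-1, 0) and (1, 0). Params: `h` (default 5), `ky` (default 10).
#' * `multi_basin_2d`: harmonic confinement plus Gaussian wells,
#'   `U = kconf/2 (x^2 + y^2) - sum_i A_i exp(-((x-xi)^2+(y-yi)^2)/(2 wi^2))`.
#'   Params: `kconf` (default 2) and `wells`, a matrix with columns
#'   `A, x, y, w` (default three wells at (-1,0), (1,0), (0,1.2)).
#'
#' @param name landscape name.
#' @param params named list overriding the documented defaults.
#' @return object of class `g4_landscape` with elements `name`, `dimension`,
#'   `energy` (function of a coordinate vector or row matrix), `gradient`,
#'   `minima` (matrix of documented minimum positions), `range`
#'   (2 x dimension matrix), and internal engine ids.
#' @export
make_analytic_landscape <- function(name = c("double_well", "two_basin_2d",
                                             "multi_basin_2d"),
                                    params = list()) {
  name <- match.arg(name)
  if (name == "double_well") {
    p <- utils::modifyList(list(h = 5), params)
    if (p$h <= 0) stopf("barrier height h must be positive")
    obj <- list(
      name = name, dimension = 1L, id = 1L, par = c(p$h), params = p,
      energy = function(x) {
        x <- as.matrix(x); p$h * (x[, 1]^2 - 1)^2
      },
      gradient = function(x) {
        x <- as.matrix(x); cbind(4 * p$h * x[, 1] * (x[, 1]^2 - 1))
      },
      minima = matrix(c(-1, 1), ncol = 1),
      range = matrix(c(-2.5, 2.5), nrow = 2))
  } else if (name == "two_basin_2d") {
    p <- utils::modifyList(list(h = 5, ky = 10), params)
    if (p$h <= 0 || p$ky <= 0) stopf("h and ky must be positive")
    obj <- list(
      name = name, dimension = 2L, id = 2L, par = c(p$h, p$ky), params = p,
      energy = function(x) {
        x <- as.matrix(x)
        p$h * (x[, 1]^2 - 1)^2 + 0.5 * p$ky * x[, 2]^2
      },
      gradient = function(x) {
        x <- as.matrix(x)
        cbind(4 * p$h * x[, 1] * (x[, 1]^2 - 1), p$ky * x[, 2])
      },
      minima = matrix(c(-1, 0, 1, 0), ncol = 2, byrow = TRUE),
      range = matrix(c(-2.5, 2.5, -2.5, 2.5), nrow = 2))
  } else {
    wells <- matrix(c(10, -1, 0, 0.3,
                      10,  1, 0, 0.3,
                       8,  0, 1.2, 0.3), ncol = 4, byrow = TRUE)
    colnames(wells) <- c("A", "x", "y", "w")
    p <- utils::modifyList(list(kconf = 2, wells = wells), params)
    w <- as.matrix(p$wells)
    if (any(w[, "w"] <= 0) || any(w[, "A"] <= 0))
      stopf("well depths and widths must be positive")
    obj <- list(
      name = name, dimension = 2L, id = 3L,
      par = c(p$kconf, as.vector(t(w))), params = p,
      energy = function(x) {
        x <- as.matrix(x)
        u <- 0.5 * p$kconf * (x[, 1]^2 + x[, 2]^2)
        for (i in seq_len(nrow(w)))
          u <- u - w[i, "A"] * exp(-((x[, 1] - w[i, "x"])^2 +
                                     (x[, 2] - w[i, "y"])^2) /
                                     (2 * w[i, "w"]^2))
        u
      },
      gradient = function(x) {
        x <- as.matrix(x)
        gx <- p$kconf * x[, 1]; gy <- p$kconf * x[, 2]
        for (i in seq_len(nrow(w))) {
          dx <- x[, 1] - w[i, "x"]; dy <- x[, 2] - w[i, "y"]
          e <- w[i, "A"] * exp(-(dx^2 + dy^2) / (2 * w[i, "w"]^2)) /
            w[i, "w"]^2
          gx <- gx + e * dx; gy <- gy + e * dy
        }
        cbind(gx, gy)
      },
      minima = unname(w[, c("x", "y"), drop = FALSE]),
      range = matrix(c(-2.5, 2.5, -2.5, 2.5), nrow = 2))
  }
  class(obj) <- "g4_landscape"
  obj
}

#' @export
print.g4_landscape <- function(x, ...) {
  cat(sprintf("g4_landscape '%s' (%dD)\n", x$name, x$dimension))
  invisible(x)
}
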