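#' Replica-exchange diagnostics
#'
#' From an exchange log (one row per attempt: `time`, replica ids `a` and
#' `b`, `accepted`), computes per-replica cumulative accepted-exchange
#' counts over time, the mean acceptance per replica, and the least-squares
#' slope and R-squared of count versus time. A steadily exchanging
#' simulation shows near-linear curves (R-squared close to 1).
#'
#' @param exchange_log data.frame with columns `time`, `a`, `b`, `accepted`.
#' @param n_replicas total replica count (default: max id seen).
#' @return object of class `g4_exchange_diag`: `per_replica` data.frame
#'   (replica, attempts, accepted, acceptance, slope, r2) and `curves`, a
#'   list of data.frames (time, count). Replicas with no attempts report NA
#'   acceptance.
#' @export
exchange_diagnostics <- function(exchange_log, n_replicas = NULL) {
  if (nrow(exchange_log) == 0) stopf("empty exchange log")
  if (is.null(n_replicas)) n_replicas <- max(exchange_log$a, exchange_log$b)
  per <- data.frame(replica = seq_len(n_replicas), attempts = 0L,
                    accepted = 0L, acceptance = NA_real_, slope = NA_real_,
                    r2 = NA_real_)
  curves <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    sel <- exchange_log$a == r | exchange_log$b == r
    n <- sum(sel)
    per$attempts[r] <- n
    if (n == 0) { curves[[r]] <- data.frame(time = numeric(0),
                                            count = numeric(0)); next }
    tm <- exchange_log$time[sel]
    acc <- exchange_log$accepted[sel]
    cnt <- cumsum(acc)
    per$accepted[r] <- sum(acc)
    per$acceptance[r] <- mean(acc)
    curves[[r]] <- data.frame(time = tm, count = cnt)
    if (n >= 2 && sd(cnt) > 0) {
      fit <- lm(cnt ~ tm)
      per$slope[r] <- coef(fit)[2]
      # summary.lm warns on exact fits (e.g. every attempt accepted at a
      # uniform rate); the R^2 of 1 is still the right answer
      per$r2[r] <- suppressWarnings(summary(fit)$r.squared)
    }
  }
  structure(list(per_replica = per, curves = curves),
            class = "g4_exchange_diag")
}

#' @export
print.g4_exchange_diag <- function(x, ...) {
  print(x$per_replica)
  invisible(x)
}

#' Coverage and traversal count of a CV trace
#'
#' How thoroughly a replica explored its CV range: the fraction of
#' `n_segments` equal segments of the range visited at least once, and the
#' number of traversals, counted as alternations between the lowest and
#' highest decile of the range (a walker that goes back and forth many
#' times samples the landscape well).
#'
#' @param trace numeric CV time series.
#' @param range `c(lo, hi)` (default the observed range).
#' @param n_segments segment count for the coverage fraction.
#' @return list with `covered_fraction` and `traversals`.
#' @export
cv_coverage <- function(trace, range = NULL, n_segments = 20) {
  if (length(trace) == 0) stopf("empty trace")
  if (is.null(range)) range <- base::range(trace)
  span <- range[2] - range[1]
  if (span <= 0)
    return(list(covered_fraction = 1 / n_segments, traversals = 0L))
  seg <- findInterval(trace, seq(range[1], range[2],
                                 length.out = n_segments + 1),
                      rightmost.closed = TRUE)
  seg <- seg[seg >= 1 & seg <= n_segments]
  covered <- length(unique(seg)) / n_segments
  lo <- range[1] + 0.1 * span
  hi <- range[2] - 0.1 * span
  state <- ifelse(trace <= lo, 1L, ifelse(trace >= hi, 2L, NA_integer_))
  state <- state[!is.na(state)]
  traversals <- if (length(state) < 2) 0L else sum(diff(state) != 0)
  list(covered_fraction = covered, traversals = as.integer(traversals))
}
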