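#' Leader clustering of trajectory frames
#'
#' One-pass, order-dependent clustering: each frame is compared with the
#' representative structures of the clusters created so far, in creation
#' order; if a dRMSD below `threshold` is found the frame joins that (first
#' matching) cluster, otherwise it founds a new cluster and becomes its
#' representative. The default threshold is 0.3 nm; unfolding trajectories
#' are typically clustered with a looser 0.45 nm threshold.
#'
#' @param trajectory a [g4_trajectory()] (or a precomputed
#'   frames-by-distance-features matrix via `features`).
#' @param threshold dRMSD threshold, nm.
#' @param roles atom roles defining the dRMSD selection (default the `C4*`
#'   backbone).
#' @param features optional `n_frames x n_pairs` pairwise-distance matrix to
#'   cluster instead of computing it from `trajectory`.
#' @return object of class `g4_clusters`: `representatives` (frame indices),
#'   `membership` (cluster id per frame), `populations` (normalised,
#'   summing to 1), `threshold`.
#' @export
leader_cluster <- function(trajectory = NULL, threshold = 0.3, roles = "C4*",
                           features = NULL) {
  if (threshold <= 0) stopf("threshold must be positive")
  D <- if (is.null(features)) pairdist_frames(trajectory, roles) else
    as.matrix(features)
  nf <- nrow(D)
  if (nf < 1) stopf("need at least one frame")
  reps <- 1L
  membership <- integer(nf)
  membership[1] <- 1L
  for (f in seq_len(nf)[-1]) {
    # dRMSD of frame f to each representative, in creation order
    dd <- sqrt(rowMeans((D[reps, , drop = FALSE] -
                           matrix(D[f, ], length(reps), ncol(D),
                                  byrow = TRUE))^2))
    hit <- which(dd < threshold)
    if (length(hit) > 0) {
      membership[f] <- hit[1]
    } else {
      reps <- c(reps, f)
      membership[f] <- length(reps)
    }
  }
  structure(list(representatives = reps, membership = membership,
                 populations = as.numeric(table(factor(membership,
                   levels = seq_along(reps)))) / nf,
                 threshold = threshold),
            class = "g4_clusters")
}

#' @export
print.g4_clusters <- function(x, ...) {
  cat(sprintf("g4_clusters: %d clusters over %d frames (threshold %.2f nm)\n",
              length(x$representatives), length(x$membership), x$threshold))
  cat("populations:", paste(sprintf("%.3f",
      sort(x$populations, decreasing = TRUE)[seq_len(min(10,
      length(x$populations)))]), collapse = " "), "\n")
  invisible(x)
}
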