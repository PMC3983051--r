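#' Signed torsion (dihedral) angle of four points
#'
#' Standard signed dihedral about the p2-p3 axis, in degrees, using the range
#' convention `[-180, 180)` (so a perfectly trans arrangement reports -180).
#' This is the convention used downstream for the syn/anti windows of the
#' glycosidic torsion measured on O4'-C1'-N9-C8.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (nm).
#' @return angle in degrees in `[-180, 180)`.
#' @export
compute_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  eps <- 1e-12
  if (sum(b1^2) < eps || sum(b2^2) < eps || sum(b3^2) < eps)
    stopf("degenerate geometry: consecutive points coincide")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < eps || sum(n2^2) < eps)
    stopf("degenerate geometry: three consecutive points are collinear")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# wrap to [-180, 180)
wrap_angle <- function(a) {
  a <- ((a + 180) %% 360) - 180
  a[a >= 180] <- -180
  a
}

# vectorised dihedral over frames: P* are n_frames x 3 matrices
torsion_frames <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  cr <- function(A, B) cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
                             A[, 3] * B[, 1] - A[, 1] * B[, 3],
                             A[, 1] * B[, 2] - A[, 2] * B[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3); m1 <- cr(n1, b2)
  nb2 <- sqrt(rowSums(b2^2))
  wrap_angle(-atan2(rowSums(m1 * n2) / nb2, rowSums(n1 * n2)) * 180 / pi)
}

# place a fourth point from three reference points given bond length r (nm),
# bond angle theta (deg, at P3) and dihedral phi (deg); vectorised over rows
place_dihedral_point <- function(P1, P2, P3, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- P3 - P2
  bc <- bc / sqrt(rowSums(bc^2))
  ab <- P2 - P1
  cr <- function(A, B) cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
                             A[, 3] * B[, 1] - A[, 1] * B[, 3],
                             A[, 1] * B[, 2] - A[, 2] * B[, 1])
  n <- cr(ab, bc)
  n <- n / sqrt(rowSums(n^2))
  m <- cr(n, bc)
  d <- cbind(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  P3 + d[, 1] * bc + d[, 2] * m + d[, 3] * n
}

#' Radius of gyration of an atom selection
#'
#' Mass-uniform root-mean-square distance of the selected points from their
#' centroid (the Rg collective variable).
#'
#' @param structure a [g4_structure()].
#' @param roles atom roles to include (default the backbone `C4*` points).
#' @return Rg in nm.
#' @export
compute_rg <- function(structure, roles = "C4*") {
  X <- atom_coords(structure, roles)
  if (nrow(X) < 1) stopf("empty atom selection")
  ctr <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2, ctr)^2)))
}

#' Distance RMSD with respect to a reference structure
#'
#' `sqrt( mean over atom pairs of (d_ij - d_ij^ref)^2 )` over all pairs of the
#' selected atoms. Being built from internal distances only, dRMSD is
#' invariant under rigid-body rotation and translation, which is why it is
#' used both as a collective variable (on the `C4*` backbone) and as the
#' clustering metric.
#'
#' @param structure,native [g4_structure()] objects exposing the selection.
#' @param roles atom roles defining the selection (default `"C4*"`).
#' @return dRMSD in nm.
#' @export
compute_drmsd <- function(structure, native, roles = "C4*") {
  X <- atom_coords(structure, roles)
  Y <- atom_coords(native, roles)
  if (nrow(X) < 3) stopf("dRMSD needs at least 3 selected atoms")
  if (nrow(X) != nrow(Y) ||
      !identical(paste(attr(X, "resno"), attr(X, "role")),
                 paste(attr(Y, "resno"), attr(Y, "role"))))
    stopf("atom selection does not match between structure and native")
  dx <- dist(X); dy <- dist(Y)
  sqrt(mean((dx - dy)^2))
}

# pairwise-distance feature matrix over frames for a role selection:
# returns n_frames x n_pairs matrix (row = flattened upper triangle)
pairdist_frames <- function(trajectory, roles = "C4*") {
  top <- trajectory$topology
  idx <- which(top$atoms$role %in% roles)
  if (length(idx) < 3) stopf("selection has fewer than 3 atoms")
  idx <- idx[order(top$atoms$resno[idx], match(top$atoms$role[idx], roles))]
  pr <- utils::combn(idx, 2)
  nf <- n_frames(trajectory)
  out <- matrix(NA_real_, nf, ncol(pr))
  A <- trajectory$coords
  for (k in seq_len(ncol(pr))) {
    d <- matrix(A[pr[1, k], , ], nrow = 3) - matrix(A[pr[2, k], , ], nrow = 3)
    out[, k] <- sqrt(colSums(d^2))
  }
  out
}
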