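# shared fixtures and independent reference implementations

toy_native <- function() make_toy_quadruplex()

# minimal two-nucleotide structure with a single atom each, a given distance
# apart (used for contact-definition edge cases)
two_point_structure <- function(d = 0.3, role = "O6") {
  g4_structure(
    nucleotides = data.frame(resno = 1:2, resname = "DG"),
    atoms = data.frame(resno = 1:2, role = role,
                       x = c(0, d), y = 0, z = 0))
}

# rigid-body motion: rotate rows of an n x 3 matrix by random angles and
# translate
rigid_transform <- function(X, seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  sweep(X %*% (Rx %*% Ry %*% Rz), 2, runif(3, -2, 2), "+")
}

apply_rigid <- function(structure, seed = 1) {
  X <- as.matrix(structure$atoms[, c("x", "y", "z")])
  structure$atoms[, c("x", "y", "z")] <- rigid_transform(X, seed)
  structure
}

# independent leader-clustering reference: plain double loop, recomputing
# each frame-to-representative dRMSD directly from coordinates
reference_leader_cluster <- function(trajectory, threshold, roles = "C4*") {
  nf <- n_frames(trajectory)
  reps <- integer(0)
  membership <- integer(nf)
  drmsd_frames <- function(i, j) {
    compute_drmsd(get_frame(trajectory, i), get_frame(trajectory, j),
                  roles = roles)
  }
  for (f in seq_len(nf)) {
    hit <- 0L
    for (ri in seq_along(reps)) {
      if (drmsd_frames(f, reps[ri]) < threshold) { hit <- ri; break }
    }
    if (hit > 0) membership[f] <- hit
    else { reps <- c(reps, f); membership[f] <- length(reps) }
  }
  list(representatives = reps, membership = membership,
       populations = as.numeric(table(factor(membership,
         levels = seq_along(reps)))) / nf)
}

# small noisy trajectory around the native structure
noisy_trajectory <- function(native, n = 20, sd = 0.05, seed = 1) {
  set.seed(seed)
  structures <- lapply(seq_len(n), function(i) {
    s <- native
    s$atoms[, c("x", "y", "z")] <-
      as.matrix(s$atoms[, c("x", "y", "z")]) +
      rnorm(nrow(s$atoms) * 3, sd = sd)
    s
  })
  trajectory_from_structures(structures)
}
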