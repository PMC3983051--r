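#' Deterministic toy quadruplex structure
#'
#' Builds a reduced pseudo-atom model of a parallel-stacked G-quadruplex:
#' `n_repeats` strands of `repeat_len` guanines each, arranged as
#' `repeat_len` stacked tetrad layers around a central channel, with two
#' channel cations between the layers. Each guanine carries the pseudo-atoms
#' the analyses need (`C4*`, `O4'`, `C1'`, `N9`, `C8`, `O6`, a donor `N2`
#' and an acceptor `N7` on the Hoogsteen face), placed so that exactly the
#' adjacent-in-tetrad donor-acceptor pairs satisfy the 0.35 nm hydrogen-bond
#' criterion. The glycosidic torsion of every guanine is set to its native
#' syn/anti state (a fixed mixed pattern, as in hybrid-type folds).
#'
#' @param n_repeats number of G-repeats (strands), >= 2.
#' @param repeat_len guanines per repeat (= tetrad layers).
#' @param geometry named list overriding the default geometry (nm):
#'   `rise` (layer spacing, 0.34), `r_o6` (0.25), `r_n7` (0.17),
#'   `r_n2` (0.47), `r_n9` (0.55), `r_c1` (0.72), `r_o4` (0.84),
#'   `r_c4` (0.95), `twist` (deg per layer, 0).
#' @param seed unused randomness hook (the structure is deterministic);
#'   accepted for interface uniformity.
#' @return a [g4_structure()] serving as the native reference.
#' @export
make_toy_quadruplex <- function(n_repeats = 4, repeat_len = 3,
                                geometry = list(), seed = NULL) {
  if (n_repeats < 2) stopf("need at least 2 repeats")
  g <- utils::modifyList(list(rise = 0.34, r_o6 = 0.25, r_n7 = 0.17,
                              r_n2 = 0.47, r_n9 = 0.55, r_c1 = 0.72,
                              r_o4 = 0.84, r_c4 = 0.95, twist = 0), geometry)
  radii <- unlist(g[c("r_o6", "r_n7", "r_n2", "r_n9", "r_c1", "r_o4",
                      "r_c4")])
  if (g$rise <= 0 || any(radii <= 0))
    stopf("invalid geometry: rise and radii must be positive")
  pol <- function(az_deg, r, z) {
    a <- az_deg * pi / 180
    c(r * cos(a), r * sin(a), z)
  }
  chi_pattern <- c("syn", "anti", "anti")  # per layer, alternated by repeat
  nts <- list(); ats <- list()
  n <- 0L
  for (rep_i in seq_len(n_repeats)) for (lay in seq_len(repeat_len)) {
    n <- n + 1L
    az <- 360 / n_repeats * (rep_i - 1) + g$twist * (lay - 1)
    z <- g$rise * (lay - 1)
    chi_state <- chi_pattern[(lay - 1) %% 3 + 1]
    if (rep_i %% 2 == 0)
      chi_state <- if (chi_state == "syn") "anti" else "syn"
    nts[[n]] <- data.frame(resno = n, resname = "DG", repeat_id = rep_i,
                           tetrad = lay, native_chi = chi_state,
                           stringsAsFactors = FALSE)
    pts <- rbind(
      `O6` = pol(az, g$r_o6, z),
      `N7` = pol(az - 45, g$r_n7, z),
      `N2` = pol(az + 45, g$r_n2, z),
      `N9` = pol(az, g$r_n9, z),
      `C1'` = pol(az + 10, g$r_c1, z + 0.02),
      `O4'` = pol(az + 24, g$r_o4, z + 0.08),
      `C4*` = pol(az + 30, g$r_c4, z))
    chi <- if (chi_state == "syn") 45 else -160
    c8 <- place_dihedral_point(matrix(pts["O4'", ], 1),
                               matrix(pts["C1'", ], 1),
                               matrix(pts["N9", ], 1),
                               r = 0.38, theta = 115, phi = chi)
    pts <- rbind(pts, C8 = c8[1, ])
    ats[[n]] <- data.frame(resno = n, role = rownames(pts),
                           x = pts[, 1], y = pts[, 2], z = pts[, 3],
                           stringsAsFactors = FALSE)
  }
  ions <- rbind(c(0, 0, 0.5 * g$rise),
                c(0, 0, (repeat_len - 1.5) * g$rise))
  at <- do.call(rbind, ats)
  rownames(at) <- NULL
  g4_structure(do.call(rbind, nts), at, ions)
}

#' Specification of a synthetic intermediate ensemble
#'
#' Describes the statistical structure planted in a
#' [make_intermediate_ensemble()] trajectory: per-pair hydrogen-bond
#' formation probabilities, per-site cation occupancies, two-state
#' glycosidic dynamics with stated mean dwell times, frame count, stride
#' and coordinate noise.
#'
#' @param hbond_pairs data.frame with columns `resno_i`, `resno_j`, `donor`,
#'   `acceptor`, `prob`, `native` (logical annotation).
#' @param ion_sites data.frame with columns `resno` (the O6 the site sits
#'   on) and `occupancy` in `[0, 1]`.
#' @param torsion data.frame with columns `resno`, `state` (`"syn"`,
#'   `"anti"` or `"dynamic"`), `dwell_syn_ns`, `dwell_anti_ns` (used for
#'   dynamic nucleotides).
#' @param noise_nm Gaussian coordinate noise per axis, nm.
#' @param n_frames frames to generate.
#' @param stride_ns frame spacing, ns.
#' @param seed RNG seed (generation is bit-reproducible given it).
#' @return list of class `g4_ensemble_spec`.
#' @export
ensemble_spec <- function(hbond_pairs, ion_sites, torsion = NULL,
                          noise_nm = 0.02, n_frames = 2000, stride_ns = 0.5,
                          seed = 1) {
  if (any(hbond_pairs$prob < 0 | hbond_pairs$prob > 1))
    stopf("hbond probabilities must be in [0, 1]")
  if (any(ion_sites$occupancy < 0 | ion_sites$occupancy > 1))
    stopf("ion occupancies must be in [0, 1]")
  if (!is.null(torsion) &&
      any(c(torsion$dwell_syn_ns, torsion$dwell_anti_ns) <= 0, na.rm = TRUE))
    stopf("dwell times must be positive")
  if (n_frames < 1) stopf("n_frames must be >= 1")
  structure(list(hbond_pairs = hbond_pairs, ion_sites = ion_sites,
                 torsion = torsion, noise_nm = noise_nm,
                 n_frames = as.integer(n_frames), stride_ns = stride_ns,
                 seed = seed),
            class = "g4_ensemble_spec")
}

#' Default planted-intermediate specification
#'
#' The study-condition ensemble used throughout the package's validation:
#' four native tetrad hydrogen bonds planted at probability 0.9 and two
#' non-native pairs at 0.3; two cation sites with occupancies 1.0 and 0.5
#' (mean bound count 1.5); two nucleotides with symmetric two-state
#' glycosidic dynamics of 10 ns mean dwell, the rest fixed in their native
#' state; 2000 frames at 0.5 ns with 0.02 nm coordinate noise.
#'
#' @param native a [make_toy_quadruplex()] structure.
#' @param seed RNG seed.
#' @param n_frames,stride_ns optionally resize the ensemble.
#' @export
default_ensemble_spec <- function(native, seed = 1, n_frames = 2000,
                                  stride_ns = 0.5) {
  nt <- native$nucleotides
  lay1 <- nt$resno[nt$tetrad == 1]
  # native bonds: around tetrad layer 1 (donor of i to acceptor of next)
  hb <- data.frame(resno_i = lay1,
                   resno_j = lay1[c(2:length(lay1), 1)],
                   donor = "N2", acceptor = "N7", prob = 0.9, native = TRUE)
  # non-native: long-range pairs that are far apart in the native fold
  top_lay <- max(nt$tetrad)
  far1 <- nt$resno[nt$tetrad == top_lay][1]
  far2 <- nt$resno[nt$tetrad == top_lay][3]
  hb <- rbind(hb,
              data.frame(resno_i = lay1[1], resno_j = far2, donor = "N2",
                         acceptor = "N7", prob = 0.3, native = FALSE),
              data.frame(resno_i = lay1[3], resno_j = far1, donor = "N2",
                         acceptor = "N7", prob = 0.3, native = FALSE))
  sites <- data.frame(resno = c(nt$resno[nt$tetrad == 2][1],
                                nt$resno[nt$tetrad == 2][3]),
                      occupancy = c(1.0, 0.5))
  tor <- data.frame(resno = nt$resno, state = nt$native_chi,
                    dwell_syn_ns = NA_real_, dwell_anti_ns = NA_real_)
  dyn <- nt$resno[nt$tetrad == 3][1:2]
  tor$state[tor$resno %in% dyn] <- "dynamic"
  tor$dwell_syn_ns[tor$resno %in% dyn] <- 10
  tor$dwell_anti_ns[tor$resno %in% dyn] <- 10
  ensemble_spec(hb, sites, tor, noise_nm = 0.02, n_frames = n_frames,
                stride_ns = stride_ns, seed = seed)
}

#' Generate a conformational ensemble with planted statistics
#'
#' Produces a trajectory around the native structure in which every planted
#' feature is geometrically realised, so the analysis operations can be
#' validated by parameter recovery:
#' * each hydrogen-bond pair is in contact with its Bernoulli probability —
#'   the acceptor atom is placed along the native donor-acceptor direction
#'   at a distance drawn from 0.28-0.33 nm (in contact) or 0.5-0.8 nm (out),
#'   straddling the 0.35 nm criterion with margin;
#' * each cation site is occupied with its planted probability (ion placed
#'   0.25 nm radially outward of its O6, otherwise parked far away);
#' * glycosidic torsions follow per-nucleotide two-state Markov (telegraph)
#'   dynamics with the planted mean dwell times, discretised at the frame
#'   stride, realised exactly by re-placing the C8 atom;
#' * all atoms get Gaussian coordinate noise.
#'
#' @param spec an [ensemble_spec()].
#' @param native a [g4_structure()] consistent with the spec.
#' @return a [g4_trajectory()]; the spec is attached as attribute `"spec"`.
#' @export
make_intermediate_ensemble <- function(spec, native) {
  hb <- spec$hbond_pairs
  # conflicting constraints: an acceptor atom may be repositioned by at most
  # one pair, and must not double as a planted donor
  akey <- paste(hb$resno_j, hb$acceptor)
  dkey <- paste(hb$resno_i, hb$donor)
  if (anyDuplicated(akey))
    stopf("infeasible constraints: pair %d-%d reuses acceptor atom %s of nucleotide %d",
          hb$resno_i[duplicated(akey)][1], hb$resno_j[duplicated(akey)][1],
          hb$acceptor[duplicated(akey)][1], hb$resno_j[duplicated(akey)][1])
  if (any(akey %in% dkey))
    stopf("infeasible constraints: atom used as both donor and acceptor (pair %d-%d)",
          hb$resno_i[which(akey %in% dkey)[1]],
          hb$resno_j[which(akey %in% dkey)[1]])
  top_atoms <- native$atoms
  na_xyz <- as.matrix(top_atoms[, c("x", "y", "z")])
  nf <- spec$n_frames
  natm <- nrow(top_atoms)
  with_seed(spec$seed, {
    coords <- array(rep(na_xyz, nf), c(natm, 3, nf)) +
      array(rnorm(natm * 3 * nf, sd = spec$noise_nm), c(natm, 3, nf))
    # --- hydrogen bonds ---
    trow <- function(resno, role) {
      i <- which(top_atoms$resno == resno & top_atoms$role == role)
      if (length(i) != 1) stopf("nucleotide %d lacks atom '%s'", resno, role)
      i
    }
    # a direction is admissible for a placement range when every point of
    # the segment stays clear of all other donors, so no unplanned
    # donor-acceptor contact can arise
    donor_rows <- vapply(seq_len(nrow(hb)),
                         function(k) trow(hb$resno_i[k], hb$donor[k]), 1L)
    ctr_xy <- colMeans(na_xyz[, 1:2, drop = FALSE])
    pick_direction <- function(di, drange, k) {
      u_nat <- na_xyz[trow(hb$resno_j[k], hb$acceptor[k]), ] - na_xyz[di, ]
      L <- sqrt(sum(u_nat^2))
      if (L < 1e-6)
        stopf("infeasible constraints: pair %d-%d has coincident donor/acceptor",
              hb$resno_i[k], hb$resno_j[k])
      u_out <- c(na_xyz[di, 1:2] - ctr_xy, 0)
      if (sqrt(sum(u_out^2)) < 1e-6) u_out <- c(1, 0, 0)
      cands <- list(u_nat / L, u_out / sqrt(sum(u_out^2)),
                    c(0, 0, 1), c(0, 0, -1))
      all_donor_rows <- which(top_atoms$role %in% unique(hb$donor))
      others <- na_xyz[setdiff(all_donor_rows, di), , drop = FALSE]
      for (u in cands) {
        pts <- outer(seq(drange[1], drange[2], length.out = 9), u) +
          rep(na_xyz[di, ], each = 9)
        if (nrow(others) == 0 ||
            min(cross_dist(pts, others)) >= 0.36) return(u)
      }
      stopf("infeasible constraints: no clear placement direction for pair %d-%d",
            hb$resno_i[k], hb$resno_j[k])
    }
    for (k in seq_len(nrow(hb))) {
      di <- donor_rows[k]
      ai <- trow(hb$resno_j[k], hb$acceptor[k])
      u_in <- pick_direction(di, c(0.28, 0.33), k)
      u_out <- pick_direction(di, c(0.5, 0.8), k)
      formed <- runif(nf) < hb$prob[k]
      d <- ifelse(formed, runif(nf, 0.28, 0.33), runif(nf, 0.5, 0.8))
      u <- t(vapply(formed, function(f) if (f) u_in else u_out,
                    numeric(3)))
      for (ax in 1:3)
        coords[ai, ax, ] <- coords[di, ax, ] + u[, ax] * d
    }
    # --- glycosidic torsions ---
    tor <- spec$torsion
    if (!is.null(tor)) {
      for (k in seq_len(nrow(tor))) {
        rn <- tor$resno[k]
        if (tor$state[k] == "dynamic") {
          p_sa <- 1 - exp(-spec$stride_ns / tor$dwell_syn_ns[k])
          p_as <- 1 - exp(-spec$stride_ns / tor$dwell_anti_ns[k])
          st <- integer(nf)  # 1 = syn, 2 = anti
          st[1] <- sample(1:2, 1)
          flips <- runif(nf)
          for (f in 2:nf)
            st[f] <- if (st[f - 1] == 1)
              (if (flips[f] < p_sa) 2L else 1L) else
              (if (flips[f] < p_as) 1L else 2L)
        } else {
          st <- rep(if (tor$state[k] == "syn") 1L else 2L, nf)
        }
        target <- ifelse(st == 1L, 45, -160)
        phi <- target + rnorm(nf, sd = 8)
        P1 <- t(matrix(coords[trow(rn, "O4'"), , ], nrow = 3))
        P2 <- t(matrix(coords[trow(rn, "C1'"), , ], nrow = 3))
        P3 <- t(matrix(coords[trow(rn, "N9"), , ], nrow = 3))
        C8 <- place_dihedral_point(P1, P2, P3, r = 0.38, theta = 115,
                                   phi = phi)
        coords[trow(rn, "C8"), , ] <- t(C8)
      }
    }
    # --- cations ---
    sites <- spec$ion_sites
    ni <- nrow(sites)
    ion_coords <- array(NA_real_, c(ni, 3, nf))
    for (k in seq_len(ni)) {
      oi <- trow(sites$resno[k], "O6")
      outward <- na_xyz[oi, ]
      outward[3] <- 0
      no <- sqrt(sum(outward^2))
      if (no < 1e-6) outward <- c(1, 0, 0) else outward <- outward / no
      occupied <- runif(nf) < sites$occupancy[k]
      far <- c(5 + k, 5, 5)
      for (ax in 1:3)
        ion_coords[k, ax, ] <- ifelse(occupied,
                                      coords[oi, ax, ] + 0.25 * outward[ax],
                                      far[ax])
    }
    traj <- g4_trajectory(
      list(nucleotides = native$nucleotides,
           atoms = top_atoms[, c("resno", "role")]),
      coords, ion_coords, times = (seq_len(nf) - 1) * spec$stride_ns)
    attr(traj, "spec") <- spec
    traj
  })
}

#' Generate a labelled set of unfolding trajectories
#'
#' Each trajectory walks through a planted sequence of conformational stages
#' (native, possibly intermediates, unfolded), realised as uniformly scaled
#' copies of the native structure separated by a backbone dRMSD much larger
#' than the clustering threshold, with small intra-stage coordinate noise.
#' The planted per-pathway multiplicities and true per-frame stage labels
#' are returned for oracle comparison.
#'
#' @param native a [g4_structure()].
#' @param paths list of stage-label vectors, each starting from the native
#'   stage (default three routes mirroring a dominant-pathway split:
#'   native -> triplex -> unfolded, native -> hairpin -> unfolded,
#'   native -> unfolded).
#' @param multiplicities trajectories per path (must sum to
#'   `n_trajectories`); default `c(8, 1, 1)`.
#' @param n_trajectories total count (default `sum(multiplicities)`).
#' @param frames_per_stage frames spent in each stage.
#' @param noise_nm intra-stage coordinate noise.
#' @param stage_gap_nm target backbone dRMSD between consecutive stage
#'   conformations (default 1.0, well above the 0.45 nm unfolding
#'   clustering threshold).
#' @param seed RNG seed.
#' @return list of class `g4_unfolding_set`: `trajectories` (list of
#'   [g4_trajectory()]), `labels` (true per-frame stage labels), `paths`,
#'   `multiplicities`, `stages` (stage names in scale order).
#' @export
make_unfolding_set <- function(native,
                               paths = list(c("N", "T", "U"),
                                            c("N", "H", "U"),
                                            c("N", "U")),
                               multiplicities = c(8, 1, 1),
                               n_trajectories = sum(multiplicities),
                               frames_per_stage = 5, noise_nm = 0.01,
                               stage_gap_nm = 1.0, seed = 1) {
  if (length(multiplicities) != length(paths))
    stopf("multiplicities must match the number of paths")
  if (sum(multiplicities) != n_trajectories)
    stopf("multiplicities must sum to n_trajectories")
  stages <- unique(unlist(paths))
  X <- atom_coords(native, "C4*")
  rms_nat <- sqrt(mean(dist(X)^2))
  dscale <- stage_gap_nm / rms_nat
  scale_of <- setNames(1 + dscale * (seq_along(stages) - 1), stages)
  top_atoms <- native$atoms
  na_xyz <- as.matrix(top_atoms[, c("x", "y", "z")])
  natm <- nrow(top_atoms)
  with_seed(seed, {
    trajs <- list(); labels <- list()
    ti <- 0L
    for (p in seq_along(paths)) for (rep_i in seq_len(multiplicities[p])) {
      ti <- ti + 1L
      seq_st <- rep(paths[[p]], each = frames_per_stage)
      nf <- length(seq_st)
      coords <- array(NA_real_, c(natm, 3, nf))
      for (f in seq_len(nf))
        coords[, , f] <- na_xyz * scale_of[seq_st[f]] +
          rnorm(natm * 3, sd = noise_nm)
      trajs[[ti]] <- g4_trajectory(
        list(nucleotides = native$nucleotides,
             atoms = top_atoms[, c("resno", "role")]),
        coords, times = seq_len(nf) - 1)
      labels[[ti]] <- seq_st
    }
    structure(list(trajectories = trajs, labels = labels, paths = paths,
                   multiplicities = multiplicities, stages = stages),
              class = "g4_unfolding_set")
  })
}

#' Stage-label trajectories by leader clustering
#'
#' Concatenates the frames of several trajectories, leader-clusters them on
#' backbone dRMSD (default threshold 0.45 nm, the looser setting used for
#' high-temperature unfolding runs) and returns the per-trajectory cluster
#' label sequences, ready for [build_pathway_graph()].
#'
#' @param trajectories list of [g4_trajectory()] with identical topology.
#' @param threshold clustering threshold, nm.
#' @param roles dRMSD selection.
#' @return list with `label_sequences` (one integer vector per trajectory)
#'   and `clusters` (the underlying [leader_cluster()] result).
#' @export
label_stages_by_clustering <- function(trajectories, threshold = 0.45,
                                       roles = "C4*") {
  feats <- lapply(trajectories, pairdist_frames, roles = roles)
  nfr <- vapply(feats, nrow, 1L)
  cl <- leader_cluster(features = do.call(rbind, feats),
                       threshold = threshold)
  idx <- cumsum(c(0, nfr))
  seqs <- lapply(seq_along(trajectories), function(i)
    cl$membership[(idx[i] + 1):idx[i + 1]])
  list(label_sequences = seqs, clusters = cl)
}
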