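#' Hydrogen-bond probability map of an ensemble
#'
#' For every nucleotide pair, the fraction of frames in which at least one
#' donor-acceptor atom pair satisfies the geometric criterion. In the
#' reduced representation (no explicit hydrogens) the criterion is
#' donor-to-acceptor heavy-atom distance below `cutoff`; when hydrogen
#' positions are supplied a donor-H-acceptor angle condition is applied as
#' well. Pairs are annotated native or non-native against the map computed
#' on the reference structure.
#'
#' @param trajectory a [g4_trajectory()] whose frames expose the donor and
#'   acceptor roles.
#' @param native reference [g4_structure()] used for the native/non-native
#'   annotation (optional).
#' @param donors,acceptors atom roles acting as donors / acceptors (defaults
#'   `"N2"` and `"N7"`, the guanine Hoogsteen-face pair of the reduced
#'   representation).
#' @param cutoff heavy-atom distance criterion, nm (default 0.35).
#' @param h_role optional hydrogen role; when present in the topology the
#'   donor-H-acceptor angle must also exceed `min_angle`.
#' @param min_angle degrees (default 135).
#' @return object of class `g4_hbond_map`: `probability` (n_nt x n_nt
#'   matrix, diagonal 0), `native` (logical matrix or NULL).
#' @export
hbond_map <- function(trajectory, native = NULL, donors = "N2",
                      acceptors = "N7", cutoff = 0.35, h_role = NULL,
                      min_angle = 135) {
  top <- trajectory$topology
  nt <- top$nucleotides$resno
  n <- length(nt)
  nf <- n_frames(trajectory)
  for (role in c(donors, acceptors)) {
    miss <- setdiff(nt, top$atoms$resno[top$atoms$role == role])
    if (length(miss) > 0)
      stopf("nucleotide %d is missing donor/acceptor atom '%s'",
            miss[1], role)
  }
  prob <- matrix(0, n, n, dimnames = list(nt, nt))
  A <- trajectory$coords
  use_h <- !is.null(h_role) && any(top$atoms$role == h_role)
  formed_pair <- function(di, aj) {
    # di, aj: atom row indices; returns logical over frames
    d <- matrix(A[di, , ], nrow = 3) - matrix(A[aj, , ], nrow = 3)
    ok <- sqrt(colSums(d^2)) < cutoff
    if (use_h) {
      hi <- which(top$atoms$resno == top$atoms$resno[di] &
                    top$atoms$role == h_role)[1]
      if (!is.na(hi)) {
        H <- matrix(A[hi, , ], nrow = 3)
        v1 <- matrix(A[di, , ], nrow = 3) - H
        v2 <- matrix(A[aj, , ], nrow = 3) - H
        cosang <- colSums(v1 * v2) /
          sqrt(colSums(v1^2) * colSums(v2^2))
        ok <- ok & (acos(pmin(pmax(cosang, -1), 1)) * 180 / pi >= min_angle)
      }
    }
    ok
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    formed <- rep(FALSE, nf)
    for (dr in donors) for (ar in acceptors) {
      di_i <- atom_row(top, nt[i], dr); aj_j <- atom_row(top, nt[j], ar)
      di_j <- atom_row(top, nt[j], dr); aj_i <- atom_row(top, nt[i], ar)
      formed <- formed | formed_pair(di_i, aj_j) | formed_pair(di_j, aj_i)
    }
    prob[i, j] <- prob[j, i] <- mean(formed)
  }
  native_map <- NULL
  if (!is.null(native)) {
    ntr <- trajectory_from_structures(list(native))
    nm <- hbond_map(ntr, donors = donors, acceptors = acceptors,
                    cutoff = cutoff, h_role = h_role, min_angle = min_angle)
    native_map <- nm$probability > 0
  }
  structure(list(probability = prob, native = native_map, cutoff = cutoff),
            class = "g4_hbond_map")
}

#' @export
print.g4_hbond_map <- function(x, ...) {
  nz <- sum(x$probability[upper.tri(x$probability)] > 0)
  cat(sprintf("g4_hbond_map: %d x %d nucleotides, %d pairs with P > 0\n",
              nrow(x$probability), ncol(x$probability), nz))
  invisible(x)
}

#' Ion-binding profile of an ensemble
#'
#' Per-nucleotide binding probability (fraction of frames with at least one
#' cation within `cutoff` of that nucleotide's binding atom, O6 by default)
#' and the mean bound-ion count (average over frames of the number of ions
#' within `cutoff` of at least one binding atom, each ion counted once).
#'
#' @param trajectory a [g4_trajectory()] carrying ion coordinates.
#' @param cutoff binding distance, nm (default 0.35, shared with the N_ion
#'   collective variable).
#' @param target_role binding atom role (default `"O6"`).
#' @return object of class `g4_ion_profile`: `probability` (named per
#'   nucleotide), `mean_bound` (scalar), `bound_per_frame`.
#' @export
ion_binding_profile <- function(trajectory, cutoff = 0.35,
                                target_role = "O6") {
  top <- trajectory$topology
  sel <- which(top$atoms$role == target_role)
  nt <- top$atoms$resno[sel]
  nf <- n_frames(trajectory)
  ni <- dim(trajectory$ion_coords)[1]
  prob <- setNames(rep(0, length(nt)), nt)
  bound <- rep(0, nf)
  if (ni > 0 && length(sel) > 0) {
    hits <- matrix(0, length(nt), nf)
    for (f in seq_len(nf)) {
      O <- matrix(trajectory$coords[sel, , f], ncol = 3)
      I <- matrix(trajectory$ion_coords[, , f], ncol = 3)
      d <- cross_dist(I, O)          # ions x binding atoms
      hits[, f] <- colSums(d < cutoff) > 0
      bound[f] <- sum(rowSums(d < cutoff) > 0)
    }
    prob[] <- rowMeans(hits)
  }
  structure(list(probability = prob, mean_bound = mean(bound),
                 bound_per_frame = bound, cutoff = cutoff),
            class = "g4_ion_profile")
}

#' @export
print.g4_ion_profile <- function(x, ...) {
  cat(sprintf("g4_ion_profile: mean bound ions %.2f; per-nucleotide P in [%.2f, %.2f]\n",
              x$mean_bound, min(x$probability), max(x$probability)))
  invisible(x)
}

#' Glycosidic torsion traces of a trajectory
#'
#' The chi torsion per nucleotide and frame, measured on the
#' O4'-C1'-N9-C8 atom quadruple.
#'
#' @param trajectory a [g4_trajectory()] exposing the four roles.
#' @return matrix `n_frames x n_nucleotides` of angles in degrees.
#' @export
glycosidic_traces <- function(trajectory) {
  top <- trajectory$topology
  nt <- top$nucleotides$resno
  nf <- n_frames(trajectory)
  out <- matrix(NA_real_, nf, length(nt), dimnames = list(NULL, nt))
  for (k in seq_along(nt)) {
    idx <- vapply(c("O4'", "C1'", "N9", "C8"),
                  function(r) atom_row(top, nt[k], r), 1L)
    P <- lapply(idx, function(i) t(matrix(trajectory$coords[i, , ],
                                          nrow = 3)))
    out[, k] <- torsion_frames(P[[1]], P[[2]], P[[3]], P[[4]])
  }
  out
}

#' Classify a glycosidic torsion trace as syn, anti or fluctuating
#'
#' Each sample is mapped to syn or anti by angular windows (syn for chi in
#' `(-90, 90]`, anti otherwise, by default). The nucleotide is classified as
#' the single state when that state's occupancy is at least `occ_threshold`
#' and fewer than `max_transitions` state changes occur; otherwise it is
#' fluctuating. Mean dwell times are the average run lengths in each state
#' times the sampling interval.
#'
#' @param chi numeric chi series, degrees.
#' @param times timestamps in ns (default unit spacing).
#' @param syn_window `c(lo, hi)`: chi in `(lo, hi]` is syn.
#' @param occ_threshold occupancy needed for a pure-state call (default 0.8).
#' @param max_transitions transitions allowed in a pure-state call
#'   (default 2, i.e. "fewer than 2").
#' @return object of class `g4_glyco`: `states` (factor per sample),
#'   `classification` (`"syn"`, `"anti"` or `"fluctuating"`),
#'   `n_transitions`, `mean_dwell_ns` (named syn/anti, NA when a state is
#'   never visited), `occupancy`.
#' @export
classify_glycosidic <- function(chi, times = NULL, syn_window = c(-90, 90),
                                occ_threshold = 0.8, max_transitions = 2) {
  if (length(chi) < 2) stopf("chi series must have length >= 2")
  if (is.null(times)) times <- seq_along(chi) - 1
  dt <- if (length(times) > 1) mean(diff(times)) else 1
  st <- ifelse(chi > syn_window[1] & chi <= syn_window[2], "syn", "anti")
  trans <- sum(st[-1] != st[-length(st)])
  occ <- c(syn = mean(st == "syn"), anti = mean(st == "anti"))
  r <- rle(st)
  dwell <- c(syn = NA_real_, anti = NA_real_)
  for (s in c("syn", "anti"))
    if (any(r$values == s))
      dwell[s] <- mean(r$lengths[r$values == s]) * dt
  cls <- if (max(occ) >= occ_threshold && trans < max_transitions)
    names(occ)[which.max(occ)] else "fluctuating"
  structure(list(states = factor(st, levels = c("syn", "anti")),
                 classification = cls, n_transitions = as.integer(trans),
                 mean_dwell_ns = dwell, occupancy = occ),
            class = "g4_glyco")
}

#' @export
print.g4_glyco <- function(x, ...) {
  cat(sprintf("glycosidic trace: %s (%d transitions; dwell syn %.2f / anti %.2f ns)\n",
              x$classification, x$n_transitions, x$mean_dwell_ns["syn"],
              x$mean_dwell_ns["anti"]))
  invisible(x)
}

#' Syn/anti summary table of a trajectory
#'
#' Applies [classify_glycosidic()] to every nucleotide's chi trace.
#'
#' @param trajectory a [g4_trajectory()].
#' @param ... passed to [classify_glycosidic()].
#' @return data.frame with one row per nucleotide: resno, classification,
#'   n_transitions, occupancy_syn, dwell_syn_ns, dwell_anti_ns.
#' @export
glycosidic_summary <- function(trajectory, ...) {
  chi <- glycosidic_traces(trajectory)
  nt <- trajectory$topology$nucleotides$resno
  out <- data.frame(resno = nt, classification = NA_character_,
                    n_transitions = NA_integer_, occupancy_syn = NA_real_,
                    dwell_syn_ns = NA_real_, dwell_anti_ns = NA_real_)
  for (k in seq_along(nt)) {
    g <- classify_glycosidic(chi[, k], trajectory$times, ...)
    out$classification[k] <- g$classification
    out$n_transitions[k] <- g$n_transitions
    out$occupancy_syn[k] <- g$occupancy["syn"]
    out$dwell_syn_ns[k] <- g$mean_dwell_ns["syn"]
    out$dwell_anti_ns[k] <- g$mean_dwell_ns["anti"]
  }
  out
}

#' Unfolding-pathway graph from stage-label sequences
#'
#' Consecutive distinct labels of each trajectory become directed edges
#' (repeated labels collapse); edge traversal counts aggregate over
#' trajectories, and each distinct collapsed path is reported with its
#' multiplicity. The total path count equals the number of input
#' trajectories.
#'
#' @param label_sequences list of per-trajectory label vectors (character or
#'   integer; `NA` entries are dropped).
#' @return object of class `g4_pathways`: `nodes`, `edges` (data.frame from,
#'   to, count), `paths` (data.frame path, count), `n_trajectories`.
#' @export
build_pathway_graph <- function(label_sequences) {
  if (length(label_sequences) < 1) stopf("need at least one label sequence")
  edge_key <- character(0)
  path_key <- character(0)
  nodes <- character(0)
  for (s in label_sequences) {
    s <- as.character(s[!is.na(s)])
    if (length(s) == 0) stopf("empty label sequence")
    s <- rle(s)$values
    nodes <- union(nodes, s)
    if (length(s) > 1)
      edge_key <- c(edge_key, paste(s[-length(s)], s[-1], sep = " -> "))
    path_key <- c(path_key, paste(s, collapse = " -> "))
  }
  et <- table(edge_key)
  edges <- if (length(et) > 0) {
    parts <- strsplit(names(et), " -> ", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, "", 1),
               to = vapply(parts, `[`, "", 2),
               count = as.integer(et), stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0),
                    count = integer(0))
  pt <- sort(table(path_key), decreasing = TRUE)
  structure(list(nodes = nodes,
                 edges = edges[order(-edges$count, edges$from, edges$to), ,
                               drop = FALSE],
                 paths = data.frame(path = names(pt), count = as.integer(pt),
                                    stringsAsFactors = FALSE),
                 n_trajectories = length(label_sequences)),
            class = "g4_pathways")
}

#' @export
print.g4_pathways <- function(x, ...) {
  cat(sprintf("g4_pathways: %d trajectories, %d nodes, %d edges\n",
              x$n_trajectories, length(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$paths)))
    cat(sprintf("  %2d x  %s\n", x$paths$count[i], x$paths$path[i]))
  invisible(x)
}

#' Export a pathway graph as Graphviz DOT
#'
#' @param pathways a [build_pathway_graph()] result.
#' @param file optional output path; when NULL the DOT text is returned.
#' @export
pathway_graph_to_dot <- function(pathways, file = NULL) {
  lines <- c("digraph pathways {",
             sprintf("  \"%s\";", pathways$nodes),
             sprintf("  \"%s\" -> \"%s\" [label=\"%d\"];",
                     pathways$edges$from, pathways$edges$to,
                     pathways$edges$count),
             "}")
  if (is.null(file)) return(paste(lines, collapse = "\n"))
  writeLines(lines, file)
  invisible(file)
}
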