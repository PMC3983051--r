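#' Reduced nucleic-acid structure
#'
#' A `g4_structure` holds one conformation of a (toy or real) quadruplex in a
#' reduced per-nucleotide representation: a table of nucleotides, a table of
#' named per-nucleotide pseudo-atoms with coordinates in nm, and the positions
#' of any cations. Atom names follow the roles the analyses need: `C4*`
#' (backbone), `O4'`, `C1'`, `N9`, `C8` (glycosidic torsion), `O6` (ion
#' coordination) and hydrogen-bond donor/acceptor points such as `N2`/`N7`.
#'
#' @param nucleotides data.frame with columns `resno` (1-based, unique,
#'   contiguous), `resname`, and optionally `repeat_id`, `tetrad`,
#'   `native_chi` (`"syn"`/`"anti"`).
#' @param atoms data.frame with columns `resno`, `role`, `x`, `y`, `z`
#'   (coordinates in nm).
#' @param ions numeric matrix with 3 columns (cation coordinates, nm); may
#'   have zero rows.
#' @return An object of class `g4_structure`.
#' @export
g4_structure <- function(nucleotides, atoms, ions = matrix(numeric(0), 0, 3)) {
  nucleotides <- as.data.frame(nucleotides)
  atoms <- as.data.frame(atoms)
  ions <- as.matrix(ions)
  if (ncol(ions) != 3 && nrow(ions) > 0) stopf("ions must have 3 columns")
  if (ncol(ions) == 0) ions <- matrix(numeric(0), 0, 3)
  x <- structure(list(nucleotides = nucleotides, atoms = atoms, ions = ions),
                 class = "g4_structure")
  validate_structure(x)
  x
}

#' @export
print.g4_structure <- function(x, ...) {
  cat(sprintf("g4_structure: %d nucleotides, %d atoms, %d ions\n",
              nrow(x$nucleotides), nrow(x$atoms), nrow(x$ions)))
  invisible(x)
}

validate_structure <- function(x) {
  nt <- x$nucleotides
  if (!all(c("resno", "resname") %in% names(nt)))
    stopf("nucleotides needs resno and resname columns")
  r <- sort(nt$resno)
  if (anyDuplicated(r) || !identical(as.integer(r), seq_along(r)))
    stopf("residue indices must be unique and contiguous starting at 1")
  at <- x$atoms
  if (!all(c("resno", "role", "x", "y", "z") %in% names(at)))
    stopf("atoms needs resno, role, x, y, z columns")
  if (!all(at$resno %in% nt$resno)) stopf("atom resno outside nucleotide table")
  if (!all(is.finite(c(at$x, at$y, at$z)))) stopf("non-finite atom coordinates")
  if (nrow(x$ions) > 0 && !all(is.finite(x$ions)))
    stopf("non-finite ion coordinates")
  invisible(TRUE)
}

#' Extract coordinates of selected atom roles
#'
#' @param structure a [g4_structure()].
#' @param roles character vector of atom roles, e.g. `"C4*"` or
#'   `c("O4'", "C1'")`.
#' @param resno optional residue numbers to restrict to.
#' @param require if `TRUE` (default) every requested (residue, role) must be
#'   present; a missing atom raises an error naming the nucleotide and role.
#' @return numeric matrix (n x 3) of coordinates in nm, with attributes
#'   `resno` and `role`.
#' @export
atom_coords <- function(structure, roles, resno = NULL, require = TRUE) {
  at <- structure$atoms
  keep <- at$role %in% roles
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  sel <- at[keep, , drop = FALSE]
  if (require) {
    want <- expand.grid(
      resno = if (is.null(resno)) structure$nucleotides$resno else resno,
      role = roles, stringsAsFactors = FALSE)
    have <- paste(sel$resno, sel$role)
    miss <- !(paste(want$resno, want$role) %in% have)
    if (any(miss)) {
      m <- want[miss, , drop = FALSE][1, ]
      stopf("nucleotide %d is missing required atom '%s'", m$resno, m$role)
    }
  }
  ord <- order(match(sel$role, roles), sel$resno)
  sel <- sel[ord, , drop = FALSE]
  m <- as.matrix(sel[, c("x", "y", "z")])
  attr(m, "resno") <- sel$resno
  attr(m, "role") <- sel$role
  m
}

#' Multi-frame trajectory of reduced structures
#'
#' A `g4_trajectory` stores a shared topology (nucleotide and atom tables
#' without coordinates) plus dense coordinate arrays over frames, which keeps
#' per-frame statistics vectorisable. All frames share the same topology.
#'
#' @param topology list with elements `nucleotides` and `atoms` (as in
#'   [g4_structure()] but without coordinate columns).
#' @param coords numeric array `n_atoms x 3 x n_frames` (nm), rows matching
#'   `topology$atoms`.
#' @param ion_coords numeric array `n_ions x 3 x n_frames` (nm); may have 0
#'   ions.
#' @param times strictly increasing frame timestamps in ns.
#' @return An object of class `g4_trajectory`.
#' @export
g4_trajectory <- function(topology, coords, ion_coords = NULL, times = NULL) {
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stopf("length(times) must equal the frame count")
  if (nf > 1 && any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (dim(coords)[1] != nrow(topology$atoms))
    stopf("coords rows must match the topology atom table")
  if (is.null(ion_coords)) ion_coords <- array(numeric(0), c(0, 3, nf))
  structure(list(topology = topology, coords = coords,
                 ion_coords = ion_coords, times = as.numeric(times)),
            class = "g4_trajectory")
}

#' @export
print.g4_trajectory <- function(x, ...) {
  cat(sprintf("g4_trajectory: %d frames, %d nucleotides, %d atoms, %d ions\n",
              n_frames(x), nrow(x$topology$nucleotides),
              nrow(x$topology$atoms), dim(x$ion_coords)[1]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a [g4_trajectory()].
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame of a trajectory as a structure
#'
#' @param trajectory a [g4_trajectory()].
#' @param i frame index (1-based).
#' @return a [g4_structure()].
#' @export
get_frame <- function(trajectory, i) {
  if (i < 1 || i > n_frames(trajectory)) stopf("frame index out of range")
  at <- trajectory$topology$atoms
  at$x <- trajectory$coords[, 1, i]
  at$y <- trajectory$coords[, 2, i]
  at$z <- trajectory$coords[, 3, i]
  ions <- if (dim(trajectory$ion_coords)[1] > 0)
    trajectory$ion_coords[, , i, drop = FALSE][, , 1] else
    matrix(numeric(0), 0, 3)
  if (is.null(dim(ions))) ions <- matrix(ions, ncol = 3)
  g4_structure(trajectory$topology$nucleotides, at, ions)
}

#' Build a trajectory from a list of structures
#'
#' All structures must share the same topology (nucleotides, atom roles and
#' order, ion count).
#'
#' @param structures list of [g4_structure()] objects.
#' @param times frame timestamps in ns (default `0, 1, 2, ...`).
#' @export
trajectory_from_structures <- function(structures, times = NULL) {
  if (length(structures) < 1) stopf("need at least one structure")
  s1 <- structures[[1]]
  key <- paste(s1$atoms$resno, s1$atoms$role)
  nf <- length(structures)
  coords <- array(NA_real_, c(nrow(s1$atoms), 3, nf))
  ni <- nrow(s1$ions)
  ion_coords <- array(NA_real_, c(ni, 3, nf))
  for (f in seq_len(nf)) {
    s <- structures[[f]]
    if (!identical(paste(s$atoms$resno, s$atoms$role), key) ||
        nrow(s$ions) != ni)
      stopf("frame %d does not share the first frame's topology", f)
    coords[, , f] <- as.matrix(s$atoms[, c("x", "y", "z")])
    if (ni > 0) ion_coords[, , f] <- s$ions
  }
  topology <- list(nucleotides = s1$nucleotides,
                   atoms = s1$atoms[, c("resno", "role")])
  g4_trajectory(topology, coords, ion_coords, times)
}

# index rows of the topology atom table for (resno, role); errors when missing
atom_row <- function(topology, resno, role) {
  i <- which(topology$atoms$resno == resno & topology$atoms$role == role)
  if (length(i) != 1)
    stopf("nucleotide %d is missing required atom '%s'", resno, role)
  i
}
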