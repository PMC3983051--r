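#' Default PDB atom-name to role mapping
#'
#' Maps PDB atom names onto the internal roles the analyses use. Both the
#' primed (`C4'`) and starred (`C4*`) backbone spellings are accepted;
#' potassium is recognised from atom or residue name `K`/`K+`/`POT`.
#'
#' @return named character vector: PDB atom name -> internal role.
#' @export
default_role_map <- function() {
  c("C4'" = "C4*", "C4*" = "C4*", "O4'" = "O4'", "O4*" = "O4'",
    "C1'" = "C1'", "C1*" = "C1'", "N9" = "N9", "C8" = "C8", "O6" = "O6",
    "N7" = "N7", "N2" = "N2", "N1" = "N1")
}

ion_names <- c("K", "K+", "POT")

# internal: build a bio3d pdb object from a structure (nm -> Angstrom)
as_bio3d_pdb <- function(structure) {
  inv <- c("C4*" = "C4'", "O4'" = "O4'", "C1'" = "C1'", "N9" = "N9",
           "C8" = "C8", "O6" = "O6", "N7" = "N7", "N2" = "N2", "N1" = "N1")
  at <- structure$atoms
  elety <- unname(ifelse(at$role %in% names(inv), inv[at$role], at$role))
  resname <- structure$nucleotides$resname[match(at$resno,
                                            structure$nucleotides$resno)]
  ni <- nrow(structure$ions)
  n_nt <- max(structure$nucleotides$resno)
  atom <- data.frame(
    type = c(rep("ATOM", nrow(at)), rep("HETATM", ni)),
    eleno = seq_len(nrow(at) + ni),
    elety = c(elety, rep("K", ni)),
    alt = NA, resid = c(resname, rep("K", ni)),
    chain = c(rep("A", nrow(at)), rep("B", ni)),
    resno = c(at$resno, if (ni > 0) n_nt + seq_len(ni)),
    insert = NA,
    x = c(at$x, structure$ions[, 1]) * 10,
    y = c(at$y, structure$ions[, 2]) * 10,
    z = c(at$z, structure$ions[, 3]) * 10,
    o = 1, b = 0, segid = NA,
    elesy = substr(c(elety, rep("K", ni)), 1, 1), charge = NA,
    stringsAsFactors = FALSE)
  pdb <- list(atom = atom,
              xyz = bio3d::as.xyz(matrix(t(as.matrix(
                atom[, c("x", "y", "z")])), nrow = 1)),
              calpha = rep(FALSE, nrow(atom)))
  class(pdb) <- "pdb"
  pdb
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Coordinates are converted from nm to Angstrom; cations become `HETATM K`
#' records on a separate chain.
#'
#' @param x a [g4_structure()] or [g4_trajectory()].
#' @param file output path.
#' @export
write_structure_pdb <- function(x, file) {
  if (inherits(x, "g4_structure")) {
    bio3d::write.pdb(as_bio3d_pdb(x), file = file)
  } else if (inherits(x, "g4_trajectory")) {
    s1 <- get_frame(x, 1)
    pdb <- as_bio3d_pdb(s1)
    nf <- n_frames(x)
    ni <- dim(x$ion_coords)[1]
    xyz <- matrix(NA_real_, nf, (nrow(s1$atoms) + ni) * 3)
    for (f in seq_len(nf)) {
      m <- rbind(x$coords[, , f],
                 if (ni > 0) matrix(x$ion_coords[, , f], ncol = 3))
      xyz[f, ] <- as.vector(t(m)) * 10
    }
    bio3d::write.pdb(pdb, xyz = xyz, file = file)
  } else stopf("x must be a g4_structure or g4_trajectory")
  invisible(file)
}

parse_bio3d <- function(path, multi) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tryCatch(bio3d::read.pdb(path, multi = multi),
           error = function(e) stopf("malformed PDB '%s': %s", path,
                                     conditionMessage(e)))
}

build_topology <- function(pdb, role_map, require_roles, quiet) {
  at <- pdb$atom
  is_ion <- at$elety %in% ion_names | at$resid %in% ion_names
  nt_at <- at[!is_ion, , drop = FALSE]
  role <- role_map[nt_at$elety]
  unknown <- sum(is.na(role))
  if (unknown > 0 && !quiet)
    message(sprintf("ignored %d atoms with unmapped names", unknown))
  keep <- !is.na(role)
  nt_at <- nt_at[keep, , drop = FALSE]
  role <- role[keep]
  resno_orig <- nt_at$resno
  ures <- sort(unique(resno_orig))
  resno <- match(resno_orig, ures)
  nucleotides <- data.frame(
    resno = seq_along(ures),
    resname = nt_at$resid[match(ures, resno_orig)],
    stringsAsFactors = FALSE)
  if (!is.null(require_roles)) {
    for (r in require_roles) {
      miss <- setdiff(nucleotides$resno, resno[role == r])
      if (length(miss) > 0)
        stopf("missing role '%s' on nucleotide(s) %s", r,
              paste(miss, collapse = ", "))
    }
  }
  list(rows = which(!is_ion)[keep], ion_rows = which(is_ion),
       atoms = data.frame(resno = resno, role = unname(role),
                          stringsAsFactors = FALSE),
       nucleotides = nucleotides)
}

#' Read a structure from a single-model PDB file
#'
#' Atom names are resolved to internal roles through `role_map`; unmapped
#' atoms are ignored (their count is reported). Potassium records become
#' the structure's ion list. Coordinates are converted to nm.
#'
#' @param path PDB file.
#' @param role_map named vector PDB-name -> role (default
#'   [default_role_map()]).
#' @param require_roles roles that must be present on every nucleotide
#'   (error lists offending nucleotides).
#' @param quiet suppress the unmapped-atom message.
#' @return a [g4_structure()].
#' @export
read_structure <- function(path, role_map = default_role_map(),
                           require_roles = NULL, quiet = FALSE) {
  pdb <- parse_bio3d(path, multi = FALSE)
  top <- build_topology(pdb, role_map, require_roles, quiet)
  at <- pdb$atom
  atoms <- cbind(top$atoms,
                 at[top$rows, c("x", "y", "z"), drop = FALSE] / 10)
  ions <- as.matrix(at[top$ion_rows, c("x", "y", "z"), drop = FALSE]) / 10
  g4_structure(top$nucleotides, atoms, ions)
}

#' Read a trajectory from a multi-model PDB file
#'
#' @inheritParams read_structure
#' @param times frame timestamps in ns (default `0, 1, ...`).
#' @return a [g4_trajectory()] (a single-model file gives one frame).
#' @export
read_trajectory <- function(path, role_map = default_role_map(),
                            require_roles = NULL, times = NULL,
                            quiet = FALSE) {
  pdb <- parse_bio3d(path, multi = TRUE)
  top <- build_topology(pdb, role_map, require_roles, quiet)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  natm <- nrow(top$atoms)
  ni <- length(top$ion_rows)
  coords <- array(NA_real_, c(natm, 3, nf))
  ion_coords <- array(NA_real_, c(ni, 3, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    coords[, , f] <- m[top$rows, , drop = FALSE]
    if (ni > 0) ion_coords[, , f] <- m[top$ion_rows, , drop = FALSE]
  }
  g4_trajectory(list(nucleotides = top$nucleotides, atoms = top$atoms),
                coords, ion_coords, times)
}

#' Export a free-energy surface
#'
#' Writes the surface both as JSON (axes, edges, values, mask) and as a
#' long-format CSV (one row per bin with centres, value and support flag).
#'
#' @param fel a [fel()] object.
#' @param json_file,csv_file output paths (either may be NULL to skip).
#' @export
write_fel <- function(fel, json_file = NULL, csv_file = NULL) {
  if (!is.null(json_file))
    jsonlite::write_json(list(axes = fel$axes, edges = fel$edges,
                              values = fel$values, mask = fel$mask),
                         json_file, digits = 10, auto_unbox = TRUE,
                         na = "null", matrix = "columnmajor")
  if (!is.null(csv_file)) {
    d <- length(fel$centers)
    if (d == 1) {
      df <- data.frame(fel$centers[[1]], value_kjmol = as.vector(fel$values),
                       supported = as.vector(fel$mask))
      names(df)[1] <- fel$axes[1]
    } else {
      g <- expand.grid(fel$centers[[1]], fel$centers[[2]])
      df <- data.frame(g[[1]], g[[2]], value_kjmol = as.vector(fel$values),
                       supported = as.vector(fel$mask))
      names(df)[1:2] <- fel$axes
    }
    write.csv(df, csv_file, row.names = FALSE)
  }
  invisible(NULL)
}
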