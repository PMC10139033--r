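# Trajectory container, atom-selection mini-grammar, and plain-text PDB
# input/output (single-model reference + multi-model trajectory).

#' Trajectory of coordinates with atom metadata
#'
#' @param coords numeric array of dimension frames x atoms x 3 (Angstrom).
#'   A single N x 3 matrix is promoted to a one-frame trajectory.
#' @param atoms data frame with one row per atom: `residue_index`,
#'   `residue_name`, `atom_name`, `element`, `backbone` (logical), `mass`,
#'   `chain` (`"protein"`, `"ligand"` or `"solvent"`).
#' @param time_per_frame frame spacing in picoseconds.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms, time_per_frame = 2) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    .err("coords must be a frames x atoms x 3 array")
  }
  if (any(!is.finite(coords))) .err("coordinates must be finite")
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) != dim(coords)[2]) {
    .err("atoms table must have one row per atom")
  }
  structure(list(coords = coords, atoms = atoms,
                 time_per_frame = time_per_frame),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms (%.3g ps/frame)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$time_per_frame))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an atoms x 3 matrix
#' @param traj a [trajectory()].
#' @param frame frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, frame = 1L) {
  if (frame < 1L || frame > n_frames(traj)) .err("frame %d out of range", frame)
  matrix(traj$coords[frame, , ], ncol = 3)
}

#' Select atoms with a small selection grammar
#'
#' Clauses joined by `and` are intersected. Supported clauses:
#' `protein`, `ligand`, `solvent` (chain tags), `backbone`, `heavy`
#' (equivalently `noh`), `all`, `resid A` / `resid A-B` (residue-index
#' ranges) and `name X Y ...` (atom names).
#'
#' @param x a [trajectory()] or an atoms data frame.
#' @param expr selection string, e.g. `"protein and backbone"`; an integer
#'   vector is passed through unchanged.
#' @return Sorted integer vector of atom indices.
#' @examples
#' \dontrun{select_atoms(traj, "protein and backbone and heavy")}
#' @export
select_atoms <- function(x, expr) {
  atoms <- if (inherits(x, "trajectory")) x$atoms else as.data.frame(x)
  if (is.numeric(expr)) {
    idx <- sort(unique(as.integer(expr)))
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(atoms))) {
      .err("atom index out of range")
    }
    return(idx)
  }
  clauses <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    keep <- keep & switch(toks[1],
      all = TRUE,
      protein = atoms$chain == "protein",
      ligand = atoms$chain == "ligand",
      solvent = atoms$chain == "solvent",
      backbone = atoms$backbone,
      heavy = ,
      noh = atoms$element != "H",
      resid = {
        if (length(toks) < 2L) .err("resid clause needs a range")
        rng <- as.integer(strsplit(toks[2], "-")[[1]])
        if (length(rng) == 1L) rng <- c(rng, rng)
        atoms$residue_index >= rng[1] & atoms$residue_index <= rng[2]
      },
      name = atoms$atom_name %in% toks[-1],
      .err("unknown selection clause '%s'", cl)
    )
  }
  which(keep)
}

# ---- PDB I/O --------------------------------------------------------------

.pdb_atom_lines <- function(xyz, atoms) {
  chain_code <- c(protein = "A", ligand = "L", solvent = "S")
  ch <- chain_code[atoms$chain]
  ch[is.na(ch)] <- "A"
  nm <- substr(atoms$atom_name, 1, 4)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)), nm,
          substr(atoms$residue_name, 1, 3), ch,
          atoms$residue_index, xyz[, 1], xyz[, 2], xyz[, 3],
          0, 0, substr(atoms$element, 1, 2))
}

#' Write a trajectory as a multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, occupancy and B-factor columns
#' zero-filled.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(.pdb_atom_lines(frame_coords(traj, t), traj$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a reference structure as a single-model PDB
#'
#' @param reference atoms data frame with `x`, `y`, `z` columns (as
#'   returned by [gen_trajectory()]), or a [trajectory()] whose first frame
#'   is written.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(reference, path) {
  if (inherits(reference, "trajectory")) {
    xyz <- frame_coords(reference, 1L)
    atoms <- reference$atoms
  } else {
    atoms <- as.data.frame(reference)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
  }
  writeLines(c(.pdb_atom_lines(xyz, atoms), "END"), path)
  invisible(path)
}

# map a bio3d atom table to the internal atoms schema
.atoms_from_bio3d <- function(at) {
  chain <- rep("protein", nrow(at))
  chain[at$chain == "L"] <- "ligand"
  chain[at$chain == "S"] <- "solvent"
  element <- trimws(at$elesy)
  element[!nzchar(element)] <- substr(trimws(at$elety)[!nzchar(element)], 1, 1)
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              P = 30.974)
  m <- masses[element]
  m[is.na(m)] <- 12.011
  data.frame(
    residue_index = at$resno,
    residue_name = at$resid,
    atom_name = trimws(at$elety),
    element = element,
    backbone = trimws(at$elety) %in% c("N", "CA", "C", "O") |
      grepl("^(N|CA|C|O)[0-9]+$", trimws(at$elety)),
    mass = as.numeric(m),
    chain = chain,
    stringsAsFactors = FALSE
  )
}

#' Read a (multi-model) PDB file into a trajectory
#'
#' Uses bio3d's PDB parser; each `MODEL` becomes one frame. Backbone flags
#' are inferred from the atom names (`N`, `CA`, `C`, `O`, optionally
#' number-suffixed), chain tags from the chain identifiers written by
#' [write_trajectory_pdb()] (`A` protein, `L` ligand, `S` solvent), and
#' masses from the element symbol.
#'
#' @param path PDB file.
#' @param time_per_frame frame spacing in ps.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, time_per_frame = 2) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (t in seq_len(nf)) {
    coords[t, , ] <- matrix(xyz[t, ], ncol = 3, byrow = TRUE)
  }
  trajectory(coords, .atoms_from_bio3d(pdb$atom), time_per_frame)
}
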