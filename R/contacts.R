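#' Write a trajectory slice as a multi-MODEL PDB file
#'
#' Serialises a [gen_trajectory()] slice (or any `"trajectory_slice"`) as
#' a plain-text multi-MODEL PDB, one MODEL per frame, converting the
#' internal nm coordinates to the Angstroms of the PDB format.
#'
#' @param traj A `"trajectory_slice"`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory_slice"))
  n_at <- nrow(traj$atoms)
  xyz <- matrix(NA_real_, nrow = traj$n_frames, ncol = 3 * n_at)
  for (f in seq_len(traj$n_frames))
    xyz[f, ] <- as.vector(t(traj$xyz[f, , ])) * 10  # nm -> Angstrom
  bio3d::write.pdb(file = file, xyz = xyz,
                   eleno = traj$atoms$eleno, elety = traj$atoms$elety,
                   resid = traj$atoms$resid, resno = traj$atoms$resno,
                   chain = traj$atoms$chain, elesy = traj$atoms$elesy)
  invisible(file)
}

# Heavy-atom call: element symbol where available, else the standard PDB
# convention that hydrogen atom names start with H (after any digit).
is_heavy_atom <- function(elesy, elety) {
  sy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  known <- sy != ""
  heavy <- !(sy %in% c("H", "D"))
  nm <- toupper(sub("^[0-9]*", "", trimws(elety)))
  heavy[!known] <- !startsWith(nm[!known], "H")
  heavy
}

#' Load a ligand/channel trajectory from PDB (and optionally DCD) files
#'
#' Reads a topology PDB — multi-MODEL PDBs provide the coordinates
#' directly — or a single-frame topology PDB plus a DCD coordinate file.
#' Atoms of the named ligand residue are flagged, hydrogens are flagged
#' non-heavy from the element column (falling back to the atom-name
#' prefix), and subunits are taken from the chain identifiers; when chain
#' information is missing, all protein atoms fall back to a single
#' subunit with a warning. Coordinates are stored in nm.
#'
#' @param topology Path to a PDB file.
#' @param coords Optional path to a DCD coordinate file; its atom count
#'   must match the topology.
#' @param ligand_resid Residue name of the ligand (default `"LIG"`).
#' @return A `"trajectory_slice"` (see [gen_trajectory()]).
#' @export
load_trajectory <- function(topology, coords = NULL, ligand_resid = "LIG") {
  pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz_mat <- if (is.null(coords)) {
    m <- pdb$xyz
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m
  } else {
    m <- bio3d::read.dcd(coords, verbose = FALSE)
    if (ncol(m) != 3 * nrow(at))
      stop("coordinate file has ", ncol(m) / 3, " atoms but the topology has ",
           nrow(at))
    m
  }
  n_frames <- nrow(xyz_mat)
  n_at <- nrow(at)
  chain <- as.character(at$chain)
  if (all(is.na(chain) | chain == "")) {
    warning("topology carries no chain identifiers; treating all protein ",
            "atoms as a single subunit 'A'")
    chain <- rep("A", n_at)
  }
  atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                      resno = at$resno, chain = chain, elesy = at$elesy)
  atoms$is_ligand <- atoms$resid == ligand_resid
  if (!any(atoms$is_ligand))
    stop("ligand residue '", ligand_resid, "' not found in the topology")
  atoms$is_heavy <- is_heavy_atom(atoms$elesy, atoms$elety)
  xyz <- array(NA_real_, dim = c(n_frames, n_at, 3))
  for (f in seq_len(n_frames))
    xyz[f, , ] <- matrix(xyz_mat[f, ], ncol = 3, byrow = TRUE) / 10 # A -> nm
  structure(list(xyz = xyz, atoms = atoms, n_frames = n_frames, box = NULL,
                 meta = list(topology = topology, coords = coords)),
            class = "trajectory_slice")
}

# All pairwise distances between two coordinate sets (rows = atoms, nm),
# with the orthorhombic minimum-image convention when a box is supplied.
pairwise_dist <- function(A, B, box = NULL) {
  if (is.null(box)) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  } else {
    d2 <- matrix(0, nrow(A), nrow(B))
    for (k in 1:3) {
      dk <- outer(A[, k], B[, k], `-`)
      dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk^2
    }
    sqrt(d2)
  }
}

#' Per-frame minimum heavy-atom distance between ligand and one residue
#'
#' For every frame, the smallest Euclidean distance between any heavy atom
#' of the ligand and any heavy atom of the given residue in the given
#' subunit — the quantity whose time course diagnoses whether a docked
#' compound stays bound. Minimum-image distances are used when the slice
#' carries box vectors.
#'
#' @param traj A `"trajectory_slice"`.
#' @param resno Residue number.
#' @param chain Subunit (chain) identifier.
#' @return Numeric vector, one distance (nm) per frame.
#' @export
min_distance_series <- function(traj, resno, chain = "A") {
  stopifnot(inherits(traj, "trajectory_slice"))
  lig <- which(traj$atoms$is_ligand & traj$atoms$is_heavy)
  if (length(lig) == 0) stop("trajectory has no ligand heavy atoms")
  res <- which(!traj$atoms$is_ligand & traj$atoms$is_heavy &
                 traj$atoms$resno == resno & traj$atoms$chain == chain)
  if (length(res) == 0)
    stop("residue ", resno, " in subunit ", chain,
         " has no heavy atoms in this trajectory")
  frame_coords <- function(f, idx) matrix(traj$xyz[f, idx, ], ncol = 3)
  vapply(seq_len(traj$n_frames), function(f)
    min(pairwise_dist(frame_coords(f, lig), frame_coords(f, res), traj$box)),
    numeric(1))
}

#' Ligand-residue contact frequencies across a trajectory
#'
#' For each (residue, subunit) pair, the fraction of frames in which any
#' ligand heavy atom lies within `cutoff_nm` of any residue heavy atom
#' (inclusive: a distance exactly at the cutoff counts as a contact). The
#' four chains of a homotetrameric channel act as quasi-independent
#' replicates, so frequencies are reported per subunit.
#'
#' @param traj A `"trajectory_slice"`.
#' @param residues Residue numbers to analyse; default all protein
#'   residues.
#' @param cutoff_nm Contact cutoff in nm (default 0.45 nm = 4.5 Angstrom).
#' @param chains Subunits to analyse; default all protein chains.
#' @return Object of class `"contact_profile"`: list with `cutoff_nm`,
#'   `frequencies` (data frame `resno`, `chain`, `frequency`, `n_frames`)
#'   and `distances` (named list of per-frame minimum-distance series).
#' @export
contact_frequency <- function(traj, residues = NULL, cutoff_nm = 0.45,
                              chains = NULL) {
  stopifnot(inherits(traj, "trajectory_slice"))
  if (cutoff_nm <= 0) stop("'cutoff_nm' must be > 0")
  prot <- traj$atoms[!traj$atoms$is_ligand, , drop = FALSE]
  if (is.null(residues)) residues <- sort(unique(prot$resno))
  if (length(residues) == 0) stop("empty residue list")
  if (is.null(chains)) chains <- sort(unique(prot$chain))
  grid <- expand.grid(resno = residues, chain = chains,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$resno, grid$chain), , drop = FALSE]
  series <- vector("list", nrow(grid))
  freq <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- min_distance_series(traj, grid$resno[i], grid$chain[i])
    series[[i]] <- s
    freq[i] <- sum(s <= cutoff_nm) / traj$n_frames
  }
  names(series) <- paste0(grid$resno, "_", grid$chain)
  structure(list(cutoff_nm = cutoff_nm,
                 frequencies = data.frame(resno = grid$resno,
                                          chain = grid$chain,
                                          frequency = freq,
                                          n_frames = traj$n_frames,
                                          row.names = NULL),
                 distances = series),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("Contact profile at cutoff", x$cutoff_nm, "nm (",
      x$frequencies$n_frames[1], "frames )\n")
  print(x$frequencies)
  invisible(x)
}

#' Long-format contact-frequency report
#'
#' The per-(residue, subunit) contact frequencies of a profile as a long
#' table sorted by residue then subunit — the layout of per-subunit
#' contact bar charts.
#'
#' @param profile A [contact_frequency()] result.
#' @return Data frame with columns `resno`, `chain`, `frequency`,
#'   `n_frames`, deterministically ordered.
#' @export
profile_report <- function(profile) {
  stopifnot(inherits(profile, "contact_profile"))
  f <- profile$frequencies
  f[order(f$resno, f$chain), , drop = FALSE]
}
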