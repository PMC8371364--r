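#' Build a topology table
#'
#' A topology is a tibble with one row per atom, in file order, carrying the
#' naming frame that every selection resolves against: atom serial and name,
#' element, residue name/number (author numbering, as deposited), chain,
#' insertion code, mass and a hetero flag. It is the tidy analogue of a
#' structure's atom table.
#'
#' @param serial Integer atom serials (unique).
#' @param name Atom names, PDB column convention (`"CA"`, `"OD1"`, ...).
#' @param element Element symbols; empty strings are inferred from `name`.
#' @param res_name Three-letter residue codes.
#' @param res_seq Author residue numbers (integer).
#' @param chain Single-character chain identifiers.
#' @param icode Insertion codes (`""` when absent); part of the residue key.
#' @param is_het Logical, `TRUE` for HETATM records (ligands, ions).
#' @return A tibble of class `md_topology` with an additional `mass` column
#'   (amu, derived from the element).
#' @examples
#' top <- md_topology(1:2, c("CA", "CA"), c("C", "C"),
#'                    c("GLY", "ALA"), 1:2, "A")
#' residues(top)
#' @export
md_topology <- function(serial, name, element, res_name, res_seq, chain,
                        icode = "", is_het = FALSE) {
  n <- length(serial)
  if (n == 0L) {
    abort("Topology must contain at least one atom.",
          class = "btkloop_empty_structure")
  }
  element <- toupper(trimws(element))
  blank <- !nzchar(element)
  if (any(blank)) element[blank] <- .element_from_name(name[blank])
  top <- tibble(
    serial = as.integer(serial),
    name = trimws(as.character(name)),
    element = element,
    res_name = trimws(as.character(res_name)),
    res_seq = as.integer(res_seq),
    chain = rep_len(as.character(chain), n),
    icode = rep_len(as.character(icode), n),
    mass = element_mass(element),
    is_het = rep_len(as.logical(is_het), n)
  )
  if (anyDuplicated(top$serial)) {
    abort("Atom serials must be unique within a topology.",
          class = "btkloop_topology_error")
  }
  class(top) <- c("md_topology", class(top))
  top
}

#' Residue table of a topology
#'
#' @param topology An `md_topology`.
#' @return A tibble with one row per residue (chain, res_seq, icode,
#'   res_name, first/last atom row indices), in topology order.
#' @export
residues <- function(topology) {
  key <- paste(topology$chain, topology$res_seq, topology$icode, sep = "|")
  idx <- which(!duplicated(key))
  grp <- match(key, key[idx])
  tibble(
    chain = topology$chain[idx],
    res_seq = topology$res_seq[idx],
    icode = topology$icode[idx],
    res_name = topology$res_name[idx],
    first_atom = idx,
    last_atom = vapply(seq_along(idx), function(i) max(which(grp == i)), 1L),
    n_atoms = tabulate(grp, nbins = length(idx))
  )
}

#' Assemble a trajectory object
#'
#' A trajectory couples a topology with a `frames x atoms x 3` coordinate
#' array in Angstrom, plus optional frame times in nanoseconds. Frames are
#' 1-indexed throughout the package, following R convention.
#'
#' @param topology An `md_topology`.
#' @param coords Numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param time_ns Optional numeric vector of frame times (ns).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, time_ns = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != nrow(topology)) {
    abort(sprintf(
      "Coordinate array has %d atoms but topology has %d.",
      dim(coords)[2], nrow(topology)), class = "btkloop_topology_mismatch")
  }
  if (!all(is.finite(coords))) {
    abort("Trajectory coordinates must all be finite.",
          class = "btkloop_coordinate_error")
  }
  if (!is.null(time_ns) && length(time_ns) != dim(coords)[1]) {
    abort("time_ns length must equal the number of frames.",
          class = "btkloop_trajectory_error")
  }
  structure(
    list(topology = topology, coords = coords, time_ns = time_ns),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frame(s), %d atoms, %d residues\n",
              n_frames(x), n_atoms(x), nrow(residues(x$topology))))
  if (!is.null(x$time_ns)) {
    cat(sprintf("  time: %.4g - %.4g ns\n", min(x$time_ns), max(x$time_ns)))
  }
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj An `md_trajectory`.
#' @return An integer scalar.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame's coordinates
#'
#' @param traj An `md_trajectory`.
#' @param frame Frame index (1-based).
#' @return An `n_atoms x 3` numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 1L || frame > n_frames(traj)) {
    abort(sprintf("Frame %d out of range (1..%d).", frame, n_frames(traj)),
          class = "btkloop_frame_error")
  }
  matrix(traj$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset a trajectory to a frame window
#'
#' @param traj An `md_trajectory`.
#' @param frames Integer vector of frame indices to keep (1-based).
#' @return An `md_trajectory` restricted to those frames, in the given order.
#' @export
frame_window <- function(traj, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(traj))) {
    abort("Frame window outside trajectory range.",
          class = "btkloop_frame_error")
  }
  md_trajectory(traj$topology,
                traj$coords[frames, , , drop = FALSE],
                traj$time_ns[frames])
}

# frame/time scaffold shared by all per-frame metric tibbles
.metric_tibble <- function(traj, metric, value, units) {
  tibble(
    frame = seq_len(n_frames(traj)),
    time_ns = if (is.null(traj$time_ns)) NA_real_ else traj$time_ns,
    metric = metric,
    value = value,
    units = units
  )
}
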