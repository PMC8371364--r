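#' Read a PDB file into a trajectory
#'
#' Parses `ATOM`/`HETATM` records (fixed columns) into a topology and one
#' trajectory frame per `MODEL` block (a single frame when the file has no
#' `MODEL` records). Coordinates are kept in Angstrom exactly as printed and
#' author residue numbers are preserved — residues are addressed as deposited
#' (Thr474, Tyr551, ...), never renumbered. `HETATM` atoms (e.g. an ATP
#' ligand) are retained and flagged via the `is_het` column.
#'
#' Alternate locations: for each atom site the highest-occupancy conformer is
#' kept (first on ties) and a warning is issued. Insertion codes are part of
#' the residue key.
#'
#' @param path Path to a PDB file.
#' @return An [md_trajectory()]; its `$topology` is the parsed topology.
#' @examples
#' top <- make_toy_topology(3)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(top, f)
#' traj <- read_pdb(f)
#' n_atoms(traj)
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path), class = "btkloop_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) {
    abort(sprintf("No ATOM/HETATM records in %s", path),
          class = "btkloop_empty_structure")
  }

  # assign each atom line to a model (0 when the file has no MODEL records)
  model_id <- cumsum(is_model)
  atom_lines <- which(is_atom)
  atom_model <- model_id[atom_lines]

  fx <- function(l, a, b) substr(l, a, b)
  txt <- lines[atom_lines]
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & nzchar(trimws(s))
    bad <- bad | !nzchar(trimws(s)) & what %in% c("x", "y", "z")
    if (any(bad)) {
      ln <- atom_lines[which(bad)[1]]
      abort(sprintf("Unreadable %s field in PDB record at line %d of %s",
                    what, ln, path),
            class = "btkloop_parse_error")
    }
    v
  }

  atoms <- tibble(
    model = atom_model,
    line = atom_lines,
    serial = as.integer(num(fx(txt, 7, 11), "serial")),
    name = trimws(fx(txt, 13, 16)),
    altloc = trimws(fx(txt, 17, 17)),
    res_name = trimws(fx(txt, 18, 20)),
    chain = fx(txt, 22, 22),
    res_seq = as.integer(num(fx(txt, 23, 26), "residue-number")),
    icode = trimws(fx(txt, 27, 27)),
    x = num(fx(txt, 31, 38), "x"),
    y = num(fx(txt, 39, 46), "y"),
    z = num(fx(txt, 47, 54), "z"),
    occ = suppressWarnings(as.numeric(fx(txt, 55, 60))),
    element = trimws(fx(txt, 77, 78)),
    is_het = rec[atom_lines] == "HETATM"
  )
  atoms$occ[is.na(atoms$occ)] <- 1

  # ALTLOC: keep the highest-occupancy conformer per atom site
  if (any(nzchar(atoms$altloc))) {
    site <- paste(atoms$model, atoms$chain, atoms$res_seq, atoms$icode,
                  atoms$name, sep = "|")
    best <- tapply(seq_len(nrow(atoms)), site, function(i) {
      i[which.max(atoms$occ[i])]
    })
    keep <- sort(unname(unlist(best)))
    if (length(keep) < nrow(atoms)) {
      warn(sprintf(
        "%d alternate-location atoms dropped (kept highest occupancy).",
        nrow(atoms) - length(keep)))
      atoms <- atoms[keep, ]
    }
  }

  mods <- unique(atoms$model)
  first <- atoms[atoms$model == mods[1], ]
  top <- md_topology(first$serial, first$name, first$element, first$res_name,
                     first$res_seq, first$chain, first$icode, first$is_het)
  nat <- nrow(first)
  coords <- array(NA_real_, dim = c(length(mods), nat, 3L))
  for (k in seq_along(mods)) {
    m <- atoms[atoms$model == mods[k], ]
    if (nrow(m) != nat) {
      abort(sprintf(
        "MODEL block %d has %d atoms; expected %d (first model) in %s",
        mods[k], nrow(m), nat, path), class = "btkloop_parse_error")
    }
    coords[k, , ] <- cbind(m$x, m$y, m$z)
  }
  md_trajectory(top, coords)
}

#' Write a trajectory (or single structure) as a PDB file
#'
#' Multi-frame trajectories are written as `MODEL`/`ENDMDL` blocks.
#' Coordinates are printed at the PDB's native 3-decimal precision.
#'
#' @param traj An [md_trajectory()] (a one-frame trajectory writes a plain
#'   single-model file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  top <- traj$topology
  nf <- n_frames(traj)
  pad_name <- function(nm) {
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  con <- file(path, "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(top$is_het, "HETATM", "ATOM"),
      top$serial, pad_name(top$name), "", substr(top$res_name, 1, 3),
      top$chain, top$res_seq, top$icode,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
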