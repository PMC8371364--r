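# CHARMM/NAMD binary DCD trajectories. The format is Fortran
# sequential-access: each record is framed by int32 byte counts. The header
# record carries the magic "CORD" tag and a 20-slot control block; frames are
# three float32 records (x, y, z), optionally preceded by a unit-cell record.

.dcd_read_record <- function(con, endian) {
  len <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (length(len) == 0) return(NULL)
  payload <- readBin(con, "raw", len)
  if (length(payload) < len) return(structure(payload, truncated = TRUE))
  tail_len <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (length(tail_len) == 0 || tail_len != len) {
    return(structure(payload, truncated = TRUE))
  }
  payload
}

#' Read a CHARMM/NAMD DCD trajectory
#'
#' Decodes all frames as 32-bit floats (Angstrom). Endianness is
#' auto-detected from the header's leading record length; byte-swapped files
#' produced on either architecture read identically. A unit-cell record per
#' frame (CHARMM crystal flag) is skipped if present.
#'
#' @param path Path to a DCD file.
#' @param topology An [md_topology()] whose atom count must match the file.
#' @return An [md_trajectory()]. Frame times (ns) are populated when the
#'   header's timestep and save interval are non-zero, assuming the
#'   AKMA-to-ps convention used by NAMD.
#' @export
read_dcd <- function(path, topology) {
  if (!file.exists(path)) {
    abort(sprintf("DCD file not found: %s", path), class = "btkloop_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))

  first <- readBin(con, "raw", 4)
  if (length(first) < 4) {
    abort(sprintf("Not a DCD file (truncated header): %s", path),
          class = "btkloop_parse_error")
  }
  endian <- NULL
  for (e in c("little", "big")) {
    if (readBin(first, "integer", 1, size = 4, endian = e) == 84L) endian <- e
  }
  if (is.null(endian)) {
    abort(sprintf("Not a DCD file (header record is not 84 bytes): %s", path),
          class = "btkloop_parse_error")
  }
  hdr <- readBin(con, "raw", 84)
  readBin(con, "integer", 1, size = 4, endian = endian)  # trailing length
  if (rawToChar(hdr[1:4]) != "CORD") {
    abort(sprintf("Not a coordinate DCD (missing CORD magic): %s", path),
          class = "btkloop_parse_error")
  }
  icntrl <- readBin(hdr[-(1:4)], "integer", 20, size = 4, endian = endian)
  crystal <- icntrl[11] == 1L
  delta <- readBin(hdr[4 + (9 * 4 + 1):(10 * 4)], "numeric", 1, size = 4,
                   endian = endian)

  .dcd_read_record(con, endian)  # title block (ignored)
  natom_rec <- .dcd_read_record(con, endian)
  natom <- readBin(natom_rec, "integer", 1, size = 4, endian = endian)
  if (natom != nrow(topology)) {
    abort(sprintf("DCD has %d atoms but topology has %d (%s).",
                  natom, nrow(topology), path),
          class = "btkloop_topology_mismatch")
  }

  frames <- list()
  repeat {
    if (crystal) {
      cell <- .dcd_read_record(con, endian)
      if (is.null(cell)) break
    }
    xyz <- vector("list", 3)
    ok <- TRUE
    for (d in 1:3) {
      rec <- .dcd_read_record(con, endian)
      if (is.null(rec) || isTRUE(attr(rec, "truncated")) ||
          length(rec) != 4L * natom) {
        ok <- FALSE
        break
      }
      xyz[[d]] <- readBin(rec, "numeric", natom, size = 4, endian = endian)
    }
    if (!ok) {
      if (d > 1 || !is.null(rec)) {
        abort(sprintf(
          "Truncated DCD frame in %s; %d complete frame(s) recovered.",
          path, length(frames)), class = "btkloop_partial_file")
      }
      break
    }
    frames[[length(frames) + 1L]] <- do.call(cbind, xyz)
  }
  if (length(frames) == 0) {
    abort(sprintf("DCD contains no complete frames: %s", path),
          class = "btkloop_partial_file")
  }
  coords <- array(NA_real_, dim = c(length(frames), natom, 3L))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  time_ns <- NULL
  if (is.finite(delta) && delta > 0 && icntrl[3] > 0) {
    # AKMA time unit = 0.0488882 ps; NAMD writes delta in AKMA units
    dt_ns <- delta * 0.0488882 * icntrl[3] / 1000
    time_ns <- (icntrl[2] + icntrl[3] * (seq_along(frames) - 1)) /
      icntrl[3] * dt_ns
  }
  md_trajectory(topology, coords, time_ns)
}

#' Write a trajectory as a CHARMM/NAMD DCD file
#'
#' Coordinates are stored as 32-bit floats, so a write-then-read round trip
#' preserves them to about 1e-5 Angstrom.
#'
#' @param traj An [md_trajectory()].
#' @param path Output path.
#' @param endian Byte order to write (`"little"` default; `"big"` produces a
#'   byte-swapped file that [read_dcd()] auto-detects).
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path, endian = c("little", "big")) {
  endian <- match.arg(endian)
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  nat <- n_atoms(traj)
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = endian)
  wfloat <- function(x) writeBin(as.numeric(x), con, size = 4, endian = endian)

  wint(84L)
  writeBin(charToRaw("CORD"), con)
  wint(c(nf, 0L, 1L, nf, 0L, 0L, 0L, 3L * nat, 0L))  # icntrl 1..9
  wfloat(0)                                           # icntrl 10: delta
  wint(c(0L, rep(0L, 8L), 24L))                       # icntrl 11..20
  wint(84L)

  title <- sprintf("%-80s", "Synthetic trajectory written by btkloop")
  wint(4L + 80L)
  wint(1L)
  writeBin(charToRaw(title), con)
  wint(4L + 80L)

  wint(4L); wint(nat); wint(4L)

  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (d in 1:3) {
      wint(4L * nat)
      wfloat(xyz[, d])
      wint(4L * nat)
    }
  }
  invisible(path)
}
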