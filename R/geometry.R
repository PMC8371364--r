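#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired point sets. Reflections are excluded:
#' when the optimal orthogonal transform would be improper, the sign of the
#' smallest singular direction is flipped, yielding the best proper rotation.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom), `n >= 3`.
#' @param weights Optional non-negative per-atom weights.
#' @return A list of class `superposition` with elements `rotation` (3x3,
#'   determinant +1), `translation` (length-3, Angstrom) and `rmsd_min`
#'   (Angstrom). The transform maps mobile onto reference as
#'   `x %*% t(rotation) + translation` for row-vector coordinates.
#' @examples
#' p <- matrix(rnorm(18), ncol = 3)
#' kabsch_superpose(p, p)$rmsd_min
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n) {
    abort("Superposition needs two matched point sets with n >= 3.",
          class = "btkloop_degenerate_geometry")
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    abort("Weights must be non-negative with positive sum.",
          class = "btkloop_degenerate_geometry")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  # rank-deficiency (all points collinear) leaves the rotation about the
  # line undetermined
  if (sum(svd(P)$d > 1e-8 * max(1, max(abs(P)))) < 2 ||
      sum(svd(Q)$d > 1e-8 * max(1, max(abs(Q)))) < 2) {
    abort("Degenerate (collinear) point configuration for superposition.",
          class = "btkloop_degenerate_geometry")
  }
  H <- crossprod(P * w, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = trans, rmsd_min = rmsd),
            class = "superposition")
}

.sel_coords <- function(traj, selection) {
  traj$coords[, selection, , drop = FALSE]
}

.resolve_selection <- function(traj, selection, atom_class = "CA",
                               regions = btk_default_regions()) {
  if (is.null(selection)) {
    sel <- which(!traj$topology$is_het &
                   switch(atom_class,
                          CA = traj$topology$name == "CA",
                          backbone = traj$topology$name %in%
                            c("N", "CA", "C", "O"),
                          heavy = traj$topology$element != "H",
                          all = TRUE))
    return(structure(sel, label = sprintf("protein/%s", atom_class)))
  }
  if (is.character(selection) ||
      (is.numeric(selection) && length(selection) <= 2 &&
       is.null(attr(selection, "label")))) {
    return(select_atoms(traj$topology, selection, atom_class,
                        regions = regions))
  }
  as.integer(selection)
}

#' Per-frame RMSD after superposition
#'
#' Each frame's selected atoms are superposed (Kabsch, unweighted) onto the
#' reference before the RMSD is taken over the same selection, so the series
#' reports internal deformation, not rigid-body drift. The value at the
#' reference frame is exactly 0.
#'
#' @param traj An [md_trajectory()].
#' @param selection Atom selection: an index vector from [select_atoms()], a
#'   region name, a residue range, or `NULL` for all protein atoms of
#'   `atom_class`.
#' @param reference Reference frame index (default 1, the first analysed
#'   frame) or `"mean"` for the mean structure.
#' @param atom_class Atom class used when `selection` names a region.
#' @param regions Region set for name resolution.
#' @return A tibble `(frame, time_ns, metric, value, units)`, value in
#'   Angstrom.
#' @export
rmsd_series <- function(traj, selection = NULL, reference = 1,
                        atom_class = "backbone",
                        regions = btk_default_regions()) {
  sel <- .resolve_selection(traj, selection, atom_class, regions)
  if (length(sel) < 3) {
    abort("RMSD needs a selection of at least 3 atoms.",
          class = "btkloop_degenerate_geometry")
  }
  xyz <- .sel_coords(traj, sel)
  ref <- if (identical(reference, "mean")) {
    apply(xyz, c(2, 3), mean)
  } else {
    if (reference < 1 || reference > n_frames(traj)) {
      abort(sprintf("Reference frame %s does not exist.", reference),
            class = "btkloop_frame_error")
    }
    matrix(xyz[reference, , ], ncol = 3)
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(matrix(xyz[f, , ], ncol = 3), ref)$rmsd_min
  }, 1.0)
  .metric_tibble(traj, sprintf("rmsd[%s]", attr(sel, "label") %||% "custom"),
                 vals, "angstrom")
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its mean
#' position, after superposing every frame onto the ensemble mean structure
#' (the mean is recomputed once after realignment — a single refinement
#' pass). One value per residue; when the selection holds several atoms of a
#' residue their mean-square fluctuations are averaged, so the conventional
#' C-alpha profile is obtained by selecting C-alpha atoms (the default).
#'
#' @inheritParams rmsd_series
#' @return A tibble `(chain, res_seq, res_name, value, units)`, value in
#'   Angstrom.
#' @export
rmsf_profile <- function(traj, selection = NULL, atom_class = "CA",
                         regions = btk_default_regions()) {
  if (n_frames(traj) < 2) {
    abort("RMSF needs at least 2 frames.", class = "btkloop_insufficient_frames")
  }
  sel <- .resolve_selection(traj, selection, atom_class, regions)
  if (length(sel) < 3) {
    abort("RMSF needs a selection of at least 3 atoms.",
          class = "btkloop_degenerate_geometry")
  }
  xyz <- .sel_coords(traj, sel)
  nf <- dim(xyz)[1]
  align_to <- function(ref) {
    out <- xyz
    for (f in seq_len(nf)) {
      fr <- matrix(xyz[f, , ], ncol = 3)
      sp <- kabsch_superpose(fr, ref)
      out[f, , ] <- fr %*% t(sp$rotation) +
        matrix(sp$translation, nrow(fr), 3, byrow = TRUE)
    }
    out
  }
  mean0 <- apply(align_to(matrix(xyz[1, , ], ncol = 3)), c(2, 3), mean)
  aligned <- align_to(mean0)
  mean1 <- apply(aligned, c(2, 3), mean)
  dev2 <- sweep(aligned, c(2, 3), mean1)^2
  msf <- apply(dev2, 2, sum) / nf  # per-atom mean squared fluctuation
  top <- traj$topology[sel, ]
  prof <- tibble(chain = top$chain, res_seq = top$res_seq,
                 res_name = top$res_name, msf = msf)
  prof <- dplyr::summarise(
    dplyr::group_by(prof, .data$chain, .data$res_seq, .data$res_name),
    value = sqrt(mean(.data$msf)), .groups = "drop")
  prof <- dplyr::arrange(prof, .data$chain, .data$res_seq)
  prof$metric <- "rmsf"
  prof$units <- "angstrom"
  prof[, c("chain", "res_seq", "res_name", "metric", "value", "units")]
}

#' Radius-of-gyration time series
#'
#' `Rgyr = sqrt( sum_i w_i |r_i - r_centroid|^2 / sum_i w_i )` over the
#' selection, per frame; weights are atomic masses by default (uniform by
#' flag). A compactness measure: larger values mean a more open structure.
#'
#' @inheritParams rmsd_series
#' @param mass_weighted Use atomic masses as weights (default) or uniform
#'   weights.
#' @return A tibble `(frame, time_ns, metric, value, units)`, Angstrom.
#' @export
rgyr_series <- function(traj, selection = NULL, mass_weighted = TRUE,
                        atom_class = "backbone",
                        regions = btk_default_regions()) {
  sel <- .resolve_selection(traj, selection, atom_class, regions)
  w <- if (mass_weighted) traj$topology$mass[sel] else rep(1, length(sel))
  w <- w / sum(w)
  xyz <- .sel_coords(traj, sel)
  vals <- vapply(seq_len(dim(xyz)[1]), function(f) {
    fr <- matrix(xyz[f, , ], ncol = 3)
    ctr <- colSums(fr * w)
    sqrt(sum(w * rowSums(sweep(fr, 2, ctr)^2)))
  }, 1.0)
  .metric_tibble(traj, sprintf("rgyr[%s]", attr(sel, "label") %||% "custom"),
                 vals, "angstrom")
}

.anchor_index <- function(traj, spec, regions, atom_class) {
  if (is.numeric(spec)) {
    return(select_atoms(traj$topology, c(spec[1], spec[1]), atom_class,
                        regions = regions)[1])
  }
  select_atoms(traj$topology, spec, atom_class, regions = regions)[1]
}

#' Angle between two lines sharing a vertex, per frame
#'
#' The angle between the lines vertex->b and vertex->c, in degrees within
#' `[0, 180]`. The default anchors quantify how close the DFG motif sits to
#' the beta6/beta7 sheet in BTK: one line from Leu518 (beta6) to Asn526
#' (beta7), the other from Leu518 to Asp539 in the DFG motif, each taken at
#' the residue's C-alpha atom.
#'
#' @param traj An [md_trajectory()].
#' @param vertex,end_b,end_c Residue numbers or region names resolved to a
#'   single atom of `atom_class`.
#' @param atom_class Atom whose position represents each residue
#'   (`"CA"` default).
#' @param regions Region set for anchor resolution.
#' @return A tibble `(frame, time_ns, metric, value, units)`, degrees.
#' @export
line_angle_series <- function(traj, vertex = "leu518", end_b = "asn526",
                              end_c = "asp539", atom_class = "CA",
                              regions = btk_default_regions()) {
  iv <- .anchor_index(traj, vertex, regions, atom_class)
  ib <- .anchor_index(traj, end_b, regions, atom_class)
  ic <- .anchor_index(traj, end_c, regions, atom_class)
  v <- traj$coords[, iv, , drop = FALSE]
  u1 <- traj$coords[, ib, , drop = FALSE] - v
  u2 <- traj$coords[, ic, , drop = FALSE] - v
  u1 <- matrix(u1, ncol = 3); u2 <- matrix(u2, ncol = 3)
  n1 <- sqrt(rowSums(u1^2)); n2 <- sqrt(rowSums(u2^2))
  if (any(n1 < 1e-9) || any(n2 < 1e-9)) {
    abort("Zero-length arm: angle atoms coincide in at least one frame.",
          class = "btkloop_degenerate_geometry")
  }
  cosang <- pmin(1, pmax(-1, rowSums(u1 * u2) / (n1 * n2)))
  .metric_tibble(traj, "line_angle", acos(cosang) * 180 / pi, "degrees")
}

#' DFG-to-ATP-site centroid distance, per frame
#'
#' Distance between the centre of the DFG motif and the centre of the ATP
#' binding site, the latter taken as the midpoint between the P-loop and
#' hinge-region centroids. Centroids are unweighted over the C-alpha atoms
#' of each region by default; heavy-atom centroids by flag.
#'
#' @param traj An [md_trajectory()].
#' @param regions Region set providing `dfg`, `p_loop` and `hinge`.
#' @param atom_class Atoms used for the centroids (`"CA"` default,
#'   `"heavy"` available).
#' @return A tibble `(frame, time_ns, metric, value, units)`, Angstrom.
#' @export
dfg_atp_distance_series <- function(traj, regions = btk_default_regions(),
                                    atom_class = c("CA", "heavy")) {
  atom_class <- match.arg(atom_class)
  cent <- function(region) {
    sel <- select_atoms(traj$topology, region, atom_class, regions = regions)
    apply(.sel_coords(traj, sel), c(1, 3), mean)  # frames x 3
  }
  cd <- cent("dfg")
  site <- (cent("p_loop") + cent("hinge")) / 2
  vals <- sqrt(rowSums((cd - site)^2))
  .metric_tibble(traj, "dfg_atp_distance", vals, "angstrom")
}
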