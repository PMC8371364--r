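# Shrake-Rupley solvent-accessible surface area. Each atom's van der Waals
# sphere is inflated by the probe radius and covered with a deterministic
# Fibonacci-spiral point lattice; the accessible area is the exposed-point
# fraction times the inflated sphere's area. A cell list restricts the
# burial test to geometrically possible neighbours; a brute-force mode with
# no spatial acceleration exists as an oracle and gives identical results
# for the same lattice.

#' Deterministic quasi-uniform sphere lattice
#'
#' Fibonacci (golden-angle) spiral points on the unit sphere. Deterministic,
#' so surface areas are exactly reproducible run to run.
#'
#' @param n Number of points.
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (2 - (1 + sqrt(5)) / 2)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.sasa_radii_for <- function(topology, radii) {
  r <- unname(radii[topology$element])
  if (anyNA(r)) {
    bad <- topology[is.na(r), ]
    abort(sprintf(
      "No van der Waals radius for atom %s (%s %s%d, element '%s').",
      bad$name[1], bad$res_name[1], bad$chain[1], bad$res_seq[1],
      bad$element[1]), class = "btkloop_radii_coverage")
  }
  r
}

# exposed-point fraction for target atoms given candidate neighbour sets
.sasa_areas <- function(xyz, R, targets, pts, neighbours_of) {
  np <- nrow(pts)
  areas <- numeric(length(targets))
  for (k in seq_along(targets)) {
    i <- targets[k]
    nb <- neighbours_of(i)
    if (length(nb) == 0) {
      areas[k] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    cn <- xyz[nb, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rep(1, length(nb))) +
      outer(rep(1, np), rowSums(cn^2)) - 2 * (p %*% t(cn))
    buried <- rowSums(d2 < matrix(R[nb]^2, np, length(nb),
                                  byrow = TRUE)) > 0
    areas[k] <- mean(!buried) * 4 * pi * R[i]^2
  }
  areas
}

# Rotate coordinates into the structure's principal-axis frame, with signs
# fixed by the third moment of each projection, so the point lattice is
# effectively molecule-fixed: areas are then invariant under any rigid
# motion of the input (up to principal-moment degeneracies, which generic
# structures do not have).
.canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  M <- sweep(xyz, 2, ctr)
  V <- eigen(crossprod(M) / nrow(M), symmetric = TRUE)$vectors
  P <- M %*% V
  for (k in 1:3) {
    s <- sum(P[, k]^3)
    if (s < 0) {
      V[, k] <- -V[, k]
      P[, k] <- -P[, k]
    }
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  M %*% V
}

.cell_list <- function(xyz, L) {
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / L)
  id <- paste(key[, 1], key[, 2], key[, 3])
  cells <- split(seq_len(nrow(xyz)), id)
  list(key = key, cells = cells)
}

#' Solvent-accessible surface area of one frame
#'
#' Shrake-Rupley SASA with a probe sphere (default radius 1.4 Angstrom, a
#' water molecule) and a deterministic spiral lattice of `n_points` per
#' atom. Hydrogens are excluded by default; the probe-inflated radii come
#' from [default_vdw_radii()] keyed by element and can be overridden.
#'
#' @param traj An [md_trajectory()] (or a single-frame trajectory).
#' @param frame Frame index to analyse.
#' @param radii Named radius vector (Angstrom) keyed by element.
#' @param probe Probe radius, Angstrom.
#' @param n_points Lattice points per atom (>= 32); default 960.
#' @param include_hydrogens Include hydrogen atoms as both surface and
#'   occluders.
#' @param method `"cell"` (cell-list neighbour search) or `"brute"`
#'   (all-pairs oracle); both give identical areas.
#' @param subset Optional integer vector of topology row indices: compute
#'   areas only for these atoms (the whole structure still occludes).
#' @param canonical Compute in the structure's principal-axis frame
#'   (default), making areas invariant under rigid motions of the input.
#'   With `canonical = FALSE` the lattice is fixed in the laboratory frame;
#'   at a fixed pose, removing an occluder then never decreases any area.
#' @return A list of class `sasa_result`: `$atom` (tibble with per-atom
#'   areas, Angstrom^2), `$residue` (per-residue sums), `$total`.
#' @examples
#' top <- make_toy_topology(2)
#' res <- sasa_frame(top, n_points = 64)
#' res$total
#' @export
sasa_frame <- function(traj, frame = 1, radii = default_vdw_radii(),
                       probe = 1.4, n_points = 960,
                       include_hydrogens = FALSE,
                       method = c("cell", "brute"), subset = NULL,
                       canonical = TRUE) {
  method <- match.arg(method)
  if (n_points < 32) {
    abort("n_points must be at least 32.", class = "btkloop_sasa_error")
  }
  top <- traj$topology
  keep <- if (include_hydrogens) rep(TRUE, nrow(top)) else top$element != "H"
  idx <- which(keep)
  xyz <- frame_coords(traj, frame)[idx, , drop = FALSE]
  if (canonical && nrow(xyz) > 2) xyz <- .canonical_frame(xyz)
  subtop <- top[idx, ]
  R <- .sasa_radii_for(subtop, radii) + probe
  pts <- fibonacci_sphere(n_points)
  n <- nrow(xyz)

  if (method == "brute") {
    neighbours_of <- function(i) {
      d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
      setdiff(which(d2 < (R[i] + R)^2), i)
    }
  } else {
    L <- 2 * max(R)
    cl <- .cell_list(xyz, L)
    neighbours_of <- function(i) {
      k <- cl$key[i, ]
      cand <- unlist(cl$cells[paste(rep(k[1] + (-1:1), each = 9),
                                    rep(rep(k[2] + (-1:1), each = 3), 3),
                                    rep(k[3] + (-1:1), 9))],
                     use.names = FALSE)
      d2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2)
      setdiff(cand[d2 < (R[i] + R[cand])^2], i)
    }
  }

  targets <- if (is.null(subset)) seq_len(n) else {
    t0 <- match(intersect(as.integer(subset), idx), idx)
    if (length(t0) == 0) {
      abort("SASA subset selects no included atoms.",
            class = "btkloop_empty_selection")
    }
    t0
  }
  area <- .sasa_areas(xyz, R, targets, pts, neighbours_of)
  subtop <- subtop[targets, ]
  atom <- tibble(
    serial = subtop$serial, name = subtop$name, element = subtop$element,
    chain = subtop$chain, res_seq = subtop$res_seq,
    res_name = subtop$res_name, area = area
  )
  res <- dplyr::summarise(
    dplyr::group_by(atom, .data$chain, .data$res_seq, .data$res_name),
    area = sum(.data$area), .groups = "drop")
  structure(list(atom = atom, residue = res, total = sum(area)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, %d residues, total %.2f A^2\n",
              nrow(x$atom), nrow(x$residue), x$total))
  invisible(x)
}

#' Region SASA time series and its time average
#'
#' Per frame, the summed solvent-accessible area of every residue in the
#' region (all the region's non-hydrogen atoms, with the full structure as
#' occluder); used e.g. for the exposure of the A-loop C-terminus (residues
#' 550-558) and of Tyr551. The returned tibble carries the time mean and
#' standard deviation as attributes `mean` and `sd`.
#'
#' @param traj An [md_trajectory()].
#' @param region Region name or residue range.
#' @inheritParams sasa_frame
#' @param regions Region set for name resolution.
#' @return A tibble `(frame, time_ns, metric, value, units)` in Angstrom^2,
#'   with attributes `mean` and `sd`.
#' @export
sasa_region_series <- function(traj, region, radii = default_vdw_radii(),
                               probe = 1.4, n_points = 960,
                               include_hydrogens = FALSE,
                               regions = btk_default_regions()) {
  rng <- .region_range(region, regions)
  sub <- select_atoms(traj$topology, region, "heavy", regions = regions)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    sr <- sasa_frame(traj, f, radii = radii, probe = probe,
                     n_points = n_points,
                     include_hydrogens = include_hydrogens,
                     subset = sub)
    sum(sr$atom$area)
  }, 1.0)
  out <- .metric_tibble(
    traj,
    sprintf("sasa[%s]", if (is.character(region)) region else
      sprintf("%d-%d", rng$first, rng$last)),
    vals, "angstrom^2")
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- sd(vals)
  out
}
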