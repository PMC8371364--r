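# Geometric hydrogen-bond and salt-bridge detection. A hydrogen bond is
# present when the donor-acceptor distance is below 3.5 Angstrom and the
# donor-hydrogen-acceptor angle criterion (< 30 degrees) holds; a salt
# bridge when any basic-nitrogen / acidic-oxygen pair is closer than
# 4.0 Angstrom. Occupancy ("survival") is the percentage of frames in which
# the interaction is present.

#' Hydrogen-bond detection criteria
#'
#' @param da_cutoff Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cutoff Angle cutoff, degrees (default 30).
#' @param angle_mode `"deviation"` (default): the angle between the D->H and
#'   D->A vectors, i.e. the deviation of the hydrogen from the donor-acceptor
#'   axis, must be below the cutoff — the common trajectory-analysis
#'   convention. `"literal"`: the interior D-H-A angle itself must be below
#'   the cutoff (geometrically almost never satisfied for a real hydrogen
#'   bond; provided for comparison).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(da_cutoff = 3.5, angle_cutoff = 30,
                           angle_mode = c("deviation", "literal")) {
  stopifnot(da_cutoff > 0, angle_cutoff > 0)
  structure(list(da_cutoff = da_cutoff, angle_cutoff = angle_cutoff,
                 angle_mode = match.arg(angle_mode)),
            class = "hbond_criteria")
}

#' Salt-bridge detection criteria
#'
#' @param no_cutoff Nitrogen-oxygen distance cutoff, Angstrom (default 4.0).
#' @param include_his Count histidine ND1/NE2 as basic nitrogens
#'   (protonation-dependent; off by default).
#' @return A list of class `saltbridge_criteria` carrying the basic/acidic
#'   atom tables (Lys NZ; Arg NE/NH1/NH2; Asp OD1/OD2; Glu OE1/OE2).
#' @export
saltbridge_criteria <- function(no_cutoff = 4.0, include_his = FALSE) {
  stopifnot(no_cutoff > 0)
  basic <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (include_his) basic$HIS <- c("ND1", "NE2")
  structure(list(no_cutoff = no_cutoff, basic = basic,
                 acidic = list(ASP = c("OD1", "OD2"),
                               GLU = c("OE1", "OE2"))),
            class = "saltbridge_criteria")
}

# hydrogens covalently assigned to the nearest N/O/S donor within 1.25 A
.assign_hydrogens <- function(topology, xyz) {
  h <- which(topology$element == "H")
  heavy <- which(topology$element %in% c("N", "O", "S"))
  if (length(h) == 0 || length(heavy) == 0) {
    return(tibble(h = integer(), donor = integer()))
  }
  donor <- vapply(h, function(i) {
    d2 <- rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[i, ])^2)
    j <- which.min(d2)
    if (d2[j] <= 1.25^2) heavy[j] else NA_integer_
  }, 1L)
  tibble(h = h[!is.na(donor)], donor = donor[!is.na(donor)])
}

.res_key <- function(topology) {
  paste(topology$chain, topology$res_seq, topology$icode, sep = "|")
}

#' Detect hydrogen bonds in one frame
#'
#' Reports every donor/hydrogen/acceptor triple satisfying the criteria.
#' Donors are N/O/S atoms bearing at least one covalent hydrogen; acceptors
#' are N/O/S atoms. Pairs within one residue, and adjacent backbone
#' amide-carbonyl (i, i+1 N-O) pairs, are excluded.
#'
#' @param traj An [md_trajectory()].
#' @param frame Frame index.
#' @param criteria An [hbond_criteria()].
#' @param donors,acceptors Optional atom-index vectors restricting the
#'   search scope (e.g. protein-only or ligand-only).
#' @param distance_only If `TRUE`, the angle criterion is skipped and donors
#'   need no hydrogens (for heavy-atom-only structures). If `FALSE`, a donor
#'   candidate without a resolvable hydrogen raises a missing-hydrogen
#'   error.
#' @param missing_hydrogen `"error"` (default) or `"skip"`: what to do when
#'   no donor in scope carries a hydrogen in angle mode. Skipping treats the
#'   scope as having no donors (used for ligand scopes that may have no
#'   donatable hydrogens).
#' @return A tibble with one row per bond: donor/hydrogen/acceptor atom row
#'   indices, residue identities on both sides, the D-A distance and the
#'   angle (degrees; `NA` in distance-only mode).
#' @export
detect_hbonds_frame <- function(traj, frame = 1, criteria = hbond_criteria(),
                                donors = NULL, acceptors = NULL,
                                distance_only = FALSE,
                                missing_hydrogen = c("error", "skip")) {
  missing_hydrogen <- match.arg(missing_hydrogen)
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  nos <- which(top$element %in% c("N", "O", "S"))
  hyd <- .assign_hydrogens(top, xyz)

  empty <- tibble(donor = integer(), hydrogen = integer(),
                  acceptor = integer(),
                  donor_res_seq = integer(), donor_res_name = character(),
                  acceptor_res_seq = integer(),
                  acceptor_res_name = character(),
                  distance = numeric(), angle = numeric())

  dcand <- intersect(nos, donors %||% nos)
  acand <- intersect(nos, acceptors %||% nos)
  if (!distance_only) {
    with_h <- unique(hyd$donor)
    no_h <- setdiff(dcand, with_h)
    dcand <- intersect(dcand, with_h)
    if (length(dcand) == 0 && length(no_h) > 0 &&
        missing_hydrogen == "error") {
      ex <- no_h[1]
      abort(sprintf(
        paste0("No donor in scope has a resolvable hydrogen (e.g. atom %s ",
               "of %s %d); add hydrogens or set distance_only = TRUE."),
        top$name[ex], top$res_name[ex], top$res_seq[ex]),
        class = "btkloop_missing_hydrogen")
    }
  }
  if (length(dcand) == 0 || length(acand) == 0) return(empty)

  key <- .res_key(top)
  D <- xyz[dcand, , drop = FALSE]
  A <- xyz[acand, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rep(1, nrow(A))) +
    outer(rep(1, nrow(D)), rowSums(A^2)) - 2 * D %*% t(A)
  d2[d2 < 0] <- 0
  hits <- which(d2 < criteria$da_cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)

  out <- vector("list", nrow(hits))
  for (r in seq_len(nrow(hits))) {
    di <- dcand[hits[r, 1]]
    ai <- acand[hits[r, 2]]
    if (key[di] == key[ai]) next
    # adjacent backbone amide-carbonyl pair
    if (top$name[di] == "N" && top$name[ai] == "O" &&
        top$chain[di] == top$chain[ai] &&
        abs(top$res_seq[di] - top$res_seq[ai]) == 1L) next
    dist <- sqrt(d2[hits[r, 1], hits[r, 2]])
    if (distance_only) {
      out[[r]] <- tibble(donor = di, hydrogen = NA_integer_, acceptor = ai,
                         distance = dist, angle = NA_real_)
      next
    }
    hs <- hyd$h[hyd$donor == di]
    ang <- vapply(hs, function(hh) {
      if (criteria$angle_mode == "deviation") {
        v1 <- xyz[hh, ] - xyz[di, ]
        v2 <- xyz[ai, ] - xyz[di, ]
      } else {
        v1 <- xyz[di, ] - xyz[hh, ]
        v2 <- xyz[ai, ] - xyz[hh, ]
      }
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }, 1.0)
    best <- which.min(ang)
    if (ang[best] < criteria$angle_cutoff) {
      out[[r]] <- tibble(donor = di, hydrogen = hs[best], acceptor = ai,
                         distance = dist, angle = ang[best])
    }
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty)
  out$donor_res_seq <- top$res_seq[out$donor]
  out$donor_res_name <- top$res_name[out$donor]
  out$acceptor_res_seq <- top$res_seq[out$acceptor]
  out$acceptor_res_name <- top$res_name[out$acceptor]
  out[, names(empty)]
}

#' Detect salt bridges in one frame
#'
#' A bridge is reported when any listed basic-nitrogen / acidic-oxygen pair
#' between two residues is closer than the cutoff; multiple qualifying atom
#' pairs collapse to one record carrying the minimum N-O distance.
#'
#' @inheritParams detect_hbonds_frame
#' @param criteria A [saltbridge_criteria()].
#' @return A tibble: basic residue, acidic residue, `min_distance`
#'   (Angstrom).
#' @export
detect_saltbridges_frame <- function(traj, frame = 1,
                                     criteria = saltbridge_criteria()) {
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  pick <- function(tab) {
    unlist(lapply(names(tab), function(rn) {
      which(top$res_name == rn & top$name %in% tab[[rn]])
    }))
  }
  bi <- pick(criteria$basic)
  ai <- pick(criteria$acidic)
  empty <- tibble(basic_res_seq = integer(), basic_res_name = character(),
                  acidic_res_seq = integer(), acidic_res_name = character(),
                  min_distance = numeric())
  if (length(bi) == 0 || length(ai) == 0) return(empty)
  B <- xyz[bi, , drop = FALSE]
  A <- xyz[ai, , drop = FALSE]
  d2 <- outer(rowSums(B^2), rep(1, nrow(A))) +
    outer(rep(1, nrow(B)), rowSums(A^2)) - 2 * B %*% t(A)
  d2[d2 < 0] <- 0
  hits <- which(d2 < criteria$no_cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  df <- tibble(
    basic_res_seq = top$res_seq[bi[hits[, 1]]],
    basic_res_name = top$res_name[bi[hits[, 1]]],
    acidic_res_seq = top$res_seq[ai[hits[, 2]]],
    acidic_res_name = top$res_name[ai[hits[, 2]]],
    distance = sqrt(d2[hits])
  )
  dplyr::summarise(
    dplyr::group_by(df, .data$basic_res_seq, .data$basic_res_name,
                    .data$acidic_res_seq, .data$acidic_res_name),
    min_distance = min(.data$distance), .groups = "drop")
}

.find_residue_atoms <- function(topology, res) {
  idx <- which(topology$res_seq == as.integer(res) & !topology$is_het)
  if (length(idx) == 0) {
    abort(sprintf("Residue %s not found in topology.", res),
          class = "btkloop_selection_error")
  }
  idx
}

#' Per-frame presence of one residue-pair interaction
#'
#' Tracks whether a specific hydrogen bond or salt bridge between two
#' residues is present in each frame. Any qualifying donor/acceptor (or
#' basic/acidic) atom combination between the two residues counts — backbone
#' and side chain are both eligible — and multiple simultaneous atom pairs
#' collapse to a single presence, matching the bond-survival semantics.
#'
#' @param traj An [md_trajectory()].
#' @param res_a,res_b Author residue numbers of the pair.
#' @param type `"hbond"` or `"saltbridge"`.
#' @param criteria An [hbond_criteria()] or [saltbridge_criteria()] matching
#'   `type`; defaults are constructed when `NULL`.
#' @param distance_only Passed to [detect_hbonds_frame()] for `type =
#'   "hbond"`.
#' @return A tibble `(frame, time_ns, bond, present)`; `bond` is a
#'   `"RES1-RES2"` label.
#' @export
bond_timeline <- function(traj, res_a, res_b,
                          type = c("hbond", "saltbridge"), criteria = NULL,
                          distance_only = FALSE) {
  type <- match.arg(type)
  top <- traj$topology
  ia <- .find_residue_atoms(top, res_a)
  ib <- .find_residue_atoms(top, res_b)
  label <- sprintf("%s%d-%s%d", top$res_name[ia[1]], as.integer(res_a),
                   top$res_name[ib[1]], as.integer(res_b))
  scope <- c(ia, ib)
  present <- vapply(seq_len(n_frames(traj)), function(f) {
    if (type == "hbond") {
      crit <- criteria %||% hbond_criteria()
      hb <- detect_hbonds_frame(traj, f, crit, donors = scope,
                                acceptors = scope,
                                distance_only = distance_only)
      any((hb$donor %in% ia & hb$acceptor %in% ib) |
            (hb$donor %in% ib & hb$acceptor %in% ia))
    } else {
      crit <- criteria %||% saltbridge_criteria()
      sb <- detect_saltbridges_frame(traj, f, crit)
      any((sb$basic_res_seq == res_a & sb$acidic_res_seq == res_b) |
            (sb$basic_res_seq == res_b & sb$acidic_res_seq == res_a))
    }
  }, TRUE)
  tibble(
    frame = seq_len(n_frames(traj)),
    time_ns = if (is.null(traj$time_ns)) NA_real_ else traj$time_ns,
    bond = label,
    present = present
  )
}

#' Bond occupancy (survival percentage)
#'
#' The proportion of frames, as a percentage, in which the interaction is
#' present — per run when a run grouping is given, with the cross-run mean
#' and standard deviation attached as attributes `mean` and `sd`.
#'
#' @param timeline A timeline tibble from [bond_timeline()] (columns `bond`,
#'   `present`, optionally `run`).
#' @param runs Optional vector (length = frames) assigning each frame to a
#'   run; overrides any `run` column.
#' @return A tibble `(bond, run, n_frames, occupancy)` with occupancy in
#'   percent; attributes `mean` and `sd` summarise across runs.
#' @export
occupancy <- function(timeline, runs = NULL) {
  if (nrow(timeline) == 0) {
    abort("Cannot compute occupancy of an empty timeline.",
          class = "btkloop_insufficient_frames")
  }
  tl <- timeline
  tl$run <- if (!is.null(runs)) {
    rep_len(runs, nrow(tl))
  } else if ("run" %in% names(timeline)) {
    timeline$run
  } else {
    1L
  }
  out <- dplyr::summarise(
    dplyr::group_by(tl, .data$bond, .data$run),
    n_frames = dplyr::n(),
    occupancy = 100 * mean(.data$present), .groups = "drop")
  attr(out, "mean") <- mean(out$occupancy)
  attr(out, "sd") <- if (nrow(out) > 1) sd(out$occupancy) else NA_real_
  out
}

#' Protein-ligand hydrogen-bond count per frame
#'
#' Counts hydrogen bonds between the protein and a hetero ligand (e.g. ATP)
#' in each frame, in either donor/acceptor direction, under the same
#' criteria as [detect_hbonds_frame()].
#'
#' @param traj An [md_trajectory()].
#' @param ligand Ligand residue name present as HETATM records (default
#'   `"ATP"`).
#' @param criteria An [hbond_criteria()].
#' @param distance_only Skip the angle criterion (for structures without
#'   hydrogens).
#' @param by_residue If `TRUE`, return instead the per-protein-residue
#'   attribution: a tibble of protein residues with the number of frames in
#'   which they bond the ligand.
#' @return A tibble `(frame, time_ns, metric, value, units)` of counts, or
#'   the attribution tibble when `by_residue = TRUE`.
#' @export
ligand_hbond_count_series <- function(traj, ligand = "ATP",
                                      criteria = hbond_criteria(),
                                      distance_only = FALSE,
                                      by_residue = FALSE) {
  top <- traj$topology
  lig <- which(top$res_name == ligand & top$is_het)
  if (length(lig) == 0) {
    abort(sprintf("Ligand residue '%s' not present in topology.", ligand),
          class = "btkloop_selection_error")
  }
  prot <- which(!top$is_het)
  per_frame <- purrr::map(seq_len(n_frames(traj)), function(f) {
    fwd <- detect_hbonds_frame(traj, f, criteria, donors = prot,
                               acceptors = lig,
                               distance_only = distance_only)
    rev <- detect_hbonds_frame(traj, f, criteria, donors = lig,
                               acceptors = prot,
                               distance_only = distance_only,
                               missing_hydrogen = "skip")
    fwd$protein_res_seq <- fwd$donor_res_seq
    fwd$protein_res_name <- fwd$donor_res_name
    rev$protein_res_seq <- rev$acceptor_res_seq
    rev$protein_res_name <- rev$acceptor_res_name
    dplyr::bind_rows(fwd, rev)
  })
  if (by_residue) {
    all <- dplyr::bind_rows(per_frame, .id = "frame")
    if (nrow(all) == 0) {
      return(tibble(res_seq = integer(), res_name = character(),
                    n_frames_bonded = integer()))
    }
    per <- dplyr::distinct(all, .data$frame, .data$protein_res_seq,
                           .data$protein_res_name)
    out <- dplyr::count(per, .data$protein_res_seq, .data$protein_res_name,
                        name = "n_frames_bonded")
    return(dplyr::rename(out, res_seq = "protein_res_seq",
                         res_name = "protein_res_name"))
  }
  .metric_tibble(traj, sprintf("hbonds[protein-%s]", ligand),
                 vapply(per_frame, nrow, 1L), "count")
}
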