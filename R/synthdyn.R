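# Synthetic topologies and trajectories with planted, machine-readable
# ground truth: per-residue Gaussian fluctuation amplitudes, Bernoulli
# bond-formation probabilities, rigid-body motions and three-atom angle
# series. These stand in for cluster-scale MD ensembles so every analysis
# stage can be tested against known answers. The dynamics are deliberately
# unphysical (no force field, no solvent); only the planted statistical
# properties are meaningful.

.backbone_template <- list(
  N  = c(0.00, 0.00, 0.00),
  CA = c(1.46, 0.00, 0.00),
  C  = c(2.45, 1.10, 0.00),
  O  = c(2.00, 2.20, 0.30)
)
.cb_offset <- c(0.0, -1.20, 0.90)  # from CA

# Residue origins trace a loose helical tube (radius 6 A, 0.6 rad per
# residue, 1.2 A rise): consecutive origins are ~3.7 A apart, like a real
# chain, and the trace spans all three dimensions, so superposition onto
# the ensemble is well-conditioned (an extended straight chain is nearly
# collinear and leaves the rotation about its axis undetermined).
.helix_origin <- function(i) {
  a <- 0.6 * (i - 1)
  c(6 * cos(a), 6 * sin(a), 1.2 * (i - 1))
}
.helix_radial <- function(i) {
  a <- 0.6 * (i - 1)
  c(cos(a), sin(a), 0)
}

.side_chain_offsets <- list(  # from CB
  SER = list(OG = c(0.0, -1.00, 1.05)),
  THR = list(OG1 = c(0.6, -1.00, 1.00), CG2 = c(-0.8, -1.0, 1.0)),
  LEU = list(CG = c(0, -1.2, 1.0), CD1 = c(0.7, -2.1, 1.5),
             CD2 = c(-0.8, -2.0, 1.5)),
  MET = list(CG = c(0, -1.2, 1.0), SD = c(0, -2.3, 2.0),
             CE = c(0.8, -3.2, 2.6)),
  ASP = list(CG = c(0, -1.2, 1.0), OD1 = c(0.7, -2.1, 1.4),
             OD2 = c(-0.8, -2.0, 1.5)),
  ASN = list(CG = c(0, -1.2, 1.0), OD1 = c(0.7, -2.1, 1.4),
             ND2 = c(-0.8, -2.0, 1.5)),
  GLU = list(CG = c(0, -1.2, 1.0), CD = c(0, -2.3, 2.0),
             OE1 = c(0.7, -3.2, 2.5), OE2 = c(-0.8, -3.1, 2.6)),
  LYS = list(CG = c(0, -1.2, 1.0), CD = c(0, -2.3, 2.0),
             CE = c(0, -3.4, 2.9), NZ = c(0, -4.4, 3.7)),
  ARG = list(CG = c(0, -1.2, 1.0), CD = c(0, -2.3, 2.0),
             NE = c(0, -3.3, 2.8), CZ = c(0, -4.4, 3.5),
             NH1 = c(0.9, -5.2, 3.9), NH2 = c(-1.0, -5.1, 4.0)),
  TYR = list(CG = c(0, -1.2, 1.0), CZ = c(0, -3.0, 2.5),
             OH = c(0, -4.2, 3.3))
)
.polar_h_parents <- c("OG", "OG1", "NZ", "NE", "NH1", "NH2", "ND2", "OH")

.ligand_offsets <- list(  # ATP-like phosphate/adenine fragment
  PG = c(0, 0, 0), O1G = c(1.45, 0.3, 0), O2G = c(-0.8, 1.25, 0),
  O3G = c(-0.6, -1.25, 0.4), PB = c(0.4, 0.4, 2.9),
  O1B = c(1.6, 0.9, 3.3), N1 = c(-2.5, 0.5, 5.0), C2 = c(-3.3, 1.3, 5.7),
  N6 = c(-2.9, -1.6, 4.6)
)

#' Build a toy peptide topology with ideal local geometry
#'
#' A peptide whose residue origins trace a loose helical tube (so the
#' structure spans all three dimensions and superposition onto it is
#' well-conditioned), with backbone `N, CA, C, O` per residue, an
#' amide hydrogen on every backbone nitrogen except the first when
#' requested, `CB` plus minimal polar side chains for non-glycine residues
#' (Ser, Thr, Leu, Met, Asp, Asn, Glu, Lys, Arg, Tyr have their functional
#' atoms), and optionally one ATP-like hetero residue placed near a
#' designated site. Residue numbering starts at `first_res`, so the BTK
#' author numbering (389...) can be mimicked directly.
#'
#' @param n_residues Number of residues (>= 1).
#' @param with_hydrogens Add amide and polar side-chain hydrogens.
#' @param with_ligand Add one ATP-like HETATM residue (res_name `"ATP"`).
#' @param first_res Author number of the first residue.
#' @param sequence Optional character vector of 3-letter codes (recycled);
#'   defaults to a mixed Ala-rich sequence.
#' @param chain Chain identifier.
#' @param ligand_site Residue number near whose CA the ligand is placed
#'   (default: the middle residue).
#' @return A one-frame [md_trajectory()]; frame 1 holds the base
#'   coordinates.
#' @examples
#' make_toy_topology(3)
#' @export
make_toy_topology <- function(n_residues, with_hydrogens = FALSE,
                              with_ligand = FALSE, first_res = 1L,
                              sequence = NULL, chain = "A",
                              ligand_site = NULL) {
  stopifnot(n_residues >= 1)
  if (is.null(sequence)) {
    sequence <- rep_len(c("ALA", "SER", "GLY", "LEU", "ASP", "LYS"),
                        n_residues)
  } else {
    sequence <- rep_len(toupper(sequence), n_residues)
  }
  rows <- list()
  add <- function(name, element, res_name, res_seq, het, pos) {
    rows[[length(rows) + 1L]] <<- list(name = name, element = element,
                                       res_name = res_name,
                                       res_seq = res_seq, het = het,
                                       pos = pos)
  }
  for (i in seq_len(n_residues)) {
    org <- .helix_origin(i)
    rn <- sequence[i]
    rs <- first_res + i - 1L
    for (nm in names(.backbone_template)) {
      add(nm, substr(nm, 1, 1), rn, rs, FALSE, org + .backbone_template[[nm]])
    }
    if (with_hydrogens && i > 1) {
      add("H", "H", rn, rs, FALSE, org + c(-0.50, -0.85, 0.00))
    }
    if (rn != "GLY") {
      cb <- org + .backbone_template$CA + .cb_offset
      add("CB", "C", rn, rs, FALSE, cb)
      for (nm in names(.side_chain_offsets[[rn]] %||% list())) {
        pos <- cb + .side_chain_offsets[[rn]][[nm]]
        add(nm, .element_from_name(nm), rn, rs, FALSE, pos)
        if (with_hydrogens && nm %in% .polar_h_parents) {
          add(paste0("H", substr(nm, 2, 4)), "H", rn, rs, FALSE,
              pos + c(0.33, -0.78, 0.45))
        }
      }
    }
  }
  if (with_ligand) {
    site <- ligand_site %||% (first_res + n_residues %/% 2)
    i <- site - first_res + 1
    ca <- .helix_origin(i) + .backbone_template$CA
    org <- ca + 5.5 * .helix_radial(i)
    for (nm in names(.ligand_offsets)) {
      add(nm, .element_from_name(nm), "ATP",
          first_res + n_residues, TRUE, org + .ligand_offsets[[nm]])
    }
  }
  name <- vapply(rows, `[[`, "", "name")
  top <- md_topology(
    serial = seq_along(rows), name = name,
    element = vapply(rows, `[[`, "", "element"),
    res_name = vapply(rows, `[[`, "", "res_name"),
    res_seq = as.integer(vapply(rows, `[[`, 1.0, "res_seq")),
    chain = chain, is_het = vapply(rows, `[[`, TRUE, "het"))
  coords <- do.call(rbind, lapply(rows, `[[`, "pos"))
  md_trajectory(top, coords)
}

.base_array <- function(base, n_frames) {
  nf0 <- n_frames(base)
  if (nf0 == 1L) {
    arr <- array(NA_real_, dim = c(n_frames, n_atoms(base), 3L))
    for (f in seq_len(n_frames)) arr[f, , ] <- base$coords[1, , ]
    arr
  } else {
    if (!is.null(n_frames) && n_frames != nf0) {
      abort("n_frames disagrees with the multi-frame base trajectory.",
            class = "btkloop_spec_error")
    }
    base$coords
  }
}

#' Plant per-residue Gaussian fluctuations
#'
#' Each frame is the base structure plus an independent Gaussian
#' displacement of every coordinate, with a per-residue standard deviation
#' applied to all of that residue's atoms. The closed-form expectation of
#' the resulting per-residue RMSF is `sigma * sqrt(3)`, which the analysis
#' side must recover. Deterministic for a given seed (Mersenne-Twister).
#'
#' @param base A one-frame [md_trajectory()] (e.g. [make_toy_topology()]).
#' @param sigma Per-residue standard deviation (Angstrom per coordinate);
#'   length must equal the residue count.
#' @param n_frames Number of frames.
#' @param seed Integer RNG seed, recorded in the output's `truth`.
#' @return An [md_trajectory()] with attribute `truth`, a list carrying
#'   `sigma` and `seed`.
#' @details Hydrogens ride along with their covalent parent (the nearest
#'   N/O/S within 1.25 Angstrom in the base structure): they receive the
#'   parent's displacement instead of an independent draw, so covalent
#'   geometry — and with it donor-hydrogen assignment — survives the
#'   planted noise.
#' @export
gen_fluctuation_traj <- function(base, sigma, n_frames, seed) {
  res <- residues(base$topology)
  if (length(sigma) != nrow(res)) {
    abort(sprintf("sigma has length %d but topology has %d residues.",
                  length(sigma), nrow(res)), class = "btkloop_spec_error")
  }
  if (any(sigma < 0)) {
    abort("sigma must be non-negative.", class = "btkloop_spec_error")
  }
  key <- .res_key(base$topology)
  rkey <- paste(res$chain, res$res_seq, res$icode, sep = "|")
  sig_atom <- sigma[match(key, rkey)]
  arr <- .base_array(base, n_frames)
  set.seed(seed, kind = "Mersenne-Twister")
  na <- n_atoms(base)
  hyd <- .assign_hydrogens(base$topology, frame_coords(base, 1))
  for (f in seq_len(n_frames)) {
    disp <- matrix(rnorm(3 * na, sd = sig_atom), na, 3)
    if (nrow(hyd) > 0) disp[hyd$h, ] <- disp[hyd$donor, ]
    arr[f, , ] <- arr[f, , ] + disp
  }
  out <- md_trajectory(base$topology, arr)
  attr(out, "truth") <- list(kind = "fluctuation", sigma = sigma,
                             seed = seed)
  out
}

#' Plant a random rigid-body motion per frame
#'
#' Each frame is the base structure under an independent proper rotation
#' (uniform over SO(3), via normalised quaternions) plus a random
#' translation. Every internal observable — RMSD after superposition,
#' radius of gyration, angles, distances, SASA — must be invariant on this
#' trajectory.
#'
#' @inheritParams gen_fluctuation_traj
#' @param max_shift Translations are drawn uniformly in
#'   `[-max_shift, max_shift]` per axis (Angstrom).
#' @return An [md_trajectory()] with attribute `truth` (list of per-frame
#'   rotations and translations, plus `seed`).
#' @export
gen_rigid_motion_traj <- function(base, n_frames, seed, max_shift = 10) {
  arr <- .base_array(base, n_frames)
  set.seed(seed, kind = "Mersenne-Twister")
  rots <- vector("list", n_frames)
  shifts <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    tr <- runif(3, -max_shift, max_shift)
    arr[f, , ] <- arr[f, , ] %*% t(R) +
      matrix(tr, n_atoms(base), 3, byrow = TRUE)
    rots[[f]] <- R; shifts[[f]] <- tr
  }
  out <- md_trajectory(base$topology, arr)
  attr(out, "truth") <- list(kind = "rigid", rotations = rots,
                             translations = shifts, seed = seed)
  out
}

# place the planted atoms of one bond into on- or off-geometry, relative to
# the current (possibly noisy) positions of the partner atoms
.apply_bond_state <- function(xyz, plan, on) {
  if (plan$type == "hbond") {
    dN <- xyz[plan$donor_n, ]
    dH <- xyz[plan$donor_h, ]
    u <- dH - dN; u <- u / sqrt(sum(u^2))
    # re-place the hydrogen at covalent distance along the same direction,
    # so the plant stays valid on noisy bases
    xyz[plan$donor_h, ] <- dN + 0.98 * u
    d <- if (on) plan$on_dist else plan$off_dist
    xyz[plan$acceptor, ] <- dN + d * u
    # noise can push a bystander N/O/S into the hydrogen's covalent shell,
    # which would steal the donor assignment; nudge such atoms clear
    h <- xyz[plan$donor_h, ]
    for (j in setdiff(plan$nos, c(plan$donor_n, plan$acceptor))) {
      v <- xyz[j, ] - h
      dj <- sqrt(sum(v^2))
      if (dj < 1.3) {
        xyz[j, ] <- if (dj < 1e-6) h + 1.45 * u else h + v * (1.45 / dj)
      }
    }
  } else {
    bN <- xyz[plan$basic_n, ]
    d <- if (on) plan$on_dist else plan$off_dist
    for (k in seq_along(plan$acidic_o)) {
      xyz[plan$acidic_o[k], ] <- bN + (d + 0.6 * (k - 1)) * plan$dir
    }
  }
  xyz
}

.bond_plan <- function(topology, res_a, res_b, type) {
  ia <- .find_residue_atoms(topology, res_a)
  ib <- .find_residue_atoms(topology, res_b)
  nm <- topology$name
  if (type == "hbond") {
    donor_n <- ia[nm[ia] == "N"][1]
    donor_h <- ia[nm[ia] == "H"][1]
    acceptor <- ib[nm[ib] == "O"][1]
    if (is.na(donor_n) || is.na(donor_h) || is.na(acceptor)) {
      abort(sprintf(
        "Cannot plant an H-bond between residues %d and %d: need backbone N+H and O (build the topology with_hydrogens = TRUE).",
        res_a, res_b), class = "btkloop_generation_error")
    }
    list(type = "hbond", donor_n = donor_n, donor_h = donor_h,
         acceptor = acceptor, on_dist = 2.9, off_dist = 6.0,
         nos = which(topology$element %in% c("N", "O", "S")))
  } else {
    basic <- ia[nm[ia] %in% c("NZ", "NH1", "NE")]
    acidic <- ib[nm[ib] %in% c("OD1", "OD2", "OE1", "OE2")]
    if (length(basic) == 0 || length(acidic) == 0) {
      # allow the pair in either order
      basic <- ib[nm[ib] %in% c("NZ", "NH1", "NE")]
      acidic <- ia[nm[ia] %in% c("OD1", "OD2", "OE1", "OE2")]
    }
    if (length(basic) == 0 || length(acidic) == 0) {
      abort(sprintf(
        "Cannot plant a salt bridge between residues %d and %d: need a basic (Lys/Arg) and an acidic (Asp/Glu) residue.",
        res_a, res_b), class = "btkloop_generation_error")
    }
    list(type = "saltbridge", basic_n = basic[1], acidic_o = acidic,
         dir = c(0, 1, 0) / 1, on_dist = 3.2, off_dist = 8.0)
  }
}

.assert_bond_states <- function(base, plan, res_a, res_b, type, criteria) {
  check <- function(on) {
    xyz <- .apply_bond_state(frame_coords(base, 1), plan, on)
    t1 <- md_trajectory(base$topology, xyz)
    tl <- bond_timeline(t1, res_a, res_b, type = type, criteria = criteria)
    tl$present[1]
  }
  if (!check(TRUE)) {
    abort("Planted on-geometry fails its own detection criterion.",
          class = "btkloop_generation_error")
  }
  if (check(FALSE)) {
    abort("Planted off-geometry satisfies the detection criterion.",
          class = "btkloop_generation_error")
  }
}

#' Plant a Bernoulli-toggled residue-pair bond
#'
#' In each frame the bond's planted atoms are placed in an on- or
#' off-geometry according to an independent Bernoulli(`p_on`) draw; the
#' ground-truth timeline is returned alongside the trajectory, and the
#' detector must reproduce it frame-exactly. Both geometries are asserted
#' against the detection criteria at generation time. H-bond plants move
#' the acceptor backbone O collinear with the donor's N-H (2.9 vs 6.0
#' Angstrom); salt-bridge plants move the acidic oxygens relative to the
#' basic nitrogen (3.2 vs 8.0 Angstrom).
#'
#' @param base A [md_trajectory()]; a multi-frame base (e.g. from
#'   [gen_fluctuation_traj()]) lets plants compose with planted noise, the
#'   planted atoms being re-placed after the noise.
#' @param res_a,res_b The residue pair (donor/basic first, or either order
#'   for salt bridges).
#' @param type `"hbond"` or `"saltbridge"`.
#' @param p_on Bernoulli probability of the bond being present per frame.
#' @param n_frames Number of frames (must match a multi-frame base).
#' @param seed Integer RNG seed.
#' @param criteria Detection criteria the plant must satisfy; defaults per
#'   `type`.
#' @return A list: `trajectory` (an [md_trajectory()]) and `timeline` (the
#'   ground-truth tibble `(frame, bond, present)`); also stored in the
#'   trajectory's `truth` attribute with `p_on` and `seed`.
#' @export
gen_bond_toggle_traj <- function(base, res_a, res_b,
                                 type = c("hbond", "saltbridge"),
                                 p_on, n_frames, seed, criteria = NULL) {
  type <- match.arg(type)
  stopifnot(p_on >= 0, p_on <= 1)
  criteria <- criteria %||%
    if (type == "hbond") hbond_criteria() else saltbridge_criteria()
  plan <- .bond_plan(base$topology, res_a, res_b, type)
  base1 <- md_trajectory(base$topology, frame_coords(base, 1))
  .assert_bond_states(base1, plan, res_a, res_b, type, criteria)
  arr <- .base_array(base, n_frames)
  set.seed(seed, kind = "Mersenne-Twister")
  draws <- runif(dim(arr)[1]) < p_on
  for (f in seq_len(dim(arr)[1])) {
    arr[f, , ] <- .apply_bond_state(arr[f, , ], plan, draws[f])
  }
  traj <- md_trajectory(base$topology, arr)
  top <- base$topology
  label <- sprintf("%s%d-%s%d",
                   top$res_name[.find_residue_atoms(top, res_a)[1]], res_a,
                   top$res_name[.find_residue_atoms(top, res_b)[1]], res_b)
  timeline <- tibble(frame = seq_along(draws), bond = label,
                     present = draws)
  attr(traj, "truth") <- list(kind = "bond_toggle", p_on = p_on,
                              timeline = timeline, seed = seed)
  list(trajectory = traj, timeline = timeline)
}

#' Plant an exact three-atom angle series
#'
#' Re-places the third anchor atom in each frame so that the angle at the
#' vertex between the two arms equals the requested value exactly, whatever
#' noise the base trajectory carries: the arm direction to `end_b` is
#' measured per frame and `end_c` is placed at `radius` Angstrom along a
#' direction rotated by the target angle within a fixed plane.
#'
#' @param base A [md_trajectory()].
#' @param angles_deg Per-frame target angles (degrees); its length sets the
#'   frame count.
#' @param vertex,end_b,end_c Residue numbers whose CA atoms form the angle.
#' @param radius Arm length for the re-placed atom (Angstrom).
#' @return An [md_trajectory()] with attribute `truth` carrying
#'   `angles_deg`.
#' @export
gen_angle_traj <- function(base, angles_deg, vertex, end_b, end_c,
                           radius = 6) {
  top <- base$topology
  ia <- .find_residue_atoms(top, vertex); ia <- ia[top$name[ia] == "CA"][1]
  ib <- .find_residue_atoms(top, end_b); ib <- ib[top$name[ib] == "CA"][1]
  ic <- .find_residue_atoms(top, end_c); ic <- ic[top$name[ic] == "CA"][1]
  nf <- length(angles_deg)
  arr <- .base_array(base, nf)
  for (f in seq_len(nf)) {
    v <- arr[f, ia, ]; bpos <- arr[f, ib, ]
    u1 <- bpos - v; u1 <- u1 / sqrt(sum(u1^2))
    ref <- if (abs(u1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u2 <- ref - sum(ref * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
    th <- angles_deg[f] * pi / 180
    arr[f, ic, ] <- v + radius * (cos(th) * u1 + sin(th) * u2)
  }
  out <- md_trajectory(top, arr)
  attr(out, "truth") <- list(kind = "angle", angles_deg = angles_deg)
  out
}
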