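# Hydrogen-bond and salt-bridge detection, timelines and occupancy.

# donor N (+H) in residue 1, acceptor O in residue 3, at a controllable
# geometry: d = donor-acceptor distance, bend = deviation of H from the
# D->A axis in degrees
dha_fixture <- function(d, bend = 0) {
  th <- bend * pi / 180
  h <- c(cos(th), sin(th), 0)  # 1.0 A from the donor
  point_topology(
    c("N", "H", "O"), c("N", "H", "O"), c(1L, 1L, 3L),
    rbind(c(0, 0, 0), h, c(d, 0, 0)))
}

test_that("the hydrogen-bond criteria gate distance and angle", {
  crit <- hbond_criteria()
  expect_equal(nrow(detect_hbonds_frame(dha_fixture(3.0), 1, crit)), 1)
  expect_equal(nrow(detect_hbonds_frame(dha_fixture(3.6), 1, crit)), 0)
  expect_equal(nrow(detect_hbonds_frame(dha_fixture(3.0, bend = 45), 1,
                                        crit)), 0)
  # just inside both cutoffs
  hb <- detect_hbonds_frame(dha_fixture(3.49, bend = 29), 1, crit)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 3.49)
  expect_equal(hb$angle, 29)
})

test_that("the literal interior-angle mode is a different convention", {
  # collinear D-H...A: deviation angle 0, interior D-H-A angle 180
  crit_dev <- hbond_criteria(angle_mode = "deviation")
  crit_lit <- hbond_criteria(angle_mode = "literal")
  expect_equal(nrow(detect_hbonds_frame(dha_fixture(3.0), 1, crit_dev)), 1)
  expect_equal(nrow(detect_hbonds_frame(dha_fixture(3.0), 1, crit_lit)), 0)
})

test_that("donors without hydrogens error unless distance-only", {
  fix <- point_topology(c("N", "O"), c("N", "O"), c(1L, 3L),
                        rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(detect_hbonds_frame(fix, 1),
               class = "btkloop_missing_hydrogen")
  hb <- detect_hbonds_frame(fix, 1, distance_only = TRUE)
  expect_equal(nrow(hb), 2)  # N->O and O->N, both within distance
})

test_that("salt bridges follow the minimum N-O distance rule", {
  mk <- function(d1, d2 = NULL) {
    names <- c("NH1", "OE1"); el <- c("N", "O")
    res <- c(1L, 5L); rn <- c("ARG", "GLU")
    xyz <- rbind(c(0, 0, 0), c(d1, 0, 0))
    if (!is.null(d2)) {
      names <- c("NZ", "OD1", "OD2"); el <- c("N", "O", "O")
      res <- c(1L, 5L, 5L); rn <- c("LYS", "ASP", "ASP")
      xyz <- rbind(c(0, 0, 0), c(d1, 0, 0), c(d2, 0, 0))
    }
    top <- md_topology(seq_along(names), names, el, rn, res, "A")
    md_trajectory(top, xyz)
  }
  expect_equal(nrow(detect_saltbridges_frame(mk(3.8), 1)), 1)
  expect_equal(nrow(detect_saltbridges_frame(mk(4.2), 1)), 0)
  sb <- detect_saltbridges_frame(mk(3.9, 3.5), 1)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$min_distance, 3.5)
})

test_that("detection equals the brute-force all-pairs oracle", {
  base <- make_toy_topology(12, with_hydrogens = TRUE)
  traj <- gen_fluctuation_traj(base, rep(0.8, 12), 8, seed = 19)
  for (f in 1:8) {
    got <- detect_hbonds_frame(traj, f)
    want <- hbond_bruteforce(traj, f)
    got_pairs <- unique(cbind(got$donor, got$acceptor))
    expect_equal(nrow(got_pairs), nrow(want))
    if (nrow(want) > 0) {
      o1 <- got_pairs[order(got_pairs[, 1], got_pairs[, 2]), , drop = FALSE]
      o2 <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(unname(o1), unname(o2))
    }
  }
})

test_that("loosening cutoffs never removes a detected bond", {
  base <- make_toy_topology(12, with_hydrogens = TRUE)
  traj <- gen_fluctuation_traj(base, rep(0.8, 12), 5, seed = 23)
  for (f in 1:5) {
    tight <- detect_hbonds_frame(traj, f, hbond_criteria(3.2, 25))
    loose <- detect_hbonds_frame(traj, f, hbond_criteria(3.8, 40))
    tight_id <- paste(tight$donor, tight$acceptor)
    loose_id <- paste(loose$donor, loose$acceptor)
    expect_true(all(tight_id %in% loose_id))
  }
})

test_that("bond timelines report exactly the planted frames", {
  base <- make_toy_topology(10, with_hydrogens = TRUE)
  plan <- btkloop:::.bond_plan(base$topology, 2, 8, "hbond")
  arr <- array(NA_real_, dim = c(10, n_atoms(base), 3))
  truth <- rep(c(TRUE, FALSE), each = 5)
  for (f in 1:10) {
    arr[f, , ] <- btkloop:::.apply_bond_state(frame_coords(base, 1), plan,
                                              truth[f])
  }
  traj <- md_trajectory(base$topology, arr)
  tl <- bond_timeline(traj, 2, 8, "hbond")
  expect_identical(tl$present, truth)

  # alternating plant
  alt <- rep(c(TRUE, FALSE), 5)
  for (f in 1:10) {
    arr[f, , ] <- btkloop:::.apply_bond_state(frame_coords(base, 1), plan,
                                              alt[f])
  }
  traj <- md_trajectory(base$topology, arr)
  expect_identical(bond_timeline(traj, 2, 8, "hbond")$present, alt)

  # a pair that is never within the cutoff
  far <- bond_timeline(traj, 3, 9, "hbond")
  expect_false(any(far$present))
  expect_error(bond_timeline(traj, 2, 999, "hbond"),
               class = "btkloop_selection_error")
})

test_that("occupancy is the survival percentage and permutation-invariant", {
  tl <- tibble::tibble(frame = 1:10, bond = "X-Y",
                       present = c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(occupancy(tl)$occupancy, 30)
  expect_equal(occupancy(tl[sample(10), ])$occupancy, 30)
  all_on <- tibble::tibble(frame = 1:5, bond = "X-Y", present = TRUE)
  expect_equal(occupancy(all_on)$occupancy, 100)
  expect_error(occupancy(all_on[0, ]),
               class = "btkloop_insufficient_frames")

  # per-run grouping with cross-run summary
  runs <- rep(1:2, each = 5)
  tl2 <- tibble::tibble(frame = 1:10, bond = "X-Y",
                        present = c(rep(TRUE, 5), rep(FALSE, 5)))
  occ <- occupancy(tl2, runs = runs)
  expect_equal(occ$occupancy, c(100, 0))
  expect_equal(attr(occ, "mean"), 50)
})

test_that("planted Bernoulli occupancies are recovered frame-exactly", {
  base <- make_toy_topology(10, with_hydrogens = TRUE)
  gb <- gen_bond_toggle_traj(base, 2, 8, "hbond", p_on = 0.6,
                             n_frames = 800, seed = 3)
  tl <- bond_timeline(gb$trajectory, 2, 8, "hbond")
  expect_identical(tl$present, gb$timeline$present)
  got <- occupancy(tl)$occupancy
  expect_lt(abs(got - 60), 100 * 1.96 * sqrt(0.6 * 0.4 / 800) + 1e-9)
})

test_that("protein-ligand bond counts and attribution track the plants", {
  base <- make_toy_topology(9, with_hydrogens = TRUE, with_ligand = TRUE)
  top <- base$topology
  xyz <- frame_coords(base, 1)
  # plant two protein->ATP bonds: donors are the backbone N of residues 3
  # and 7, acceptors two ligand oxygens
  o1 <- which(top$name == "O1G"); o2 <- which(top$name == "O2G")
  for (spec in list(c(3, o1), c(7, o2))) {
    di <- which(top$res_seq == spec[1] & top$name == "N")
    hi <- which(top$res_seq == spec[1] & top$name == "H")
    u <- xyz[hi, ] - xyz[di, ]; u <- u / sqrt(sum(u^2))
    xyz[spec[2], ] <- xyz[di, ] + 2.9 * u
  }
  traj <- md_trajectory(top, array(rep(xyz, each = 2),
                                   dim = c(2, nrow(top), 3)))
  cnt <- ligand_hbond_count_series(traj)
  expect_equal(cnt$value, c(2, 2))
  attrib <- ligand_hbond_count_series(traj, by_residue = TRUE)
  expect_setequal(attrib$res_seq, c(3L, 7L))
  expect_equal(attrib$n_frames_bonded, c(2L, 2L))

  # ligand displaced beyond every cutoff
  far <- xyz
  lig <- which(top$is_het)
  far[lig, ] <- far[lig, ] + 50
  traj2 <- md_trajectory(top, far)
  expect_equal(ligand_hbond_count_series(traj2)$value, 0)
  expect_error(ligand_hbond_count_series(traj, ligand = "GTP"),
               class = "btkloop_selection_error")
})
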