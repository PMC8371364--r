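# The synthetic-trajectory generators and their ground truth.

test_that("toy topologies have the documented composition", {
  t3 <- make_toy_topology(3, sequence = c("ALA", "SER", "GLY"))
  expect_true(nrow(t3$topology) %in% 13:15)
  expect_s3_class(t3$topology, "md_topology")
  expect_equal(nrow(residues(t3$topology)), 3)

  th <- make_toy_topology(5, with_hydrogens = TRUE)
  top <- th$topology
  xyz <- frame_coords(th, 1)
  for (r in 2:5) {
    ni <- which(top$res_seq == r & top$name == "N")
    hi <- which(top$res_seq == r & top$name == "H")
    expect_length(hi, 1)
    expect_lt(sqrt(sum((xyz[ni, ] - xyz[hi, ])^2)), 1.05)
  }
  expect_length(which(top$res_seq == 1 & top$name == "H"), 0)

  tl <- make_toy_topology(4, with_ligand = TRUE)
  het <- residues(tl$topology)
  het <- het[het$res_name == "ATP", ]
  expect_equal(nrow(het), 1)
  expect_true(all(tl$topology$is_het[tl$topology$res_name == "ATP"]))

  t389 <- make_toy_topology(3, first_res = 389)
  expect_equal(residues(t389$topology)$res_seq, 389:391)
})

test_that("fluctuation plants are exact at sigma = 0 and bit-reproducible", {
  base <- make_toy_topology(6)
  still <- gen_fluctuation_traj(base, rep(0, 6), 5, seed = 1)
  for (f in 1:5) {
    expect_identical(still$coords[f, , ], base$coords[1, , ])
  }
  a <- gen_fluctuation_traj(base, rep(0.4, 6), 20, seed = 99)
  b <- gen_fluctuation_traj(base, rep(0.4, 6), 20, seed = 99)
  expect_identical(a$coords, b$coords)
  c <- gen_fluctuation_traj(base, rep(0.4, 6), 20, seed = 100)
  expect_false(identical(a$coords, c$coords))
  expect_equal(attr(a, "truth")$sigma, rep(0.4, 6))
  expect_error(gen_fluctuation_traj(base, rep(0.4, 5), 5, seed = 1),
               class = "btkloop_spec_error")
})

test_that("bond toggles hit their endpoints and return exact truth", {
  base <- make_toy_topology(10, with_hydrogens = TRUE)
  on <- gen_bond_toggle_traj(base, 2, 8, "hbond", p_on = 1,
                             n_frames = 30, seed = 5)
  expect_equal(occupancy(bond_timeline(on$trajectory, 2, 8,
                                       "hbond"))$occupancy, 100)
  off <- gen_bond_toggle_traj(base, 2, 8, "hbond", p_on = 0,
                              n_frames = 30, seed = 5)
  expect_equal(occupancy(bond_timeline(off$trajectory, 2, 8,
                                       "hbond"))$occupancy, 0)
  # impossible criteria are caught at generation time
  expect_error(
    gen_bond_toggle_traj(base, 2, 8, "hbond", p_on = 0.5, n_frames = 5,
                         seed = 1, criteria = hbond_criteria(da_cutoff = 1)),
    class = "btkloop_generation_error")
})

test_that("salt-bridge toggles work on basic/acidic residue pairs", {
  base <- make_toy_topology(
    8, sequence = c("LYS", "ALA", "ALA", "ALA", "ASP", "ALA", "ALA", "ALA"))
  gb <- gen_bond_toggle_traj(base, 1, 5, "saltbridge", p_on = 0.5,
                             n_frames = 200, seed = 8)
  tl <- bond_timeline(gb$trajectory, 1, 5, "saltbridge")
  expect_identical(tl$present, gb$timeline$present)
  # either residue order works
  gb2 <- gen_bond_toggle_traj(base, 5, 1, "saltbridge", p_on = 1,
                              n_frames = 3, seed = 8)
  expect_true(all(gb2$timeline$present))
  expect_error(
    gen_bond_toggle_traj(base, 2, 3, "saltbridge", p_on = 0.5,
                         n_frames = 3, seed = 1),
    class = "btkloop_generation_error")
})

test_that("rigid-motion trajectories are invariant for every observable", {
  base <- make_toy_topology(12)
  rigid <- gen_rigid_motion_traj(base, 8, seed = 77)
  expect_true(all(rmsd_series(rigid)$value <= 1e-9))
  rg <- rgyr_series(rigid)$value
  expect_lt(max(rg) - min(rg), 1e-9)
  truth <- attr(rigid, "truth")
  expect_length(truth$rotations, 8)
  for (R in truth$rotations) {
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
  }
})

test_that("angle plants realise their target series exactly", {
  base <- make_toy_topology(20)
  target <- c(10, 45, 90, 120, 170)
  traj <- gen_angle_traj(base, target, vertex = 3, end_b = 10, end_c = 17)
  got <- line_angle_series(traj, 3, 10, 17)$value
  expect_equal(got, target, tolerance = 1e-9)
  # composes with noise: angles stay exact on a noisy base
  noisy <- gen_fluctuation_traj(base, rep(0.5, 20), 5, seed = 2)
  traj2 <- gen_angle_traj(noisy, target, vertex = 3, end_b = 10,
                          end_c = 17)
  expect_equal(line_angle_series(traj2, 3, 10, 17)$value, target,
               tolerance = 1e-9)
})

test_that("condition runs plant every documented contrast", {
  pair <- gen_condition_pair(n_runs = 1, n_frames = 30, seed = 42)
  wt <- pair$wt[[1]]; mut <- pair$t474m[[1]]
  expect_equal(wt$truth$params$bonds$gly541_leu518$p_on, 0.15)
  expect_equal(mut$truth$params$bonds$gly541_leu518$p_on, 0.85)
  # detector agrees with returned truth frame-by-frame
  for (nm in names(wt$truth$timelines)) {
    b <- wt$truth$params$bonds[[nm]]
    tl <- bond_timeline(wt$trajectory, b$res_a, b$res_b, type = b$type)
    expect_identical(tl$present, wt$truth$timelines[[nm]]$present)
  }
  # the planted angle series is realised
  expect_equal(line_angle_series(wt$trajectory)$value, wt$truth$angles,
               tolerance = 1e-9)
  # reproducibility of the whole pair
  pair2 <- gen_condition_pair(n_runs = 1, n_frames = 30, seed = 42)
  expect_identical(pair$wt[[1]]$trajectory$coords,
                   pair2$wt[[1]]$trajectory$coords)
})
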