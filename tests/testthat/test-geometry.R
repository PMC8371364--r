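# Superposition and the structural observables.

rot_z90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)

test_that("kabsch_superpose recovers exact rigid motions", {
  set.seed(42)
  p <- matrix(rnorm(30), ncol = 3)
  id <- kabsch_superpose(p, p)
  expect_equal(id$rmsd_min, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)

  q <- p %*% t(rot_z90) + matrix(c(1, 2, 3), nrow(p), 3, byrow = TRUE)
  sp <- kabsch_superpose(p, q)
  expect_lt(sp$rmsd_min, 1e-9)
  expect_equal(sp$rotation, rot_z90, tolerance = 1e-9)
  moved <- p %*% t(sp$rotation) +
    matrix(sp$translation, nrow(p), 3, byrow = TRUE)
  expect_equal(moved, q, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch_superpose matches the quaternion eigenvalue oracle", {
  set.seed(7)
  for (k in 1:20) {
    a <- matrix(rnorm(18, sd = 3), ncol = 3)
    b <- matrix(rnorm(18, sd = 3), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd_min, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
    # symmetry of the minimal RMSD
    expect_equal(kabsch_superpose(a, b)$rmsd_min,
                 kabsch_superpose(b, a)$rmsd_min, tolerance = 1e-9)
  }
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1),
               class = "btkloop_degenerate_geometry")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)),
               class = "btkloop_degenerate_geometry")
})

test_that("rmsd_series is zero for static frames and rigid motions", {
  base <- make_toy_topology(8)
  static <- md_trajectory(base$topology,
                          base$coords[rep(1, 5), , , drop = FALSE])
  expect_true(all(rmsd_series(static)$value < 1e-12))

  rigid <- gen_rigid_motion_traj(base, 10, seed = 3)
  expect_true(all(rmsd_series(rigid)$value <= 1e-9))
  # reference frame k gives 0 at k, for any k
  for (k in c(1, 4, 10)) {
    expect_lt(rmsd_series(rigid, reference = k)$value[k], 1e-9)
  }
})

test_that("mean RMSD of planted isotropic noise approaches sigma*sqrt(3)", {
  base <- make_toy_topology(300)
  sel <- select_atoms(base$topology, c(1, 300), "CA")
  sigma <- 0.5
  nf <- 60
  arr <- array(NA_real_, dim = c(nf, n_atoms(base), 3))
  set.seed(13)
  arr[1, , ] <- base$coords[1, , ]  # noiseless reference frame
  for (f in 2:nf) {
    arr[f, , ] <- base$coords[1, , ] + rnorm(3 * n_atoms(base), sd = sigma)
  }
  traj <- md_trajectory(base$topology, arr)
  rs <- rmsd_series(traj, sel, reference = 1)
  expect_equal(mean(rs$value[-1]), sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsf recovers planted per-residue amplitudes and their order", {
  base <- make_toy_topology(150)
  sig <- rep(c(0.2, 0.5, 1.0), length.out = 150)
  traj <- gen_fluctuation_traj(base, sig, 2000, seed = 11)
  prof <- rmsf_profile(traj, atom_class = "heavy")
  expect_lt(max(abs(prof$value / (sig * sqrt(3)) - 1)), 0.03)
  # monotone recovery of the planted ordering
  expect_identical(order(prof$value[1:3]), order(sig[1:3]))

  static <- md_trajectory(base$topology,
                          base$coords[rep(1, 4), , , drop = FALSE])
  expect_true(all(rmsf_profile(static)$value < 1e-12))
  expect_error(rmsf_profile(base), class = "btkloop_insufficient_frames")
})

test_that("rgyr matches closed forms", {
  # two unit-mass atoms 2 A apart -> 1.0
  two <- point_topology(c("CA", "CA"), c("C", "C"), 1:2,
                        rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(rgyr_series(two, c(1, 2), mass_weighted = FALSE,
                           atom_class = "CA")$value, 1.0)
  # 8 atoms at cube vertices, side a -> a*sqrt(3)/2
  a <- 2
  cube <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  ct <- point_topology(rep("CA", 8), rep("C", 8), 1:8, cube)
  expect_equal(rgyr_series(ct, c(1, 8), mass_weighted = FALSE,
                           atom_class = "CA")$value, a * sqrt(3) / 2)
  # single atom -> 0
  one <- point_topology("CA", "C", 1, rbind(c(5, 5, 5)))
  expect_equal(rgyr_series(one, c(1, 1), atom_class = "CA")$value, 0)
})

test_that("line angles match closed-form fixtures", {
  mk <- function(v, b, cc) {
    point_topology(rep("CA", 3), rep("C", 3), 1:3, rbind(v, b, cc))
  }
  ang <- function(traj) line_angle_series(traj, 1, 2, 3)$value
  expect_equal(ang(mk(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 0)
  expect_equal(ang(mk(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))), 90)
  expect_equal(ang(mk(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))), 45)
  expect_error(ang(mk(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0))),
               class = "btkloop_degenerate_geometry")
})

test_that("DFG-to-ATP-site distance uses the P-loop/hinge midpoint", {
  # DFG centroid at origin, P-loop at (2,0,0), hinge at (4,0,0): midpoint
  # (3,0,0), so d = 3
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  traj <- point_topology(rep("CA", 3), rep("C", 3), 1:3, coords)
  rs <- region_set(tibble::tibble(region = c("dfg", "p_loop", "hinge"),
                                  first = 1:3, last = 1:3))
  expect_equal(dfg_atp_distance_series(traj, rs)$value, 3.0)

  same <- point_topology(rep("CA", 3), rep("C", 3), 1:3,
                         rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
  expect_equal(dfg_atp_distance_series(same, rs)$value, 0)

  set.seed(5)
  n <- c(3, 4, 5)
  xyz <- matrix(rnorm(sum(n) * 3, sd = 4), ncol = 3)
  res <- rep(1:3, times = n)
  rnd <- point_topology(rep("CA", sum(n)), rep("C", sum(n)), res, xyz)
  expect_equal(
    dfg_atp_distance_series(rnd, rs)$value,
    centroid_distance_oracle(xyz[res == 1, ], xyz[res == 2, ],
                             xyz[res == 3, ]))
})

test_that("all observables are invariant under a global rigid motion", {
  base <- make_toy_topology(20, with_hydrogens = TRUE)
  traj <- gen_fluctuation_traj(base, rep(0.3, 20), 6, seed = 21)
  moved <- traj
  R <- kabsch_superpose(matrix(rnorm(30), 10, 3),
                        matrix(rnorm(30), 10, 3))$rotation
  shift <- c(3, -7, 11)
  for (f in 1:6) {
    moved$coords[f, , ] <- traj$coords[f, , ] %*% t(R) +
      matrix(shift, n_atoms(traj), 3, byrow = TRUE)
  }
  expect_equal(rmsd_series(moved)$value, rmsd_series(traj)$value,
               tolerance = 1e-9)
  expect_equal(rgyr_series(moved)$value, rgyr_series(traj)$value,
               tolerance = 1e-9)
  expect_equal(line_angle_series(moved, 2, 10, 18)$value,
               line_angle_series(traj, 2, 10, 18)$value, tolerance = 1e-9)
  rs <- region_set(tibble::tibble(region = c("dfg", "p_loop", "hinge"),
                                  first = c(1, 8, 15),
                                  last = c(3, 11, 18)))
  expect_equal(dfg_atp_distance_series(moved, rs)$value,
               dfg_atp_distance_series(traj, rs)$value, tolerance = 1e-9)
  expect_equal(rmsf_profile(moved)$value, rmsf_profile(traj)$value,
               tolerance = 1e-7)
})
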