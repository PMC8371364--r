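# Reading and writing PDB / DCD / metric tables.

pdb_line <- function(serial, name, res, seq, x, y, z, rec = "ATOM") {
  sprintf("%-6s%5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          rec, serial, name, res, seq, x, y, z, substr(name, 1, 1))
}

test_that("PDB fixture round-trips coordinates and topology exactly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "GLY", 1, 0, 0, 0),
               pdb_line(2, "CA", "ALA", 2, 3, 0, 0), "END"), f)
  traj <- read_pdb(f)
  expect_equal(n_atoms(traj), 2)
  expect_equal(n_frames(traj), 1)
  expect_identical(unname(frame_coords(traj, 1)),
                   matrix(c(0, 3, 0, 0, 0, 0), 2, 3))
  expect_identical(traj$topology$res_seq, c(1L, 2L))
  expect_identical(traj$topology$name, c("CA", "CA"))
})

test_that("MODEL blocks become trajectory frames, in file order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  blocks <- unlist(lapply(1:3, function(m) {
    c(sprintf("MODEL     %4d", m),
      pdb_line(1, "CA", "GLY", 1, m, 0, 0),
      pdb_line(2, "CA", "ALA", 2, m + 3, 0, 0),
      "ENDMDL")
  }))
  writeLines(c(blocks, "END"), f)
  traj <- read_pdb(f)
  expect_equal(n_frames(traj), 3)
  expect_equal(traj$coords[, 1, 1], c(1, 2, 3))
})

test_that("unreadable coordinate fields raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  good <- pdb_line(1, "CA", "GLY", 1, 0, 0, 0)
  bad <- sub("   0.000", "  xx.000", pdb_line(2, "CA", "ALA", 2, 0, 1, 1))
  writeLines(c(good, bad, "END"), f)
  expect_error(read_pdb(f), "line 2", class = "btkloop_parse_error")
})

test_that("empty and absent structures are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_pdb(f), class = "btkloop_empty_structure")
  expect_error(read_pdb(file.path(tempdir(), "no-such.pdb")),
               class = "btkloop_io_error")
})

test_that("highest-occupancy ALTLOC conformer is kept with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  l1 <- pdb_line(1, "CA", "GLY", 1, 0, 0, 0)
  a <- pdb_line(2, "CB", "GLY", 1, 1, 0, 0)
  substr(a, 17, 17) <- "A"; substr(a, 57, 60) <- "0.40"
  b <- pdb_line(3, "CB", "GLY", 1, 2, 0, 0)
  substr(b, 17, 17) <- "B"; substr(b, 57, 60) <- "0.60"
  writeLines(c(l1, a, b, "END"), f)
  expect_warning(traj <- read_pdb(f), "occupancy")
  expect_equal(n_atoms(traj), 2)
  expect_equal(unname(frame_coords(traj, 1)[2, 1]), 2)  # 0.60 conformer
})

test_that("DCD write-then-read round-trips to float precision, any endianness", {
  base <- make_toy_topology(3)
  traj <- gen_fluctuation_traj(base, rep(0.5, 3), 5, seed = 2)
  fl <- withr::local_tempfile(fileext = ".dcd")
  fb <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, fl)
  write_dcd(traj, fb, endian = "big")
  rl <- read_dcd(fl, base$topology)
  rb <- read_dcd(fb, base$topology)
  expect_equal(n_frames(rl), 5)
  expect_lt(max(abs(rl$coords - traj$coords)), 1e-5)
  expect_identical(rl$coords, rb$coords)
})

test_that("DCD atom-count mismatch and truncation are reported", {
  t9 <- make_toy_topology(2)
  t10 <- make_toy_topology(3)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(md_trajectory(t9$topology, t9$coords), f)
  expect_error(read_dcd(f, t10$topology),
               class = "btkloop_topology_mismatch")

  traj <- gen_fluctuation_traj(t9, rep(0.3, 2), 4, seed = 1)
  full <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, full)
  bytes <- readBin(full, "raw", file.size(full))
  cut <- withr::local_tempfile(fileext = ".dcd")
  writeBin(bytes[1:(length(bytes) - 37)], cut)
  err <- expect_error(read_dcd(cut, t9$topology),
                      class = "btkloop_partial_file")
  expect_match(conditionMessage(err), "3 complete frame")
})

test_that("metric tables are stable, 6-significant-digit TSVs", {
  base <- make_toy_topology(4)
  traj <- gen_fluctuation_traj(base, rep(0.2, 4), 3, seed = 9)
  rg <- rgyr_series(traj)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_metric_table(rg, f1)
  write_metric_table(rg, f2)
  expect_identical(readLines(f1), readLines(f2))   # bit-identical
  expect_length(readLines(f1), 4)                  # header + 3 frames
  back <- read_metric_table(f1)
  expect_equal(back$value, signif(rg$value, 6))

  expect_error(write_metric_table(list(), tempfile()),
               class = "btkloop_index_error")
  expect_error(
    write_metric_table(list(rg, rmsf_profile(
      gen_fluctuation_traj(base, rep(0.2, 4), 5, seed = 1))), tempfile()),
    class = "btkloop_index_error")
})

test_that("frame windows preserve order and bounds", {
  base <- make_toy_topology(3)
  traj <- gen_fluctuation_traj(base, rep(0.1, 3), 10, seed = 5)
  w <- frame_window(traj, 4:6)
  expect_equal(n_frames(w), 3)
  expect_identical(w$coords[2, , ], traj$coords[5, , ])
  expect_error(frame_window(traj, 9:11), class = "btkloop_frame_error")
})

test_that("an independent reader agrees with our PDB and DCD files", {
  base <- make_toy_topology(5, with_hydrogens = TRUE)
  traj <- gen_fluctuation_traj(base, rep(0.4, 5), 4, seed = 31)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fd <- withr::local_tempfile(fileext = ".dcd")
  write_pdb(traj, fp)
  write_dcd(traj, fd)

  ref_pdb <- bio3d::read.pdb(fp, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(ref_pdb$atom), n_atoms(traj))
  got <- matrix(ref_pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(got, unname(frame_coords(traj, 1)), tolerance = 1e-3)
  expect_equal(ref_pdb$atom$resno[1], 1)

  ref_dcd <- bio3d::read.dcd(fd, verbose = FALSE)
  expect_equal(nrow(ref_dcd), 4)
  for (f in 1:4) {
    got <- matrix(ref_dcd[f, ], ncol = 3, byrow = TRUE)
    expect_equal(got, unname(frame_coords(traj, f)), tolerance = 1e-5)
  }
})
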