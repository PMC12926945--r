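test_that("a minimal hand-written PDB parses to the expected atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.451   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.250   2.380   0.000  1.00  0.00           O",
    "ATOM      5  H   GLY A   1      -0.500  -0.800   0.000  1.00  0.00           H",
    "END"
  ), path)
  st <- read_structure(path)
  expect_equal(nrow(st), 5)
  expect_equal(nrow(dplyr::distinct(st[, c("chain", "resno")])), 1)
  # PDB Angstroms land as nm
  expect_equal(st$x[2], 0.1451, tolerance = 1e-9)
  expect_false(st$is_heavy[5])
  expect_false(any(st$is_solvent))
})

test_that("atom totals match an independent ATOM/HETATM line count", {
  st <- fx_solvated(n_res = 3, n_wat = 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  n_records <- sum(grepl("^(ATOM|HETATM)", readLines(path)))
  reread <- read_structure(path)
  expect_equal(nrow(reread), n_records)
  expect_equal(nrow(reread), nrow(st))
  expect_equal(sum(reread$is_solvent), sum(st$is_solvent))
})

test_that("structure write/read round-trips keys and coordinates", {
  st <- fx_solvated(n_res = 4, n_wat = 10, seed = 3)
  for (ext in c(".pdb", ".gro")) {
    path <- withr::local_tempfile(fileext = ext)
    write_structure(st, path)
    back <- read_structure(path)
    expect_equal(nrow(back), nrow(st))
    expect_equal(paste(back$chain != "", back$resno),
                 paste(st$chain != "", st$resno))
    expect_equal(back$resname, st$resname)
    # PDB stores 3 decimals in Angstrom, GRO 3 decimals in nm
    tol <- if (ext == ".pdb") 5.1e-5 else 5.1e-4
    expect_lt(max(abs(back$x - st$x)), tol)
    expect_lt(max(abs(back$z - st$z)), tol)
  }
})

test_that("waters and monoatomic ions are flagged on parse", {
  atoms <- dplyr::bind_rows(
    fx_peptide(2, seed = 5),
    fx_atoms(90, "OW", "O", "SOL", "W", 50, matrix(c(1, 1, 1), 1)),
    fx_atoms(91, "NA", "NA", "NA", "I", 60, matrix(c(2, 2, 2), 1)),
    fx_atoms(92, "CL", "CL", "CL", "I", 61, matrix(c(-2, 2, 2), 1))
  )
  st <- parch_structure(atoms)
  expect_equal(sum(st$is_solvent), 1)
  expect_equal(sum(st$is_ion), 2)
  expect_equal(net_charge(st), 0) # Na+ and Cl- cancel; Ala carries none
})

test_that("empty-protein input is rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH W   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), path)
  expect_error(read_structure(path), "no protein residues")
  expect_error(read_structure(tempfile()), "cannot read")
})

test_that("trajectory construction validates congruence and ordering", {
  st <- fx_solvated(n_res = 2, n_wat = 3, seed = 2)
  xyz <- cbind(st$x, st$y, st$z)
  frames <- array(0, dim = c(2, nrow(st), 3))
  frames[1, , ] <- xyz
  frames[2, , ] <- xyz + 0.1
  expect_error(parch_trajectory(frames, c(0, 0), st), "strictly increasing")
  expect_error(parch_trajectory(frames, c(-1, 5), st), ">= 0")
  expect_error(
    parch_trajectory(frames[, 1:3, , drop = FALSE], c(0, 10), st),
    "atoms"
  )
  traj <- parch_trajectory(frames, c(0, 10), st)
  expect_equal(n_frames(traj), 2)
  expect_equal(frame_coords(traj, 1), xyz)
})

test_that("a single-frame trajectory reproduces the structure coordinates", {
  st <- fx_solvated(n_res = 2, n_wat = 4, seed = 8)
  xyz <- cbind(st$x, st$y, st$z)
  traj <- parch_trajectory(array(xyz, dim = c(1, nrow(st), 3)), 0, st)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, st, path)
  back <- read_trajectory(path, st)
  expect_equal(n_frames(back), 1)
  expect_lt(max(abs(frame_coords(back, 1) - xyz)), 5.1e-5)
})

test_that("multi-frame trajectories round-trip with times and frame count", {
  st <- fx_solvated(n_res = 3, n_wat = 6, seed = 4)
  base <- cbind(st$x, st$y, st$z)
  nf <- 10
  coords <- array(0, dim = c(nf, nrow(st), 3))
  times <- (seq_len(nf) - 1) * 25
  for (i in seq_len(nf)) coords[i, , ] <- round(base + (i - 1) * 0.01, 4)
  traj <- parch_trajectory(coords, times, st)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, st, path)
  # independent frame count: MODEL record scan
  expect_equal(sum(grepl("^MODEL", readLines(path))), nf)
  back <- read_trajectory(path, st)
  expect_equal(n_frames(back), nf)
  expect_equal(back$times, times)
  for (i in c(1, 5, 10)) {
    expect_lt(max(abs(frame_coords(back, i) - coords[i, , ])), 5.1e-5)
  }
})
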