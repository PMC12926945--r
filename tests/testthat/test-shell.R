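fx_protein_with_waters <- function(water_dists, seed = 1) {
  # single CA atom at origin plus waters at prescribed distances along
  # random directions
  withr::with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * length(water_dists)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
  })
  pos <- dirs * water_dists
  atoms <- dplyr::bind_rows(
    fx_atoms(1, "CA", "C", "ALA", "A", 1, matrix(0, 1, 3)),
    fx_atoms(1 + seq_along(water_dists), "OW", "O", "HOH", "W",
             1 + seq_along(water_dists), pos)
  )
  parch_structure(atoms)
}

test_that("shell carving honours the inclusive d_shell boundary", {
  st <- fx_protein_with_waters(c(0.415, 0.50, 0.10))
  shell <- carve_water_shell(st)
  kept <- shell$shell_waters
  expect_equal(nrow(kept), 2) # 0.415 retained (inclusive), 0.50 removed
  expect_true(all(kept$min_dist <= 0.415 + 1e-12))
  expect_equal(sum(shell$structure$is_solvent), 2)
  # protein untouched
  expect_equal(sum(!shell$structure$is_solvent), 1)
})

test_that("carving matches the brute-force all-pairs oracle", {
  st <- fx_solvated(n_res = 5, n_wat = 200, box = 1.2, seed = 21)
  shell <- carve_water_shell(st)
  kept_keys <- sort(paste0(shell$shell_waters$chain, ":",
                           shell$shell_waters$resno))
  expect_equal(kept_keys, oracle_shell_keep(st))
})

test_that("carving is idempotent and rigid-motion invariant", {
  st <- fx_solvated(n_res = 4, n_wat = 120, box = 1.0, seed = 31)
  once <- carve_water_shell(st)
  twice <- carve_water_shell(once)
  expect_equal(twice$shell_waters$resno, once$shell_waters$resno)
  expect_equal(nrow(twice$structure), nrow(once$structure))
  moved <- carve_water_shell(fx_rigid_motion(st, seed = 7))
  expect_equal(sort(moved$shell_waters$resno),
               sort(once$shell_waters$resno))
})

test_that("an empty shell is an error", {
  st <- fx_protein_with_waters(c(2.0, 3.0))
  expect_error(carve_water_shell(st), "no waters within")
})

test_that("counter-ion placement neutralizes and keeps its distance", {
  st <- fx_solvated(n_res = 5, n_wat = 150, box = 1.2, seed = 41)
  shell <- carve_water_shell(st)

  # charge 0: nothing to add
  expect_identical(place_counterions(shell, charge = 0), shell)

  # charge -2: two cations, each >= d_ion from every protein heavy atom
  ions2 <- place_counterions(shell, charge = -2, seed = 5)
  expect_equal(nrow(ions2$counterions), 2)
  expect_true(all(ions2$counterions$species == "NA"))
  expect_equal(net_charge(ions2$structure), 0)

  tbl <- as.data.frame(ions2$structure)
  prot <- tbl[!tbl$is_solvent & !tbl$is_ion & tbl$is_heavy, ]
  for (k in seq_len(nrow(ions2$counterions))) {
    dmin <- min(sqrt((prot$x - ions2$counterions$x[k])^2 +
                       (prot$y - ions2$counterions$y[k])^2 +
                       (prot$z - ions2$counterions$z[k])^2))
    expect_gte(dmin, 3.0 - 1e-9)
  }

  # five ions: exhaustive distance scan and exact neutralization
  ions5 <- place_counterions(shell, charge = 5, seed = 9)
  expect_equal(nrow(ions5$counterions), 5)
  expect_true(all(ions5$counterions$species == "CL"))
  expect_equal(net_charge(ions5$structure), 0)
  for (k in 1:5) {
    dmin <- min(sqrt((prot$x - ions5$counterions$x[k])^2 +
                       (prot$y - ions5$counterions$y[k])^2 +
                       (prot$z - ions5$counterions$z[k])^2))
    expect_gte(dmin, 3.0 - 1e-9)
  }
  # ions joined the restrained selection
  expect_equal(length(ions5$restrained), length(shell$restrained) + 5)
})

test_that("annealing inputs encode the ramp and replicate seeds", {
  st <- fx_solvated(n_res = 3, n_wat = 80, box = 1.0, seed = 51)
  shell <- carve_water_shell(st)
  outdir <- withr::local_tempdir()
  manifest <- emit_annealing_inputs(shell, annealing_schedule(), outdir,
                                    replicates = 5, base_seed = 3)
  expect_equal(sum(manifest$kind == "annealing_template"), 5)
  tmpl <- readLines(manifest$file[manifest$kind == "annealing_template"][1])
  expect_true(any(grepl("annealing-temp\\s*=\\s*300 800", tmpl)))
  expect_true(any(grepl("annealing-time\\s*=\\s*0 5000", tmpl)))
  seeds <- vapply(manifest$file[manifest$kind == "annealing_template"],
                  function(f) {
                    l <- grep("gen-seed", readLines(f), value = TRUE)
                    as.integer(sub(".*=\\s*", "", l))
                  }, integer(1))
  expect_equal(length(unique(seeds)), 5)

  # manifest round-trip: every listed file exists and parses
  for (f in manifest$file) expect_true(file.exists(f))
  sys <- read_structure(manifest$file[manifest$kind == "coordinates"])
  expect_equal(nrow(sys), nrow(shell$structure))
  restr <- readLines(manifest$file[manifest$kind == "restraints"])
  expect_true(any(grepl("1e\\+04|10000", restr[1])))
  expect_equal(sum(!startsWith(restr, "#")), length(shell$restrained))
})
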