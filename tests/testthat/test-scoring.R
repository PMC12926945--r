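test_that("the ramp maps time to temperature in closed form", {
  sched <- annealing_schedule()
  expect_identical(temperature_at(sched, 0), 300)
  expect_identical(temperature_at(sched, 1000), 400)
  expect_identical(temperature_at(sched, 6000), 800) # clamped past the end
  expect_identical(ramp_duration(sched), 5000)
  expect_error(temperature_at(sched, -1), "non-negative")
  expect_error(annealing_schedule(t_start = 500, t_end = 400), "exceed")
})

test_that("contact counting is inclusive at d_water", {
  mk <- function(d) {
    parch_structure(dplyr::bind_rows(
      fx_atoms(1, "CA", "C", "ALA", "A", 1, matrix(0, 1, 3)),
      fx_atoms(2, "OW", "O", "HOH", "W", 2, matrix(c(d, 0, 0), 1))
    ))
  }
  expect_equal(count_water_contacts(mk(0.314), "A", 1), 1)
  expect_equal(count_water_contacts(mk(0.315), "A", 1), 1)
  expect_equal(count_water_contacts(mk(0.316), "A", 1), 0)
  expect_error(count_water_contacts(mk(0.3), "B", 9), "not found")
})

test_that("contact counts equal the brute-force all-pairs oracle", {
  st <- fx_solvated(n_res = 3, n_wat = 50, box = 0.8, seed = 61)
  for (r in 1:3) {
    expect_equal(count_water_contacts(st, "A", r),
                 oracle_count_contacts(st, "A", r))
  }
})

test_that("profiles recount every frame of a moving-water trajectory", {
  st <- fx_solvated(n_res = 3, n_wat = 30, box = 0.7, seed = 71)
  base <- cbind(st$x, st$y, st$z)
  nf <- 6
  coords <- array(0, dim = c(nf, nrow(st), 3))
  wat_rows <- which(st$is_solvent)
  withr::with_seed(5, {
    for (i in seq_len(nf)) {
      xyz <- base
      # push waters outward by a known, growing displacement
      xyz[wat_rows, ] <- xyz[wat_rows, ] +
        (i - 1) * 0.08 * matrix(stats::rnorm(length(wat_rows) * 3,
                                             sd = 1), ncol = 3)
      coords[i, , ] <- xyz
    }
  })
  traj <- parch_trajectory(coords, (seq_len(nf) - 1) * 500, st)
  prof <- build_profiles(traj, st)
  # independent per-frame recount through the slow oracle
  for (i in c(1, 3, 6)) {
    sti <- st
    sti$x <- coords[i, , 1]; sti$y <- coords[i, , 2]; sti$z <- coords[i, , 3]
    for (r in 1:3) {
      expect_equal(
        prof$n_contacts[prof$resno == r & prof$frame == i],
        oracle_count_contacts(sti, "A", r)
      )
    }
  }
  expect_equal(unique(prof$temperature_k[prof$frame == 1]), 300)
})

test_that("static waters give constant profiles and one-frame identities", {
  st <- fx_solvated(n_res = 2, n_wat = 25, box = 0.7, seed = 81)
  xyz <- cbind(st$x, st$y, st$z)
  traj1 <- parch_trajectory(array(xyz, dim = c(1, nrow(st), 3)), 0, st)
  p1 <- build_profiles(traj1, st)
  for (r in 1:2) {
    expect_equal(p1$n_contacts[p1$resno == r],
                 count_water_contacts(st, "A", r))
  }
  coords <- array(rep(xyz, each = 4), dim = c(4, nrow(st), 3))
  # (frame-major fill) rebuild properly:
  coords <- array(0, dim = c(4, nrow(st), 3))
  for (i in 1:4) coords[i, , ] <- xyz
  traj4 <- parch_trajectory(coords, c(0, 10, 20, 30), st)
  p4 <- build_profiles(traj4, st)
  counts_by_res <- split(p4$n_contacts, p4$resno)
  for (cc in counts_by_res) expect_equal(length(unique(cc)), 1)
})

test_that("the retention ratio maps profiles to 0-10 PARCH values", {
  expect_equal(as.numeric(parch_from_profile(rep(7, 40))), 10)
  decay <- c(rep(6, 10), rep(0, 30))
  expect_equal(as.numeric(parch_from_profile(decay)), 0)
  prof <- c(rep(8, 2), rep(6, 36), rep(4, 2))
  expect_equal(as.numeric(parch_from_profile(prof)), 5) # 10 * 4/8
  buried <- parch_from_profile(c(0, 0, 0, 0))
  expect_equal(as.numeric(buried), 0)
  expect_true(attr(buried, "buried"))
  # growth clamps at 10
  expect_equal(as.numeric(parch_from_profile(c(2, 2, 5, 9, 9))), 10)
})

test_that("the escape-temperature scorer is a drop-in strategy", {
  temps <- seq(300, 800, length.out = 41)
  half_way <- c(rep(10, 20), rep(2, 21))
  s <- escape_temperature_scorer()
  r <- s(half_way, temps)
  expect_gt(r$pv, 4); expect_lt(r$pv, 6)
  expect_equal(s(rep(5, 41), temps)$pv, 10)
  expect_true(s(rep(0, 41), temps)$buried)
})

test_that("replicate aggregation gives means and sample sd per residue", {
  mk <- function(pv, rep) {
    tibble::tibble(chain = "A", resno = 1:2, resname = "ALA",
                   pv = pv, buried = FALSE, replicate = rep)
  }
  agg <- aggregate_replicates(dplyr::bind_rows(
    lapply(1:5, function(k) mk(c(3, 3), k))
  ))
  expect_equal(agg$pv_mean, c(3, 3))
  expect_equal(agg$pv_sd, c(0, 0))
  expect_equal(agg$n_rep, c(5L, 5L))

  two <- aggregate_replicates(dplyr::bind_rows(mk(c(2, 2), 1),
                                               mk(c(4, 4), 2)))
  expect_equal(two$pv_mean, c(3, 3))
  expect_equal(two$pv_sd, c(sqrt(2), sqrt(2)))

  bad <- dplyr::bind_rows(
    mk(c(1, 1), 1),
    tibble::tibble(chain = "A", resno = 3, resname = "ALA", pv = 1,
                   buried = FALSE, replicate = 2)
  )
  expect_error(aggregate_replicates(bad), "same residue keys")
})

test_that("PARCH values are bounded and rigid-motion invariant", {
  spec <- synthetic_spec(c(0.15, 0.6, 0.95), waters_per_residue = 25,
                         seed = 17)
  sys <- generate_reference_system(spec)
  traj <- generate_annealing_trajectory(sys, n_frames = 31)
  sc <- score_profiles(build_profiles(traj, sys$structure))
  expect_true(all(sc$pv >= 0 & sc$pv <= 10))

  moved <- fx_rigid_motion(sys$structure, seed = 23)
  rot_traj <- traj
  withr::with_seed(23, {
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    shift <- stats::runif(3, -5, 5)
  })
  for (i in seq_len(n_frames(traj))) {
    rot_traj$coords[i, , ] <-
      sweep(frame_coords(traj, i) %*% rot, 2, shift, "+")
  }
  sc2 <- score_profiles(build_profiles(rot_traj, moved))
  expect_equal(sc2$pv, sc$pv, tolerance = 1e-12)
})
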