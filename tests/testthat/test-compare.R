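fx_mapping <- function(n, resnames = rep("ALA", n)) {
  tibble::tibble(
    chain_unmod = "A", resno_unmod = seq_len(n), resname_unmod = resnames,
    chain_mod = "A", resno_mod = seq_len(n), resname_mod = resnames
  )
}

fx_profile <- function(pv, n_rep = 5) {
  tibble::tibble(
    chain = "A", resno = seq_along(pv), resname = "ALA",
    pv_mean = pv, pv_sd = 0.1, n_rep = n_rep, buried = FALSE
  )
}

test_that("neighborhoods respect the inclusive 0.3 nm heavy-atom cutoff", {
  # isolated residue: nothing within reach
  st <- fx_peptide(n_res = 3, atoms_per_res = 1, spacing = 2)
  st <- parch_structure(st)
  expect_equal(nrow(find_neighborhood(st, "A", 2)), 0)

  # exactly 0.30 nm apart: included
  two <- parch_structure(dplyr::bind_rows(
    fx_atoms(1, "CA", "C", "ALA", "A", 1, matrix(0, 1, 3)),
    fx_atoms(2, "CA", "C", "GLY", "A", 2, matrix(c(0.30, 0, 0), 1)),
    fx_atoms(3, "CA", "C", "SER", "A", 3, matrix(c(0.301, 0.3, 0), 1))
  ))
  nb <- find_neighborhood(two, "A", 1)
  expect_equal(nb$resno, 2)
  expect_error(find_neighborhood(two, "A", 99), "not found")
})

test_that("a packed helix-like fold matches the all-pairs oracle", {
  # 10 residues on a tight helix so several heavy-atom pairs fall under
  # the cutoff
  t <- seq(0, 3 * pi, length.out = 10)
  xyz <- cbind(0.25 * cos(t), 0.25 * sin(t), 0.05 * t)
  st <- parch_structure(
    fx_atoms(1:10, "CA", "C", "ALA", "A", 1:10, xyz)
  )
  for (site in c(1, 4, 7)) {
    nb <- find_neighborhood(st, "A", site)
    expect_equal(paste0(nb$chain, ":", nb$resno),
                 oracle_neighborhood(st, "A", site))
  }
})

test_that("exact Wilcoxon p-values match hand-enumerated cases", {
  w <- wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.25) # 2/8 sign assignments
  expect_equal(w$method, "exact")
  expect_equal(w$verdict, "ns")

  w6 <- wilcoxon_signed_rank(rep(0, 6), 1:6)
  expect_equal(w6$p_value, 2 / 64)
  expect_equal(w6$verdict, "significant")

  deg <- wilcoxon_signed_rank(c(2, 5, 5), c(2, 5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("exact p matches the 2^n enumeration oracle, ties included", {
  withr::with_seed(314, {
    for (case in 1:30) {
      n <- sample(2:10, 1)
      d <- sample(c(-3, -2, -1, 0, 1, 2, 3), n, replace = TRUE)
      if (all(d == 0)) d[1] <- 1
      w <- wilcoxon_signed_rank(d)
      expect_equal(w$p_value, oracle_wilcoxon_p(d), tolerance = 1e-12)
    }
  })
})

test_that("tie-free exact p agrees with the reference implementation", {
  withr::with_seed(2718, {
    for (case in 1:10) {
      n <- sample(4:12, 1)
      x <- stats::rnorm(n)
      y <- x + stats::rnorm(n, sd = 0.8)
      ours <- wilcoxon_signed_rank(x, y)
      ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  })
})

test_that("large-n testing falls back to a corrected normal approximation", {
  withr::with_seed(11, {
    x <- stats::rnorm(40)
    y <- x + stats::rnorm(40, mean = 0.3)
  })
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$method, "normal_approx")
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("identical profiles give all-zero deltas and 'unchanged'", {
  st <- parch_structure(fx_peptide(4, atoms_per_res = 2, spacing = 0.25))
  prof <- fx_profile(c(2, 4, 6, 8))
  d <- compute_delta(prof, prof, fx_mapping(4), list(chain = "A", resno = 2),
                     structure = st)
  expect_equal(d$site_delta, 0)
  expect_true(all(d$neighbors$delta == 0))
  expect_true(all(d$neighbors$class == "unchanged"))
  expect_equal(d$cumulative_delta, 0)
  expect_true(d$wilcoxon$degenerate)
})

test_that("site delta reproduces a printed before/after PV pair", {
  # switch-1 tyrosine going from PV 1.71 unmodified to 4.47 phosphorylated
  prof_u <- fx_profile(c(3.0, 1.71, 5.0))
  prof_m <- fx_profile(c(3.0, 4.47, 5.0))
  st <- parch_structure(fx_peptide(3, atoms_per_res = 1, spacing = 2))
  d <- compute_delta(prof_u, prof_m, fx_mapping(3),
                     list(chain = "A", resno = 2), structure = st)
  expect_equal(d$site_delta, 2.76, tolerance = 1e-12)
  expect_equal(d$site_class, "increase")
})

test_that("cumulative change follows the filtered +/-0.2 rule", {
  # neighbors with deltas +0.3, -0.1, +0.25 at threshold 0.2
  prof_u <- fx_profile(c(1.0, 2.0, 3.0, 4.0))
  prof_m <- fx_profile(c(1.5, 2.3, 2.9, 4.25))
  nbhd <- tibble::tibble(chain = "A", resno = 2:4,
                         resname = "ALA", min_dist = 0.2)
  d <- compute_delta(prof_u, prof_m, fx_mapping(4),
                     list(chain = "A", resno = 1), neighborhood = nbhd)
  expect_equal(d$neighbors$delta, c(0.3, -0.1, 0.25), tolerance = 1e-12)
  expect_equal(d$neighbors$class, c("increase", "unchanged", "increase"))
  expect_equal(d$cumulative_delta, 0.55, tolerance = 1e-12)

  d_all <- compute_delta(prof_u, prof_m, fx_mapping(4),
                         list(chain = "A", resno = 1), neighborhood = nbhd,
                         params = compare_params(cumulative_mode = "all"))
  expect_equal(d_all$cumulative_delta, 0.45, tolerance = 1e-12)
})

test_that("swapping the variants negates deltas but keeps the p-value", {
  withr::with_seed(55, {
    pvs_u <- stats::runif(8, 0, 10)
    pvs_m <- parchr:::clamp(pvs_u + stats::rnorm(8, 0.5), 0, 10)
  })
  prof_u <- fx_profile(pvs_u)
  prof_m <- fx_profile(pvs_m)
  nbhd <- tibble::tibble(chain = "A", resno = 2:8, resname = "ALA",
                         min_dist = 0.2)
  site <- list(chain = "A", resno = 1)
  fwd <- compute_delta(prof_u, prof_m, fx_mapping(8), site,
                       neighborhood = nbhd)
  rev <- compute_delta(prof_m, prof_u, fx_mapping(8), site,
                       neighborhood = nbhd)
  expect_equal(rev$site_delta, -fwd$site_delta)
  expect_equal(rev$neighbors$delta, -fwd$neighbors$delta)
  expect_equal(rev$cumulative_delta, -fwd$cumulative_delta)
  expect_equal(rev$wilcoxon$p_value, fwd$wilcoxon$p_value)
  # classification is exhaustive and exclusive
  expect_true(all(fwd$neighbors$class %in%
                    c("increase", "decrease", "unchanged")))
  swapped <- table(fwd$neighbors$class)["increase"]
  expect_equal(sum(rev$neighbors$class == "decrease"),
               sum(fwd$neighbors$class == "increase"))
})

test_that("a neighborhood residue missing from the mapping is an error", {
  prof <- fx_profile(c(1, 2))
  nbhd <- tibble::tibble(chain = "A", resno = 99, resname = "ALA",
                         min_dist = 0.1)
  expect_error(
    compute_delta(prof, prof, fx_mapping(2), list(chain = "A", resno = 1),
                  neighborhood = nbhd),
    "missing from mapping"
  )
})

test_that("delta reports tidy and glance cleanly", {
  prof_u <- fx_profile(c(1, 2, 3))
  prof_m <- fx_profile(c(4, 2.5, 2.5))
  nbhd <- tibble::tibble(chain = "A", resno = 2:3, resname = "ALA",
                         min_dist = 0.2)
  d <- compute_delta(prof_u, prof_m, fx_mapping(3),
                     list(chain = "A", resno = 1), neighborhood = nbhd)
  td <- tidy(d)
  expect_equal(nrow(td), 3)
  expect_setequal(unique(td$role), c("site", "neighbor"))
  g <- glance(d)
  expect_equal(g$site_delta, 3)
  expect_equal(g$n_neighbors, 2)
  expect_true(g$verdict %in% c("significant", "ns"))
})
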