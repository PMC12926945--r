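# Programmatic fixtures and independent brute-force oracles. Oracles are
# deliberately written as plain double loops / exhaustive scans, separate
# from the package's vectorized implementations.

fx_atoms <- function(serial, atom, element, resname, chain, resno, xyz) {
  tibble::tibble(
    serial = serial, atom = atom, element = element, resname = resname,
    chain = chain, resno = resno,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# Small peptide: n_res residues on a line, `atoms_per_res` heavy atoms each,
# jittered around the residue center. Coordinates in nm.
fx_peptide <- function(n_res = 3, atoms_per_res = 3, spacing = 0.8,
                       seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    serial <- 0L
    for (i in seq_len(n_res)) {
      center <- c((i - 1) * spacing, 0, 0)
      for (j in seq_len(atoms_per_res)) {
        serial <- serial + 1L
        pos <- center + stats::runif(3, -0.1, 0.1)
        rows[[serial]] <- fx_atoms(serial, c("CA", "CB", "CG")[(j - 1) %% 3 + 1],
                                   "C", "ALA", "A", i, matrix(pos, 1))
      }
    }
    dplyr::bind_rows(rows)
  })
}

# Peptide plus n_wat random single-oxygen waters in a cube of half-width
# `box` nm centred on the peptide.
fx_solvated <- function(n_res = 3, n_wat = 50, box = 1.5, seed = 1,
                        atoms_per_res = 3) {
  pep <- fx_peptide(n_res = n_res, atoms_per_res = atoms_per_res,
                    seed = seed)
  withr::with_seed(seed + 1000, {
    center <- colMeans(cbind(pep$x, pep$y, pep$z))
    wpos <- matrix(stats::runif(3 * n_wat, -box, box), ncol = 3)
    wpos <- sweep(wpos, 2, center, "+")
    wat <- fx_atoms(
      max(pep$serial) + seq_len(n_wat), "OW", "O", "HOH", "W",
      max(pep$resno) + seq_len(n_wat), wpos
    )
    parchr::parch_structure(dplyr::bind_rows(pep, wat))
  })
}

# Apply a random rigid rotation + translation to all coordinates.
fx_rigid_motion <- function(structure, seed = 1) {
  withr::with_seed(seed, {
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    shift <- stats::runif(3, -5, 5)
  })
  xyz <- cbind(structure$x, structure$y, structure$z) %*% rot
  xyz <- sweep(xyz, 2, shift, "+")
  out <- structure
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

# --- oracles -------------------------------------------------------------

# Brute-force water-contact count: plain double loop over waters and the
# residue's target atoms.
oracle_count_contacts <- function(structure, chain, resno,
                                  d_water = 0.315) {
  tbl <- as.data.frame(structure)
  wat <- tbl[tbl$is_solvent & tbl$element == "O", ]
  tgt <- tbl[tbl$chain == chain & tbl$resno == resno &
               !tbl$is_solvent & !tbl$is_ion & tbl$is_heavy, ]
  hits <- character(0)
  for (w in seq_len(nrow(wat))) {
    for (a in seq_len(nrow(tgt))) {
      d <- sqrt((wat$x[w] - tgt$x[a])^2 + (wat$y[w] - tgt$y[a])^2 +
                  (wat$z[w] - tgt$z[a])^2)
      if (d <= d_water) {
        hits <- c(hits, paste(wat$chain[w], wat$resno[w]))
        break
      }
    }
  }
  length(unique(hits))
}

# Brute-force shell membership: water keys whose oxygen is within d_shell
# of any protein heavy atom.
oracle_shell_keep <- function(structure, d_shell = 0.415) {
  tbl <- as.data.frame(structure)
  wat <- tbl[tbl$is_solvent & tbl$element == "O", ]
  prot <- tbl[!tbl$is_solvent & !tbl$is_ion & tbl$is_heavy, ]
  keep <- character(0)
  for (w in seq_len(nrow(wat))) {
    for (a in seq_len(nrow(prot))) {
      d <- sqrt((wat$x[w] - prot$x[a])^2 + (wat$y[w] - prot$y[a])^2 +
                  (wat$z[w] - prot$z[a])^2)
      if (d <= d_shell) {
        keep <- c(keep, paste0(wat$chain[w], ":", wat$resno[w]))
        break
      }
    }
  }
  sort(unique(keep))
}

# Brute-force neighborhood: all-pairs heavy-atom scan.
oracle_neighborhood <- function(structure, chain, resno, cutoff = 0.3) {
  tbl <- as.data.frame(structure)
  prot <- tbl[!tbl$is_solvent & !tbl$is_ion & tbl$is_heavy, ]
  site <- prot[prot$chain == chain & prot$resno == resno, ]
  other <- prot[!(prot$chain == chain & prot$resno == resno), ]
  keys <- character(0)
  for (o in seq_len(nrow(other))) {
    for (s in seq_len(nrow(site))) {
      d <- sqrt((other$x[o] - site$x[s])^2 + (other$y[o] - site$y[s])^2 +
                  (other$z[o] - site$z[s])^2)
      if (d <= cutoff) {
        keys <- c(keys, paste0(other$chain[o], ":", other$resno[o]))
        break
      }
    }
  }
  sort(unique(keys))
}

# Brute-force exact two-sided Wilcoxon signed-rank p: enumerate every sign
# assignment of the nonzero |differences| (mid-ranked) and count
# assignments at least as extreme (min tail sum <= observed).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  s <- sum(r)
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r) # W+ for each assignment
  mean(pmin(w_all, s - w_all) <= w_obs + 1e-12)
}
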