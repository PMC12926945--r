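# Annealing system geometry: carve the thin explicit water shell from a
# pre-solvated snapshot, place restrained counter-ions, and emit the
# coordinate/restraint/parameter inputs consumed by an external MD engine.

#' Water-shell construction parameters
#'
#' @param d_shell Shell thickness in nm: a water is kept when its oxygen
#'   lies within `d_shell` of the nearest protein heavy atom (default
#'   0.415, boundary inclusive).
#' @param restraint_k Position-restraint force constant for protein heavy
#'   atoms and counter-ions, kJ mol^-1 nm^-2 (default 1e4). Shell waters
#'   are never restrained -- they must be free to evaporate.
#' @param d_ion Minimum counter-ion to protein heavy-atom distance in nm
#'   (default 3).
#' @param d_b Ion-box boundary margin in nm (default 3).
#' @param min_tol Energy-minimization force tolerance, kJ mol^-1 nm^-1
#'   (default 1e3), echoed into the emitted parameter template.
#' @return A `shell_params` list.
#' @export
shell_params <- function(d_shell = 0.415, restraint_k = 1e4, d_ion = 3,
                         d_b = 3, min_tol = 1e3) {
  for (nm in c("d_shell", "restraint_k", "d_ion", "d_b", "min_tol")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(d_shell = d_shell, restraint_k = restraint_k, d_ion = d_ion,
         d_b = d_b, min_tol = min_tol),
    class = "shell_params"
  )
}

#' Carve the explicit water shell from a solvated structure
#'
#' Retains exactly the waters whose oxygen-to-nearest-protein-heavy-atom
#' distance is at most `d_shell` (inclusive); all other waters are removed
#' and the protein (and any pre-existing ions) left unchanged. The
#' operation is idempotent.
#'
#' @param solvated A `parch_structure` containing protein and waters.
#' @param params A [shell_params()] object.
#' @return A `parch_shell` list: `structure` (carved system),
#'   `shell_waters` (tibble of retained water keys with their minimum
#'   protein distance), `counterions` (tibble, empty until
#'   [place_counterions()]), `restrained` (serials of protein heavy atoms
#'   under `restraint_k`), `params`.
#' @export
carve_water_shell <- function(solvated, params = shell_params()) {
  if (inherits(solvated, "parch_shell")) solvated <- solvated$structure
  tbl <- as_tibble(solvated)
  prot_heavy <- which(protein_rows(solvated) & tbl$is_heavy)
  if (length(prot_heavy) == 0) abort("no protein heavy atoms in structure")
  wat_o <- which(tbl$is_solvent & tbl$element == "O")
  if (length(wat_o) == 0) abort("no waters in solvated structure")
  d <- min_dist_to_set(xyz_matrix(tbl, wat_o), xyz_matrix(tbl, prot_heavy))
  keep_keys <- res_key(tbl$chain[wat_o], tbl$resno[wat_o])[d <= params$d_shell]
  if (length(keep_keys) == 0) {
    abort(sprintf("no waters within d_shell = %g nm of the protein",
                  params$d_shell))
  }
  all_keys <- res_key(tbl$chain, tbl$resno)
  drop <- tbl$is_solvent & !(all_keys %in% keep_keys)
  carved <- parch_structure(tbl[!drop, ],
                            net_charge = net_charge(solvated))
  shell <- tibble(
    chain = tbl$chain[wat_o], resno = tbl$resno[wat_o], min_dist = d
  ) |> filter(.data$min_dist <= params$d_shell)
  structure(
    list(
      structure = carved,
      shell_waters = shell,
      counterions = tibble(species = character(), x = numeric(),
                           y = numeric(), z = numeric()),
      restrained = carved$serial[protein_rows(carved) & carved$is_heavy],
      params = params
    ),
    class = "parch_shell"
  )
}

#' @export
print.parch_shell <- function(x, ...) {
  cat(sprintf(
    "<parch_shell> %d shell waters | %d counter-ions | %d restrained atoms | net charge %+d e\n",
    nrow(x$shell_waters), nrow(x$counterions), length(x$restrained),
    net_charge(x$structure)
  ))
  invisible(x)
}

# Deterministic near-uniform unit directions (spherical Fibonacci lattice),
# rotated by a seeded random rotation so repeated placements with different
# seeds decorrelate.
fibonacci_directions <- function(n, seed = 1) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  rot <- with_seed(seed, {
    m <- matrix(rnorm(9), 3, 3)
    qr.Q(qr(m))
  })
  dirs %*% rot
}

#' Place neutralizing counter-ions around the shell system
#'
#' Adds `|net_charge|` monovalent ions of opposing sign (Na+ or Cl-) at
#' deterministic, seeded positions at least `d_ion` from every protein
#' heavy atom: spherical Fibonacci directions from the protein centroid at
#' radius `R_max + d_ion`, where `R_max` is the largest heavy-atom distance
#' from the centroid. Ions are added to the restrained selection, and the
#' system's net charge becomes exactly 0.
#'
#' @param shell A `parch_shell` from [carve_water_shell()].
#' @param charge Net charge to neutralize; defaults to the carved system's
#'   bookkeeping charge.
#' @param params A [shell_params()] object.
#' @param seed Integer seed for the placement rotation.
#' @return The updated `parch_shell`.
#' @export
place_counterions <- function(shell, charge = NULL, params = shell_params(),
                              seed = 1) {
  stopifnot(inherits(shell, "parch_shell"))
  st <- shell$structure
  tbl <- as_tibble(st)
  if (is.null(charge)) charge <- net_charge(st)
  n_ions <- abs(charge)
  if (n_ions == 0) return(shell)
  species <- if (charge < 0) "NA" else "CL"
  prot_heavy <- which(protein_rows(st) & tbl$is_heavy)
  P <- xyz_matrix(tbl, prot_heavy)
  centroid <- colMeans(P)
  r_max <- sqrt(max(rowSums(sweep(P, 2, centroid)^2)))
  dirs <- fibonacci_directions(max(n_ions, 2L), seed = seed)[seq_len(n_ions), ,
                                                             drop = FALSE]
  pos <- sweep(dirs * (r_max + params$d_ion), 2, centroid, "+")
  dmin <- min_dist_to_set(pos, P)
  if (any(dmin < params$d_ion - 1e-9)) {
    abort("counter-ion placement violates the d_ion constraint")
  }
  ion_atoms <- tibble(
    serial = max(tbl$serial) + seq_len(n_ions),
    atom = species,
    element = if (species == "NA") "NA" else "CL",
    resname = species,
    chain = "I",
    resno = max(tbl$resno) + seq_len(n_ions),
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
  newst <- parch_structure(bind_rows(tbl[, names(ion_atoms)], ion_atoms),
                           net_charge = 0L)
  shell$structure <- newst
  shell$counterions <- tibble(species = species, x = pos[, 1], y = pos[, 2],
                              z = pos[, 3])
  shell$restrained <- c(shell$restrained, ion_atoms$serial)
  shell
}

#' Emit annealing inputs for an external MD engine
#'
#' Writes the carved system coordinates (GRO), the restraint selection
#' (protein heavy atoms plus counter-ions at `restraint_k`), and one
#' documented key-value annealing parameter template per replicate encoding
#' the NVT ramp (300 to 800 K at 1 K per 10 ps by default, a 5000 ps ramp),
#' the minimization tolerance and a replicate seed. Running the engine is
#' user-side; this package only prepares and later consumes its files.
#'
#' @param shell A `parch_shell`.
#' @param schedule An [annealing_schedule()].
#' @param outdir Output directory (created if needed).
#' @param replicates Number of annealing replicates (protocol default 5).
#' @param base_seed Base integer seed; replicate `i` gets
#'   `base_seed * 1000 + i`.
#' @return Manifest tibble with columns `file`, `kind`, invisibly also
#'   written as `manifest.json`.
#' @export
emit_annealing_inputs <- function(shell, schedule = annealing_schedule(),
                                  outdir, replicates = 5, base_seed = 1) {
  stopifnot(inherits(shell, "parch_shell"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", outdir))
  }
  params <- shell$params
  coord_file <- file.path(outdir, "system.gro")
  write_structure(shell$structure, coord_file, format = "gro",
                  box = system_box(shell))
  restr_file <- file.path(outdir, "restraints.txt")
  writeLines(c(
    sprintf("# position restraints, k = %g kJ/mol/nm^2", params$restraint_k),
    sprintf("%d", sort(shell$restrained))
  ), restr_file)
  ramp_ps <- ramp_duration(schedule)
  tmpl_files <- character(replicates)
  for (i in seq_len(replicates)) {
    tmpl_files[i] <- file.path(outdir, sprintf("anneal_rep%d.mdp", i))
    writeLines(c(
      "; NVT simulated-annealing parameters (external engine template)",
      "integrator               = md",
      "dt                       = 0.002",
      sprintf("nsteps                   = %d", round(ramp_ps / 0.002)),
      sprintf("emtol                    = %g", params$min_tol),
      "annealing                = single",
      "annealing-npoints        = 2",
      sprintf("annealing-time           = 0 %g", ramp_ps),
      sprintf("annealing-temp           = %g %g",
              schedule$t_start, schedule$t_end),
      sprintf("ref-t                    = %g", schedule$t_start),
      sprintf("gen-seed                 = %d", base_seed * 1000 + i),
      sprintf("; restraint_k            = %g", params$restraint_k),
      sprintf("; d_shell                = %g", params$d_shell),
      sprintf("; d_ion                  = %g", params$d_ion),
      sprintf("; d_b                    = %g", params$d_b)
    ), tmpl_files[i])
  }
  manifest <- tibble(
    file = c(coord_file, restr_file, tmpl_files),
    kind = c("coordinates", "restraints", rep("annealing_template",
                                              replicates))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}

# Cubic box enclosing the system with margin max(d_b, d_ion + 0.5) nm
system_box <- function(shell) {
  tbl <- as_tibble(shell$structure)
  margin <- max(shell$params$d_b, shell$params$d_ion + 0.5)
  ext <- c(diff(range(tbl$x)), diff(range(tbl$y)), diff(range(tbl$z)))
  ext + 2 * margin
}
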