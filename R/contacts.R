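# Water-contact counting: a water "contacts" a residue when its probe atom
# (water oxygen by default) lies within d_water = 0.315 nm of any heavy atom
# of the residue, boundary inclusive. Each water counts at most once per
# residue.

#' Water-contact counting parameters
#'
#' @param d_water Contact cutoff in nm between the water probe atom and a
#'   residue target atom (default 0.315).
#' @param probe_element Element of the water probe atom (default `"O"`, the
#'   conventional water locus; hydrogens add noise).
#' @param heavy_only Restrict residue target atoms to heavy atoms (default
#'   `TRUE`).
#' @return A `contact_params` list.
#' @export
contact_params <- function(d_water = 0.315, probe_element = "O",
                           heavy_only = TRUE) {
  assert_scalar_number(d_water, "d_water", positive = TRUE)
  structure(
    list(d_water = d_water, probe_element = probe_element,
         heavy_only = heavy_only),
    class = "contact_params"
  )
}

probe_atom_rows <- function(structure, params) {
  which(structure$is_solvent & structure$element == params$probe_element)
}

residue_atom_rows <- function(structure, chain, resno, params) {
  sel <- structure$chain == chain & structure$resno == resno &
    !structure$is_solvent & !structure$is_ion
  if (params$heavy_only) sel <- sel & structure$is_heavy
  which(sel)
}

#' Count waters in contact with one residue
#'
#' @param structure A `parch_structure`.
#' @param chain,resno Residue key (chain identifier, residue number as in
#'   the source file).
#' @param xyz Optional `n_atoms x 3` frame coordinates (nm); defaults to the
#'   structure's own coordinates.
#' @param params A [contact_params()] object.
#' @return Integer: number of distinct water molecules whose probe atom is
#'   within `d_water` (inclusive) of any target atom of the residue.
#' @export
count_water_contacts <- function(structure, chain, resno, xyz = NULL,
                                 params = contact_params()) {
  rres <- residue_atom_rows(structure, chain, resno, params)
  if (length(rres) == 0) {
    abort(sprintf("residue %s:%s not found (or has no target atoms)",
                  chain, resno))
  }
  if (is.null(xyz)) xyz <- xyz_matrix(structure)
  if (nrow(xyz) != nrow(structure)) {
    abort("frame coordinates not congruent with structure")
  }
  probes <- probe_atom_rows(structure, params)
  if (length(probes) == 0) return(0L)
  d <- min_dist_to_set(xyz[probes, , drop = FALSE],
                       xyz[rres, , drop = FALSE])
  hit <- d <= params$d_water
  # distinct waters: multiple probe atoms of one water count once
  keys <- res_key(structure$chain[probes], structure$resno[probes])
  length(unique(keys[hit]))
}

#' Per-residue evaporation profiles from an annealing trajectory
#'
#' Counts, frame by frame, the waters in contact with every protein residue
#' and attaches the schedule temperature of each frame. The result is a
#' long tibble: one row per residue per frame.
#'
#' @param traj A `parch_trajectory` congruent with `structure`.
#' @param structure A `parch_structure`.
#' @param schedule An [annealing_schedule()] mapping frame time to K.
#' @param params A [contact_params()] object.
#' @param time_offset Frames earlier than this time (ps) are dropped, e.g.
#'   equilibration carry-over (default 0).
#' @return Tibble with columns `chain`, `resno`, `resname`, `frame`,
#'   `time_ps`, `temperature_k`, `n_contacts`.
#' @export
build_profiles <- function(traj, structure, schedule = annealing_schedule(),
                           params = contact_params(), time_offset = 0) {
  if (traj$n_atoms != nrow(structure)) {
    abort("trajectory not congruent with structure")
  }
  keep <- which(traj$times >= time_offset)
  if (length(keep) == 0) abort("no frames at or after `time_offset`")
  res <- residue_table(structure, protein_only = TRUE)
  if (nrow(res) == 0) abort("structure has no protein residues")
  probes <- probe_atom_rows(structure, params)
  probe_keys <- res_key(structure$chain[probes], structure$resno[probes])
  res_rows <- lapply(seq_len(nrow(res)), function(i) {
    residue_atom_rows(structure, res$chain[i], res$resno[i], params)
  })
  temps <- temperature_at(schedule, traj$times[keep])
  counts <- matrix(0L, nrow = length(keep), ncol = nrow(res))
  for (fi in seq_along(keep)) {
    xyz <- frame_coords(traj, keep[fi])
    if (length(probes) == 0) next
    pxyz <- xyz[probes, , drop = FALSE]
    for (ri in seq_len(nrow(res))) {
      d <- min_dist_to_set(pxyz, xyz[res_rows[[ri]], , drop = FALSE])
      counts[fi, ri] <- length(unique(probe_keys[d <= params$d_water]))
    }
  }
  out <- tidyr::expand_grid(
    residue = seq_len(nrow(res)), frame = seq_along(keep)
  )
  tibble(
    chain = res$chain[out$residue],
    resno = res$resno[out$residue],
    resname = res$resname[out$residue],
    frame = keep[out$frame],
    time_ps = traj$times[keep[out$frame]],
    temperature_k = temps[out$frame],
    n_contacts = counts[cbind(out$frame, out$residue)]
  )
}
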