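# Residue chemistry tables: canonical amino acids, recognized modified
# residues, solvent and ion names, and the per-residue formal charges used
# for net-charge bookkeeping.

CANONICAL_AA <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

WATER_RESNAMES <- c("HOH", "SOL", "WAT", "TIP", "TIP3", "TIP3P", "SPC", "T3P")

# species -> formal charge; resnames cover PDB and GROMACS/CHARMM conventions
ION_CHARGES <- c(
  "NA" = 1, SOD = 1, "K" = 1, POT = 1, LI = 1,
  CL = -1, CLA = -1, BR = -1,
  MG = 2, MG2 = 2, CAL = 2, ZN = 2, ZN2 = 2
)

# Residue-level formal charges at neutral pH used when computing a system's
# net charge from composition (termini ignored). Phosphorylated side chains
# carry the -2 phosphate; acetyl-lysine is neutralized; monomethylation
# preserves the +1.
RESIDUE_CHARGES <- c(
  ARG = 1, LYS = 1, ASP = -1, GLU = -1,
  SEP = -2, TPO = -2, PTR = -2,
  ALY = 0, MLZ = 1, MLY = 1, NMM = 1
)

#' Recognition table for modified residues
#'
#' Maps three-letter codes of post-translationally modified residues to the
#' modification type (`ph` phosphorylation, `ac` acetylation, `me`
#' monomethylation) and the one-letter code of the canonical parent residue.
#' The defaults cover phosphoserine (SEP), phosphothreonine (TPO),
#' phosphotyrosine (PTR), N6-acetyllysine (ALY), monomethyl-lysine
#' (MLZ/MLY) and omega-N-methylarginine (NMM). Structure-preparation tools
#' vary in the codes they emit, so the table is extensible: pass extra rows
#' to cover a local convention.
#'
#' @param extra Optional tibble/data frame with columns `resname`,
#'   `mod_type` (one of "ph", "ac", "me") and `parent_code` (one-letter),
#'   appended to (and overriding) the defaults.
#' @return A tibble with columns `resname`, `mod_type`, `parent_code`.
#' @examples
#' ptm_recognition_table()
#' ptm_recognition_table(extra = data.frame(
#'   resname = "M3L", mod_type = "me", parent_code = "K"
#' ))
#' @export
ptm_recognition_table <- function(extra = NULL) {
  tab <- tibble(
    resname = c("SEP", "TPO", "PTR", "ALY", "MLZ", "MLY", "NMM"),
    mod_type = c("ph", "ph", "ph", "ac", "me", "me", "me"),
    parent_code = c("S", "T", "Y", "K", "K", "K", "R")
  )
  if (!is.null(extra)) {
    extra <- as_tibble(extra)
    stopifnot(all(c("resname", "mod_type", "parent_code") %in% names(extra)))
    if (!all(extra$mod_type %in% c("ph", "ac", "me"))) {
      abort("`mod_type` must be one of \"ph\", \"ac\", \"me\".")
    }
    tab <- bind_rows(tab[!tab$resname %in% extra$resname, ], extra)
  }
  tab
}

# One-letter parent code for a vector of three-letter residue names; NA for
# names that are neither canonical nor in the recognition table.
parent_one_letter <- function(resname, recognition = ptm_recognition_table()) {
  out <- unname(CANONICAL_AA[resname])
  idx <- match(resname, recognition$resname)
  out[!is.na(idx)] <- recognition$parent_code[idx[!is.na(idx)]]
  out
}

is_protein_resname <- function(resname,
                               recognition = ptm_recognition_table()) {
  resname %in% names(CANONICAL_AA) | resname %in% recognition$resname
}
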