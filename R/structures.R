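# Structure container and PDB/GRO input/output. A structure is an atom-level
# tibble (one row per atom) carrying residue identity, nm coordinates and
# solvent/ion flags, with the system's net formal charge as an attribute.

STRUCTURE_COLS <- c(
  "serial", "atom", "element", "resname", "chain", "resno",
  "x", "y", "z", "is_heavy", "is_solvent", "is_ion"
)

#' Build a structure tibble from atom records
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Coordinates are in nm. Water residues (HOH/SOL/TIP3/WAT and friends) are
#' flagged `is_solvent`; monoatomic ion residues are flagged `is_ion`;
#' `is_heavy` marks non-hydrogen atoms.
#'
#' @param atoms Data frame with columns `serial`, `atom` (atom name),
#'   `element`, `resname`, `chain`, `resno`, `x`, `y`, `z` (nm).
#' @param net_charge Integer net formal charge of the system; computed from
#'   composition via [net_charge()] when `NULL`.
#' @return A `parch_structure` tibble, one row per atom.
#' @export
parch_structure <- function(atoms, net_charge = NULL) {
  atoms <- as_tibble(atoms)
  need <- c("serial", "atom", "element", "resname", "chain", "resno",
            "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("structure has no atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in structure")
  }
  if (any(atoms$serial < 1)) abort("atom serials must be >= 1")
  atoms$resno <- as.integer(atoms$resno)
  atoms$serial <- as.integer(atoms$serial)
  atoms$element <- toupper(atoms$element)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  atoms$is_solvent <- atoms$resname %in% WATER_RESNAMES
  n_per_res <- stats::ave(seq_len(nrow(atoms)),
                          paste(atoms$chain, atoms$resno, atoms$resname),
                          FUN = length)
  atoms$is_ion <- !atoms$is_solvent &
    atoms$resname %in% names(ION_CHARGES) & n_per_res == 1L
  atoms <- atoms[, STRUCTURE_COLS]
  out <- structure(atoms, class = c("parch_structure", class(atoms)))
  attr(out, "net_charge") <-
    if (is.null(net_charge)) net_charge_from_composition(out)
    else as.integer(net_charge)
  out
}

#' System net formal charge
#'
#' Returns the net formal charge stored on a structure, or (for
#' `net_charge_from_composition()`) recomputes it from residue bookkeeping:
#' Arg/Lys +1, Asp/Glu -1, phospho-residues -2, acetyl-lysine 0,
#' monomethylated Lys/Arg +1, plus ion species charges. Chain termini and
#' protonation variants are not modelled; supply `net_charge` to
#' [parch_structure()] or [read_structure()] when the prepared system's
#' charge is known.
#'
#' @param structure A `parch_structure`.
#' @return Integer charge in elementary units.
#' @export
net_charge <- function(structure) {
  attr(structure, "net_charge") %||% net_charge_from_composition(structure)
}

#' @rdname net_charge
#' @export
net_charge_from_composition <- function(structure) {
  res <- distinct(as_tibble(structure)[, c("chain", "resno", "resname",
                                           "is_solvent", "is_ion")])
  q <- 0
  prot <- res[!res$is_solvent & !res$is_ion, ]
  hit <- RESIDUE_CHARGES[prot$resname]
  q <- q + sum(hit, na.rm = TRUE)
  ions <- res[res$is_ion, ]
  q <- q + sum(ION_CHARGES[ions$resname], na.rm = TRUE)
  as.integer(round(q))
}

protein_rows <- function(structure) {
  !structure$is_solvent & !structure$is_ion &
    is_protein_resname(structure$resname)
}

# Residue-level view of a structure (one row per residue, in file order).
residue_table <- function(structure, protein_only = FALSE) {
  tbl <- as_tibble(structure)
  if (protein_only) tbl <- tbl[protein_rows(structure), ]
  distinct(tbl[, c("chain", "resno", "resname", "is_solvent", "is_ion")])
}

guess_element <- function(atom, resname) {
  ion_hit <- resname %in% names(ION_CHARGES)
  el <- toupper(sub("^[0-9']*", "", atom))
  el <- substr(el, 1L, 1L)
  # two-letter ion elements come from the residue name, not the atom name
  el[ion_hit] <- vapply(resname[ion_hit], function(rn) {
    switch(rn, "NA" = , SOD = "NA", "K" = , POT = "K", CL = , CLA = "CL",
           MG = , MG2 = "MG", CAL = "CA", ZN = , ZN2 = "ZN", BR = "BR",
           LI = "LI", substr(rn, 1, 2))
  }, character(1))
  el
}

#' Read a protein structure from PDB or GRO
#'
#' Parses ATOM/HETATM records (PDB, via bio3d) or a GRO coordinate file into
#' an atom-level tibble. Coordinates are converted to nm (PDB Angstroms are
#' divided by 10); residue numbering is kept verbatim from the source file.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param net_charge Optional known net charge; otherwise computed from
#'   composition.
#' @return A `parch_structure` tibble.
#' @examples
#' pdb <- system.file("extdata", "toy_dipeptide.pdb", package = "parchr")
#' if (nzchar(pdb)) read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           net_charge = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("cannot read structure: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_gro_atoms(path)
  st <- parch_structure(atoms, net_charge = net_charge)
  if (!any(protein_rows(st))) {
    abort(paste0("no protein residues found in ", path))
  }
  st
}

read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  element <- a$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  element[bad] <- guess_element(a$elety[bad], a$resid[bad])
  chain <- a$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  tibble(
    serial = a$eleno,
    atom = a$elety,
    element = trimws(element),
    resname = trimws(a$resid),
    chain = chain,
    resno = a$resno,
    x = a$x / 10, y = a$y / 10, z = a$z / 10
  )
}

read_gro_atoms <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("GRO file too short")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || length(lines) < 2 + natoms) {
    abort("malformed GRO file: bad atom count")
  }
  body <- lines[3:(2 + natoms)]
  resno <- as.integer(substr(body, 1, 5))
  resname <- trimws(substr(body, 6, 10))
  atom <- trimws(substr(body, 11, 15))
  serial <- suppressWarnings(as.integer(substr(body, 16, 20)))
  serial[is.na(serial)] <- seq_along(body)[is.na(serial)]
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  tibble(
    serial = serial, atom = atom,
    element = guess_element(atom, resname),
    resname = resname, chain = "A", resno = resno,
    x = x, y = y, z = z
  )
}

format_pdb_atom_name <- function(atom, element) {
  # element symbols of one letter start in column 14
  ifelse(nchar(atom) >= 4, sprintf("%-4s", atom),
         ifelse(nchar(element) == 1, sprintf(" %-3s", atom),
                sprintf("%-4s", atom)))
}

pdb_atom_lines <- function(structure, xyz = NULL) {
  tbl <- as_tibble(structure)
  if (is.null(xyz)) xyz <- xyz_matrix(tbl)
  rec <- ifelse(tbl$is_solvent | tbl$is_ion, "HETATM", "ATOM  ")
  sprintf(
    "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, tbl$serial %% 100000L,
    format_pdb_atom_name(tbl$atom, tbl$element),
    tbl$resname, substr(tbl$chain, 1, 1), tbl$resno %% 10000L,
    xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10,
    1.0, 0.0, tbl$element
  )
}

#' Write a structure to PDB or GRO
#'
#' Emits a normalized coordinate file for downstream stages or an external
#' MD engine. PDB output is in Angstroms, GRO in nm.
#'
#' @param structure A `parch_structure`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param box Optional 3-vector (nm) written as the GRO box line.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "gro"),
                            box = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (format == "pdb") {
    writeLines(c(pdb_atom_lines(structure), "END"), path)
  } else {
    tbl <- as_tibble(structure)
    if (is.null(box)) {
      box <- c(diff(range(tbl$x)), diff(range(tbl$y)), diff(range(tbl$z))) + 2
    }
    lines <- c(
      "parchr system",
      sprintf("%5d", nrow(tbl)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              tbl$resno %% 100000L, tbl$resname, substr(tbl$atom, 1, 5),
              tbl$serial %% 100000L, tbl$x, tbl$y, tbl$z),
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.parch_structure <- function(x, ...) {
  resi <- residue_table(x)
  cat(sprintf(
    "<parch_structure> %d atoms | %d protein residues | %d waters | %d ions | net charge %+d e\n",
    nrow(x), sum(!resi$is_solvent & !resi$is_ion & is_protein_resname(resi$resname)),
    sum(resi$is_solvent), sum(resi$is_ion), net_charge(x)
  ))
  NextMethod()
}
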