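# PTM site recognition and residue mapping between the unmodified and
# modified variants of a protein.

#' Identify post-translationally modified residues
#'
#' Scans a structure for residues whose three-letter code appears in the
#' recognition table and returns one row per modification site. Nonstandard
#' residue names that are neither canonical amino acids, waters, ions nor
#' recognized modifications trigger a single warning and are skipped.
#'
#' @param structure A `parch_structure`.
#' @param recognition Recognition table, see [ptm_recognition_table()].
#' @return A tibble with columns `chain`, `resno`, `resname`, `mod_type`,
#'   `parent_code` (possibly zero rows).
#' @examples
#' st <- parch_structure(data.frame(
#'   serial = 1:2, atom = "CA", element = "C",
#'   resname = c("SEP", "ALA"), chain = "A", resno = c(79, 80),
#'   x = c(0, 1), y = 0, z = 0
#' ))
#' identify_ptm_sites(st)
#' @export
identify_ptm_sites <- function(structure,
                               recognition = ptm_recognition_table()) {
  res <- residue_table(structure)
  res <- res[!res$is_solvent & !res$is_ion, ]
  unknown <- setdiff(
    res$resname, c(names(CANONICAL_AA), recognition$resname)
  )
  if (length(unknown) > 0) {
    warn(paste0(
      "skipping unrecognized residue name(s): ",
      paste(sort(unknown), collapse = ", ")
    ))
  }
  hits <- inner_join(res[, c("chain", "resno", "resname")], recognition,
                     by = "resname")
  arrange(
    hits[, c("chain", "resno", "resname", "mod_type", "parent_code")],
    .data$chain, .data$resno
  )
}

chain_sequences <- function(structure,
                            recognition = ptm_recognition_table()) {
  res <- residue_table(structure, protein_only = TRUE)
  res$code <- parent_one_letter(res$resname, recognition)
  res <- res[!is.na(res$code), ]
  split(res, res$chain)
}

#' Map residues between unmodified and modified structures
#'
#' Pairs residues of the two variants by global alignment of their
#' parent-code sequences chain by chain (match 1, mismatch 0, linear gap
#' -1), so a modified residue pairs with its canonical parent at the same
#' aligned position. Chains are paired by shared chain identifier when
#' possible, otherwise in order of appearance.
#'
#' @param unmod,mod `parch_structure` objects of the two variants.
#' @param min_identity Alignment identity floor over aligned columns
#'   (default 0.9); lower identity raises an error since the two files then
#'   likely describe different proteins.
#' @param recognition Recognition table for modified-residue parent codes.
#' @return A tibble with one row per paired residue: `chain_unmod`,
#'   `resno_unmod`, `resname_unmod`, `chain_mod`, `resno_mod`,
#'   `resname_mod`. Residues present in only one structure are recorded in
#'   the `unmatched` attribute (a tibble with a `variant` column).
#' @export
map_residues <- function(unmod, mod, min_identity = 0.9,
                         recognition = ptm_recognition_table()) {
  su <- chain_sequences(unmod, recognition)
  sm <- chain_sequences(mod, recognition)
  if (length(su) == 0 || length(sm) == 0) {
    abort("both structures must contain protein residues")
  }
  shared <- intersect(names(su), names(sm))
  chain_pairs <- if (length(shared) > 0) {
    lapply(shared, function(cn) list(u = su[[cn]], m = sm[[cn]]))
  } else {
    k <- min(length(su), length(sm))
    lapply(seq_len(k), function(i) list(u = su[[i]], m = sm[[i]]))
  }
  pairs <- list()
  unmatched <- list()
  for (cp in chain_pairs) {
    al <- align_parent_codes(cp$u$code, cp$m$code)
    ident <- mean(al$match[al$both])
    if (!is.finite(ident) || ident < min_identity) {
      abort(sprintf(
        "chain alignment identity %.2f below floor %.2f; variants do not match",
        ident %||% 0, min_identity
      ))
    }
    iu <- al$i_unmod[al$both]
    im <- al$i_mod[al$both]
    pairs[[length(pairs) + 1]] <- tibble(
      chain_unmod = cp$u$chain[iu], resno_unmod = cp$u$resno[iu],
      resname_unmod = cp$u$resname[iu],
      chain_mod = cp$m$chain[im], resno_mod = cp$m$resno[im],
      resname_mod = cp$m$resname[im]
    )
    only_u <- setdiff(seq_len(nrow(cp$u)), iu)
    only_m <- setdiff(seq_len(nrow(cp$m)), im)
    if (length(only_u) > 0) {
      unmatched[[length(unmatched) + 1]] <- tibble(
        variant = "unmod", chain = cp$u$chain[only_u],
        resno = cp$u$resno[only_u], resname = cp$u$resname[only_u]
      )
    }
    if (length(only_m) > 0) {
      unmatched[[length(unmatched) + 1]] <- tibble(
        variant = "mod", chain = cp$m$chain[only_m],
        resno = cp$m$resno[only_m], resname = cp$m$resname[only_m]
      )
    }
  }
  out <- bind_rows(pairs)
  attr(out, "unmatched") <- if (length(unmatched) > 0) bind_rows(unmatched)
    else tibble(variant = character(), chain = character(),
                resno = integer(), resname = character())
  class(out) <- c("parch_mapping", class(out))
  out
}

# Global alignment of two one-letter code vectors; returns per-column
# indices into each sequence plus match flags. Scoring: match 1, mismatch
# 0, linear gap -1 (gapOpening 0 / gapExtension 1 in Biostrings terms).
align_parent_codes <- function(codes_u, codes_m) {
  alphabet <- sort(unique(c(codes_u, codes_m, "X")))
  submat <- diag(1, length(alphabet))
  dimnames(submat) <- list(alphabet, alphabet)
  aln <- Biostrings::pairwiseAlignment(
    paste(codes_u, collapse = ""), paste(codes_m, collapse = ""),
    type = "global", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 1
  )
  gu <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gm <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i_unmod <- cumsum(gu != "-")
  i_mod <- cumsum(gm != "-")
  both <- gu != "-" & gm != "-"
  list(i_unmod = i_unmod, i_mod = i_mod, both = both,
       match = gu == gm)
}
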