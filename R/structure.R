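#' Van der Waals radius table
#'
#' Element-keyed van der Waals radii (Angstrom) in the style of an all-atom
#' molecular-mechanics force field; the exact set is configurable because
#' published force fields differ at the second decimal. Values default to the
#' standard crystallographic (Bondi-type) radii.
#'
#' @param overrides Optional named numeric vector replacing or extending the
#'   defaults (names are element symbols).
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function(overrides = NULL) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  if (!is.null(overrides)) r[names(overrides)] <- overrides
  r
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HXT")

# expected heavy side-chain atoms per residue, used to flag incomplete
# side chains (such residues are excluded from network node sets upstream)
SIDE_CHAIN_HEAVY <- list(
  GLY = character(0),
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  SER = c("CB", "OG"), THR = c("CB", "OG1", "CG2"), CYS = c("CB", "SG"),
  MET = c("CB", "CG", "SD", "CE"), ASP = c("CB", "CG", "OD1", "OD2"),
  ASN = c("CB", "CG", "OD1", "ND2"), GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  PRO = c("CB", "CG", "CD")
)

guess_element <- function(elety) {
  e <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- substr(e, 1, 2)
  out <- ifelse(two %in% c("SE", "CL", "BR"), two, substr(e, 1, 1))
  # hydrogens named like 1HB2 lose the digit above; names such as HG1 must
  # not be read as mercury in a protein context
  out[substr(e, 1, 1) == "H"] <- "H"
  out
}

#' Load a single protein chain from a PDB file
#'
#' Applies the database loading policies: standard `ATOM` records only
#' (hetero groups and waters dropped), one chain retained (the largest by
#' residue count, or a named one), and for atoms with alternate locations the
#' conformer with the highest occupancy (the first on ties). Hydrogens are
#' retained when present unless `ignore_hydrogens`.
#'
#' @param path PDB file path.
#' @param chain_policy `"largest"` or `"named"`.
#' @param chain_id Chain identifier, required for `chain_policy = "named"`.
#' @param ignore_hydrogens Drop hydrogen atoms after loading.
#' @param radii Radius table from [vdw_radii()].
#' @return Atom tibble: `atom_serial`, `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`, `occupancy`, `altloc`,
#'   `is_side_chain`, `vdw_radius`. Residues with incomplete side chains are
#'   reported with a warning and listed in the `incomplete` attribute.
#' @export
read_structure <- function(path, chain_policy = c("largest", "named"),
                           chain_id = NULL, ignore_hydrogens = FALSE,
                           radii = vdw_radii()) {
  chain_policy <- match.arg(chain_policy)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  abort_if(nrow(at) == 0, "no protein chain found in file")
  at$chain[is.na(at$chain)] <- " "
  if (chain_policy == "named") {
    abort_if(is.null(chain_id), "chain_policy = 'named' needs a chain_id")
    abort_if(!chain_id %in% at$chain,
             paste0("chain '", chain_id, "' not found"))
    at <- at[at$chain == chain_id, , drop = FALSE]
  } else {
    sizes <- vapply(split(at, at$chain), function(d) {
      length(unique(paste(d$resno, d$insert)))
    }, numeric(1))
    at <- at[at$chain == names(sizes)[which.max(sizes)], , drop = FALSE]
  }
  # altloc policy: highest occupancy, first conformer on ties (file order)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  atom_key <- paste(at$resno, at$insert, at$elety)
  ord <- order(match(atom_key, unique(atom_key)), -at$o,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
  if (ignore_hydrogens) {
    at <- at[guess_element(at$elety) != "H", , drop = FALSE]
  }
  element <- at$elesy
  element[is.na(element) | element == ""] <- guess_element(at$elety[
    is.na(element) | element == ""])
  element <- toupper(element)
  vr <- radii[element]
  abort_if(anyNA(vr), paste("no van der Waals radius for element(s):",
                            paste(unique(element[is.na(vr)]), collapse = ", ")))
  out <- tibble::tibble(
    atom_serial = at$eleno,
    chain = at$chain,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    altloc = at$alt,
    is_side_chain = !(at$elety %in% BACKBONE_ATOMS),
    vdw_radius = unname(vr)
  )
  inc <- incomplete_side_chains(out)
  if (length(inc)) {
    warning("residue(s) with incomplete side chains: ",
            paste(inc, collapse = ", "),
            "; exclude them from network node sets", call. = FALSE)
  }
  attr(out, "chain_id") <- unique(out$chain)
  attr(out, "incomplete") <- inc
  out
}

#' Residues whose expected heavy side-chain atoms are not all present
#'
#' @param atoms Atom tibble.
#' @return Character vector of residue keys.
#' @export
incomplete_side_chains <- function(atoms) {
  keys <- residue_key(atoms$resno, atoms$insert)
  bad <- character(0)
  for (k in unique(keys)) {
    sub <- atoms[keys == k, , drop = FALSE]
    expected <- SIDE_CHAIN_HEAVY[[sub$resid[1]]]
    if (is.null(expected)) next
    if (!all(expected %in% sub$elety)) bad <- c(bad, k)
  }
  bad
}

#' Write an atom tibble to a PDB file
#'
#' @param atoms Atom tibble (as produced by [read_structure()],
#'   [build_peptide()] or [gen_toy_structure()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(atoms)),
    resno = atoms$resno,
    resid = atoms$resid,
    eleno = atoms$atom_serial,
    elety = atoms$elety,
    chain = atoms$chain,
    insert = ifelse(atoms$insert == "", NA, atoms$insert),
    o = atoms$occupancy,
    b = rep(0, nrow(atoms)),
    elesy = atoms$element
  )
  invisible(path)
}
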