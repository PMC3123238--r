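# Ideal-geometry peptide construction from internal coordinates.
# Used for the extended Gly-X-Gly burial references and the synthetic toy
# structures; bond lengths/angles are standard values, no force-field
# relaxation. Heavy atoms only.

# NeRF placement: position D given references A, B, C with |CD| = bond,
# angle B-C-D and torsion A-B-C-D (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitize(c - b)
  n <- unitize(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  as.numeric(c + cbind(bc, m, n) %*% d_local)
}

# side-chain internal coordinate tables:
# each row: atom, ref atoms A/B/C, bond (A), angle B-C-D (deg), torsion
# A-B-C-D (deg). Default chi angles give extended (trans) side chains.
SIDE_CHAIN_ICS <- list(
  ALA = list(
    list("CB", c("C", "N", "CA"), 1.53, 110.5, 122.5)
  ),
  VAL = list(
    list("CB", c("C", "N", "CA"), 1.54, 111.5, 122.5),
    list("CG1", c("N", "CA", "CB"), 1.52, 110.5, 180),
    list("CG2", c("N", "CA", "CB"), 1.52, 110.5, -60)
  ),
  LEU = list(
    list("CB", c("C", "N", "CA"), 1.53, 110.5, 122.5),
    list("CG", c("N", "CA", "CB"), 1.53, 116.3, 180),
    list("CD1", c("CA", "CB", "CG"), 1.52, 110.7, 180),
    list("CD2", c("CA", "CB", "CG"), 1.52, 110.7, -60)
  ),
  ILE = list(
    list("CB", c("C", "N", "CA"), 1.54, 111.5, 122.5),
    list("CG1", c("N", "CA", "CB"), 1.53, 110.4, 180),
    list("CG2", c("N", "CA", "CB"), 1.52, 110.5, -60),
    list("CD1", c("CA", "CB", "CG1"), 1.51, 113.8, 180)
  ),
  PHE = list(
    list("CB", c("C", "N", "CA"), 1.53, 110.5, 122.5),
    list("CG", c("N", "CA", "CB"), 1.50, 113.8, 180),
    list("CD1", c("CA", "CB", "CG"), 1.39, 120.0, 90),
    list("CD2", c("CA", "CB", "CG"), 1.39, 120.0, -90),
    list("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.39, 120.0, 180),
    list("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0)
  ),
  TYR = list(
    list("CB", c("C", "N", "CA"), 1.53, 110.5, 122.5),
    list("CG", c("N", "CA", "CB"), 1.51, 113.8, 180),
    list("CD1", c("CA", "CB", "CG"), 1.39, 120.0, 90),
    list("CD2", c("CA", "CB", "CG"), 1.39, 120.0, -90),
    list("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.39, 120.0, 180),
    list("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
    list("OH", c("CD1", "CE1", "CZ"), 1.38, 120.0, 180)
  ),
  GLY = list()
)

#' Residue types available to the peptide builder
#' @return Character vector of 3-letter codes.
#' @export
peptide_residues <- function() names(SIDE_CHAIN_ICS)

#' Build an ideal-geometry peptide
#'
#' Constructs an all-heavy-atom peptide from standard internal coordinates
#' (bond lengths/angles, trans side-chain rotamers), fully extended by
#' default (phi = psi = omega = 180 degrees). This is the generator behind
#' the extended Gly-X-Gly burial references and the toy-structure fixtures.
#'
#' @param sequence Character vector of 3-letter residue names (see
#'   [peptide_residues()]).
#' @param phi,psi,omega Backbone dihedrals in degrees (recycled along the
#'   chain).
#' @return Atom tibble in the standard layout (see [read_structure()]).
#' @export
build_peptide <- function(sequence, phi = 180, psi = 180, omega = 180) {
  sequence <- toupper(sequence)
  unknown <- setdiff(sequence, peptide_residues())
  abort_if(length(unknown) > 0,
           paste("no residue template for:", paste(unknown, collapse = ", ")))
  nres <- length(sequence)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  omega <- rep_len(omega, nres)

  rows <- list()
  add <- function(resno, resid, elety, pos) {
    rows[[length(rows) + 1L]] <<- list(resno = resno, resid = resid,
                                       elety = elety, pos = pos)
  }
  pos_of <- function(resno, elety) {
    for (r in rev(rows)) {
      if (r$resno == resno && r$elety == elety) return(r$pos)
    }
    stop("internal: missing reference atom ", elety, call. = FALSE)
  }

  # first residue backbone in an arbitrary deterministic frame
  add(1L, sequence[1], "N", c(0, 0, 0))
  add(1L, sequence[1], "CA", c(1.458, 0, 0))
  add(1L, sequence[1], "C",
      place_atom(c(0, 1, 0), c(0, 0, 0), c(1.458, 0, 0), 1.525, 111.2, 0))
  for (i in seq_len(nres)) {
    n_i <- pos_of(i, "N"); ca_i <- pos_of(i, "CA"); c_i <- pos_of(i, "C")
    add(i, sequence[i], "O",
        place_atom(n_i, ca_i, c_i, 1.231, 120.8, psi[i] + 180))
    for (ic in SIDE_CHAIN_ICS[[sequence[i]]]) {
      refs <- lapply(ic[[2]], pos_of, resno = i)
      add(i, sequence[i], ic[[1]],
          place_atom(refs[[1]], refs[[2]], refs[[3]], ic[[3]], ic[[4]],
                     ic[[5]]))
    }
    if (i < nres) {
      n_next <- place_atom(n_i, ca_i, c_i, 1.329, 116.2, psi[i])
      add(i + 1L, sequence[i + 1], "N", n_next)
      ca_next <- place_atom(ca_i, c_i, n_next, 1.458, 121.7, omega[i])
      add(i + 1L, sequence[i + 1], "CA", ca_next)
      add(i + 1L, sequence[i + 1], "C",
          place_atom(c_i, n_next, ca_next, 1.525, 111.2, phi[i + 1]))
    }
  }
  atoms_from_rows(rows)
}

atoms_from_rows <- function(rows) {
  pos <- t(vapply(rows, function(r) r$pos, numeric(3)))
  elety <- vapply(rows, function(r) r$elety, "")
  element <- guess_element(elety)
  radii <- vdw_radii()[element]
  tibble::tibble(
    atom_serial = seq_along(rows),
    chain = "A",
    resno = vapply(rows, function(r) as.integer(r$resno), integer(1)),
    insert = "",
    resid = vapply(rows, function(r) r$resid, ""),
    elety = elety,
    element = element,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occupancy = 1,
    altloc = "",
    is_side_chain = !(elety %in% BACKBONE_ATOMS),
    vdw_radius = unname(radii)
  )
}
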