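#' Dot-sampled van der Waals surface with outward normals
#'
#' Each atom's van der Waals sphere is sampled at `density` dots per square
#' Angstrom on a deterministic golden-spiral lattice (so surfaces are
#' reproducible bit for bit), normals pointing radially outward. Points
#' falling strictly inside any other atom's sphere are removed — including
#' the interpenetration points of covalently bonded or disulfide-linked
#' atoms, which are occluded like any other.
#'
#' @param atoms Atom tibble with `vdw_radius` assigned.
#' @param density Dots per square Angstrom (default 10).
#' @param occlusion_tol A point survives when its distance to every other
#'   atom centre exceeds that atom's radius minus this tolerance.
#' @return Surface tibble: `x`, `y`, `z`, `nx`, `ny`, `nz`, `atom_serial`,
#'   `residue` (key), `resid`, `is_side_chain`, `area_weight`; attribute
#'   `density`.
#' @export
dot_surface <- function(atoms, density = 10, occlusion_tol = 1e-9) {
  abort_if(anyNA(atoms$vdw_radius) || any(atoms$vdw_radius <= 0),
           "all atoms need a positive van der Waals radius")
  dot_surface_radii(atoms, atoms$vdw_radius, density, occlusion_tol)
}

# shared worker: sample spheres of the given radii centred on the atoms and
# prune points strictly inside any other sphere
dot_surface_radii <- function(atoms, radii, density, occlusion_tol = 1e-9) {
  n_at <- nrow(atoms)
  centres <- as.matrix(atoms[, c("x", "y", "z")])
  pieces <- vector("list", n_at)
  for (i in seq_len(n_at)) {
    r <- radii[i]
    npt <- max(1L, round(4 * pi * r^2 * density))
    u <- sphere_lattice(npt)
    pts <- sweep(u * r, 2, centres[i, ], `+`)
    keep <- rep(TRUE, npt)
    # neighbour prefilter: only atoms whose sphere can reach atom i's surface
    d_cent <- sqrt(colSums((t(centres) - centres[i, ])^2))
    nb <- which(d_cent < r + radii & seq_len(n_at) != i)
    for (j in nb) {
      d2 <- (pts[, 1] - centres[j, 1])^2 + (pts[, 2] - centres[j, 2])^2 +
        (pts[, 3] - centres[j, 3])^2
      keep <- keep & d2 >= (radii[j] - occlusion_tol)^2
    }
    if (!any(keep)) next
    pieces[[i]] <- tibble::tibble(
      x = pts[keep, 1], y = pts[keep, 2], z = pts[keep, 3],
      nx = u[keep, 1], ny = u[keep, 2], nz = u[keep, 3],
      atom_serial = atoms$atom_serial[i],
      residue = residue_key(atoms$resno[i], atoms$insert[i]),
      resid = atoms$resid[i],
      is_side_chain = atoms$is_side_chain[i],
      area_weight = 4 * pi * r^2 / npt,
      point_index = which(keep)
    )
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "density") <- density
  out
}

# deterministic quasi-uniform unit-sphere lattice (golden spiral)
sphere_lattice <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- (i - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Solvent accessible surface area per residue
#'
#' Shrake-Rupley style SASA on the same dot lattice: spheres are inflated by
#' the probe radius, points strictly inside any other inflated sphere are
#' occluded, and the surviving area is summed per residue (all atoms of the
#' residue, backbone included).
#'
#' @param atoms Atom tibble.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param density Dots per square Angstrom (default 10).
#' @return Tibble: `residue`, `resid`, `sasa` (square Angstrom).
#' @export
residue_sasa <- function(atoms, probe = 1.4, density = 10) {
  surf <- dot_surface_radii(atoms, atoms$vdw_radius + probe, density)
  all_res <- tibble::tibble(
    residue = residue_key(atoms$resno, atoms$insert),
    resid = atoms$resid
  ) |> dplyr::distinct()
  if (nrow(surf) == 0) {
    return(dplyr::mutate(all_res, sasa = 0))
  }
  area <- surf |>
    dplyr::group_by(.data$residue, .data$resid) |>
    dplyr::summarise(sasa = sum(.data$area_weight), .groups = "drop")
  dplyr::left_join(all_res, area, by = c("residue", "resid")) |>
    dplyr::mutate(sasa = dplyr::coalesce(.data$sasa, 0))
}

#' Burial ratios against the extended Gly-X-Gly reference
#'
#' A residue's solvent accessible area in the chain divided by the area of
#' the same residue type as the middle residue of a fully extended
#' (phi = psi = 180 degrees) Gly-X-Gly tripeptide computed with the same
#' radii, probe and dot density. Classification bands: ratio <= 0.05
#' completely buried, <= 0.3 partially buried, above 0.3 excluded from
#' network node sets.
#'
#' @param atoms Atom tibble.
#' @param probe Probe radius (default 1.4).
#' @param density Dot density (default 10).
#' @param reference Optional named reference-area vector (residue name ->
#'   square Angstrom); defaults to [burial_reference()] values computed on
#'   the fly.
#' @return Tibble: `residue`, `resid`, `sasa`, `reference`, `burial`,
#'   `burial_class`.
#' @export
burial_ratios <- function(atoms, probe = 1.4, density = 10,
                          reference = NULL) {
  sas <- residue_sasa(atoms, probe = probe, density = density)
  if (is.null(reference)) {
    reference <- vapply(unique(sas$resid), burial_reference, numeric(1),
                        probe = probe, density = density)
  }
  ref <- reference[sas$resid]
  abort_if(anyNA(ref), paste("no burial reference for residue type(s):",
                             paste(unique(sas$resid[is.na(ref)]),
                                   collapse = ", ")))
  dplyr::mutate(sas,
                reference = unname(ref),
                burial = .data$sasa / .data$reference,
                burial_class = burial_class(.data$burial))
}

#' @rdname burial_ratios
#' @param burial Numeric burial ratios.
#' @export
burial_class <- function(burial) {
  dplyr::case_when(
    burial <= 0.05 ~ "completely buried",
    burial <= 0.3 ~ "partially buried",
    TRUE ~ "exposed"
  )
}

# cache of reference areas keyed by residue/probe/density
the <- new.env(parent = emptyenv())

#' Reference solvent accessible area of residue X in extended Gly-X-Gly
#'
#' Built programmatically from an ideal-geometry, fully extended tripeptide
#' (see [build_peptide()]) and memoised per session.
#'
#' @param resid 3-letter residue name (must be in the peptide template set).
#' @param probe Probe radius.
#' @param density Dot density.
#' @return Reference area in square Angstrom.
#' @export
burial_reference <- function(resid, probe = 1.4, density = 10) {
  key <- paste(resid, probe, density)
  hit <- the$burial_ref[[key]]
  if (!is.null(hit)) return(hit)
  tri <- build_peptide(c("GLY", resid, "GLY"))
  sas <- residue_sasa(tri, probe = probe, density = density)
  val <- sas$sasa[sas$residue == "2"]
  abort_if(length(val) != 1 || val <= 0,
           paste("failed to compute burial reference for", resid))
  if (is.null(the$burial_ref)) the$burial_ref <- list()
  the$burial_ref[[key]] <- val
  val
}
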