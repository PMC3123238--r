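#' Internal right-handed reference frame of a hydrophobic residue
#'
#' The Z axis is the normal to the residue's principal plane: the
#' least-squares plane of the ring atoms for aromatics (phenyl for Phe/Tyr,
#' indole for Trp) or the plane of the three fork atoms for branched residues
#' (Val: CB-CG1-CG2, Leu: CG-CD1-CD2, Ile: CB-CG1-CG2). The origin is the
#' ring centroid (aromatics) or the fork apex (branched); X points from the
#' origin towards the first defining atom, projected into the plane, and
#' Y = Z x X. Alanine, lacking a fork, uses origin CB, Z along CA->CB and X
#' as the in-plane component of CA->N — a deterministic but
#' convention-dependent choice.
#'
#' @param residue_atoms Atom tibble of a single residue (columns `resid`,
#'   `elety`, `x`, `y`, `z`).
#' @return An object of class `residue_frame`: list with `origin`, `x`, `y`,
#'   `z` (orthonormal, right-handed) and `residue`.
#' @export
residue_frame <- function(residue_atoms) {
  resid <- unique(residue_atoms$resid)
  abort_if(length(resid) != 1, "expected atoms of exactly one residue")
  get_atoms <- function(names) {
    idx <- match(names, residue_atoms$elety)
    abort_if(anyNA(idx), paste0(resid, ": missing frame atoms ",
                                paste(names[is.na(idx)], collapse = ", ")))
    as.matrix(residue_atoms[idx, c("x", "y", "z")])
  }
  ring_sets <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  )
  fork_sets <- list(
    VAL = c("CB", "CG1", "CG2"),
    LEU = c("CG", "CD1", "CD2"),
    ILE = c("CB", "CG1", "CG2")
  )
  if (resid %in% names(ring_sets)) {
    ring <- get_atoms(ring_sets[[resid]])
    origin <- colMeans(ring)
    centred <- sweep(ring, 2, origin)
    sv <- svd(centred)
    z <- sv$v[, 3]
    # deterministic normal sign: along the cross product of the first two
    # ring bonds from the centroid
    ref <- cross3(centred[1, ], centred[2, ])
    if (sum(z * ref) < 0) z <- -z
    x_raw <- centred[1, ]
  } else if (resid %in% names(fork_sets)) {
    fk <- get_atoms(fork_sets[[resid]])
    origin <- fk[1, ]
    v1 <- fk[2, ] - origin
    v2 <- fk[3, ] - origin
    nrm <- cross3(v1, v2)
    abort_if(vnorm(nrm) < 1e-9 * vnorm(v1) * vnorm(v2),
             paste0(resid, ": fork atoms are collinear, no plane defined"))
    z <- unitize(nrm)
    x_raw <- v1
  } else if (resid == "ALA") {
    at <- get_atoms(c("CB", "CA", "N"))
    origin <- at[1, ]
    z <- unitize(at[1, ] - at[2, ])           # CA -> CB
    x_raw <- at[3, ] - at[2, ]                # CA -> N, projected below
  } else {
    stop("no frame convention for residue type ", resid, call. = FALSE)
  }
  x <- x_raw - sum(x_raw * z) * z
  abort_if(vnorm(x) < 1e-9, paste0(resid, ": degenerate X axis"))
  x <- unname(unitize(x))
  z <- unname(z)
  y <- cross3(z, x)
  structure(list(origin = unname(as.numeric(origin)), x = x, y = y, z = z,
                 residue = resid),
            class = "residue_frame")
}

#' Build a residue frame directly from its components
#'
#' Used by the synthetic generators; validates orthonormality and
#' right-handedness.
#'
#' @param origin 3-vector.
#' @param x,y,z Orthonormal right-handed unit vectors (`y` defaults to
#'   `z x x`).
#' @param residue Residue name label.
#' @return A `residue_frame`.
#' @export
new_residue_frame <- function(origin, x, z, y = cross3(z, x),
                              residue = "SYN") {
  abort_if(abs(vnorm(x) - 1) > 1e-9 || abs(vnorm(z) - 1) > 1e-9,
           "frame axes must be unit vectors")
  abort_if(abs(sum(x * z)) > 1e-9, "frame axes must be orthogonal")
  abort_if(vnorm(cross3(x, y) - z) > 1e-9, "frame must be right-handed")
  structure(list(origin = as.numeric(origin), x = x, y = y, z = z,
                 residue = residue),
            class = "residue_frame")
}

#' Triangle geometry of a triplet clique
#'
#' Joins the origins of the three residue frames into a triangle (side
#' lengths `r_12`, `r_13`, `r_23`; internal angles `Omega_1..3` summing to
#' 180 degrees) and places the global frame: origin at the centroid, Z along
#' `v1 x v2` (v1 = R1->R2, v2 = R1->R3), X towards R1's origin, Y = Z x X.
#' Residue ordering follows the composition class: C1 sorts R1 > R2 > R3 by
#' side-chain volume; C2 takes the unique residue as R1 with R2/R3 assigned
#' so the tilt of R1 is acute (or, given a `template`, by best origin
#' superposition); C3 uses the given order as template, or the best of the 6
#' label permutations by superposition residual. `cls = "none"` keeps the
#' input order (synthetic round trips).
#'
#' @param frames List of three `residue_frame` objects.
#' @param cls `"C1"`, `"C2"`, `"C3"`, `"none"` or a result of
#'   [composition_class()].
#' @param template Optional template `triangle_geometry` for C2/C3
#'   superposition.
#' @param volumes Named side-chain volume table for C1 ordering.
#' @return Object of class `triangle_geometry`: list with `r` (r_12, r_13,
#'   r_23), `omega` (degrees), `centroid`, `x_tr`, `y_tr`, `z_tr`, `frames`
#'   (reordered) and `order` (permutation applied to the input).
#' @export
triangle_geometry <- function(frames, cls = "none", template = NULL,
                              volumes = side_chain_volumes()) {
  abort_if(length(frames) != 3, "need exactly three residue frames")
  if (inherits(cls, "composition_class")) cls <- cls$class
  cls <- match.arg(cls, c("C1", "C2", "C3", "none"))
  perm <- order_triplet(frames, cls, template, volumes)
  frames <- frames[perm]
  o <- t(vapply(frames, function(f) f$origin, numeric(3)))
  v1 <- o[2, ] - o[1, ]
  v2 <- o[3, ] - o[1, ]
  nrm <- cross3(v1, v2)
  abort_if(vnorm(nrm) < 1e-9, "triplet origins are collinear")
  r <- c(r_12 = vnorm(v1), r_13 = vnorm(v2), r_23 = vnorm(o[3, ] - o[2, ]))
  omega <- c(
    omega_1 = vec_angle(o[2, ] - o[1, ], o[3, ] - o[1, ]),
    omega_2 = vec_angle(o[1, ] - o[2, ], o[3, ] - o[2, ]),
    omega_3 = vec_angle(o[1, ] - o[3, ], o[2, ] - o[3, ])
  )
  centroid <- colMeans(o)
  z_tr <- unitize(nrm)
  x_raw <- o[1, ] - centroid
  x_tr <- unitize(x_raw - sum(x_raw * z_tr) * z_tr)
  y_tr <- cross3(z_tr, x_tr)
  structure(list(r = r, omega = omega, centroid = centroid,
                 x_tr = x_tr, y_tr = y_tr, z_tr = z_tr,
                 frames = frames, order = perm),
            class = "triangle_geometry")
}

order_triplet <- function(frames, cls, template, volumes) {
  res <- vapply(frames, function(f) f$residue, "")
  if (cls == "none") return(1:3)
  if (cls == "C1") {
    vol <- volumes[res]
    abort_if(anyNA(vol), paste("no side-chain volume for:",
                               paste(res[is.na(vol)], collapse = ", ")))
    # descending volume; deterministic alphabetical tie-break
    return(order(-vol, res))
  }
  if (cls == "C2") {
    tab <- table(res)
    abort_if(length(tab) != 2, "C2 requires exactly two distinct residues")
    unique_res <- names(tab)[tab == 1]
    i1 <- which(res == unique_res)
    rest <- setdiff(1:3, i1)
    cands <- list(c(i1, rest), c(i1, rev(rest)))
  } else { # C3
    abort_if(length(unique(res)) != 1, "C3 requires three identical residues")
    if (is.null(template)) {
      # the bare origin triangle is achiral, so an arbitrary label order
      # would flip the triangle normal (mirroring every tilt angle) from one
      # template to another; fix the chirality from the template's own
      # physics: the normal must have a non-negative mean projection on the
      # residue Z axes (swapping R2/R3 flips it)
      o <- t(vapply(frames, function(f) f$origin, numeric(3)))
      z_tr <- unitize(cross3(o[2, ] - o[1, ], o[3, ] - o[1, ]))
      zsum <- frames[[1]]$z + frames[[2]]$z + frames[[3]]$z
      return(if (sum(z_tr * zsum) >= 0) 1:3 else c(1, 3, 2))
    }
    cands <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
  }
  if (is.null(template)) {
    # C2 without template: pick the assignment giving an acute tilt for R1
    for (p in cands) {
      o <- t(vapply(frames[p], function(f) f$origin, numeric(3)))
      z_tr <- unitize(cross3(o[2, ] - o[1, ], o[3, ] - o[1, ]))
      if (sum(z_tr * frames[[p[1]]]$z) >= 0) return(p)
    }
    return(cands[[1]])
  }
  to <- t(vapply(template$frames, function(f) f$origin, numeric(3)))
  tz <- lapply(template$frames, function(f) f$z)
  # a bare triangle is achiral: both label chiralities of the origins can be
  # superposed exactly by a proper rotation, so the origin RMSD alone cannot
  # decide between them. The residue Z axes break that tie (small weight:
  # origins still dominate whenever they discriminate).
  rss <- vapply(cands, function(p) {
    po <- t(vapply(frames[p], function(f) f$origin, numeric(3)))
    fit <- kabsch_fit(po, to)
    zmis <- vapply(seq_len(3), function(i) {
      1 - sum((fit$rot %*% frames[[p[i]]]$z) * tz[[i]])
    }, numeric(1))
    fit$rmsd + 0.01 * sum(zmis)
  }, numeric(1))
  cands[[which.min(rss)]]
}

# rigid-body (proper rotation) least-squares fit of point set P onto Q;
# returns the residual RMSD and the rotation applied to centred P
kabsch_fit <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  sv <- svd(crossprod(pc, qc))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rmsd = sqrt(mean(rowSums((pc %*% t(rot) - qc)^2))), rot = rot)
}

kabsch_rmsd <- function(p, q) kabsch_fit(p, q)$rmsd

#' Tilt angles of a triplet clique
#'
#' Angles (degrees, in `[0, 180]`) subtended between the triangle normal
#' `Z_tr` and the internal Z axes of the three residues; they describe how
#' each residue's principal plane is inclined to the triangle plane.
#'
#' @param tri A `triangle_geometry`.
#' @return Named numeric vector `theta_1t`, `theta_2t`, `theta_3t`.
#' @export
tilt_angles <- function(tri) {
  th <- vapply(tri$frames, function(f) vec_angle(tri$z_tr, f$z), numeric(1))
  stats::setNames(th, c("theta_1t", "theta_2t", "theta_3t"))
}

#' Swivel angles of a triplet clique
#'
#' For each residue, `Z_tr` is projected onto the residue's XY plane (giving
#' `Z_p`) and the signed angle from the internal X axis to `Z_p` about the
#' internal Z axis is reported in `[0, 360)`. Undefined (returned as `NA`,
#' with a warning) when `Z_tr` is parallel to the residue Z (tilt 0 or 180
#' degrees).
#'
#' @param tri A `triangle_geometry`.
#' @param tol Projection-length tolerance below which the swivel is flagged
#'   undefined.
#' @return Named numeric vector `phi_1s`, `phi_2s`, `phi_3s` (degrees).
#' @export
swivel_angles <- function(tri, tol = 1e-9) {
  phi <- vapply(tri$frames, function(f) {
    zp <- tri$z_tr - sum(tri$z_tr * f$z) * f$z
    if (vnorm(zp) < tol) return(NA_real_)
    a <- atan2(sum(cross3(f$x, zp) * f$z), sum(f$x * zp)) * 180 / pi
    (a + 360) %% 360
  }, numeric(1))
  if (anyNA(phi)) {
    warning("swivel undefined for residue(s) with tilt 0 or 180 degrees",
            call. = FALSE)
  }
  stats::setNames(phi, c("phi_1s", "phi_2s", "phi_3s"))
}

#' Expected random tilt-bin fractions
#'
#' The angle between two randomly oriented vectors has density
#' `sin(theta)/2`, so a 30-degree bin `[a, b]` holds the fraction
#' `(cos a - cos b) / 2`. The six-bin model covers `[0, 180]`; the three-bin
#' model folds theta onto `[0, 90]` (appropriate for the two-fold ring
#' symmetry of Phe and Tyr), exactly doubling the folded fractions.
#'
#' @param bin_model `"6bin-30"` or `"3bin-30-folded"`.
#' @return A tibble with `bin_lo`, `bin_hi` (degrees) and `fraction`.
#' @export
random_tilt_fractions <- function(bin_model = c("6bin-30", "3bin-30-folded")) {
  bin_model <- match.arg(bin_model)
  edges <- seq(0, 180, by = 30)
  frac6 <- (cos(edges[-7] * pi / 180) - cos(edges[-1] * pi / 180)) / 2
  if (bin_model == "6bin-30") {
    tibble::tibble(bin_lo = edges[-7], bin_hi = edges[-1], fraction = frac6)
  } else {
    tibble::tibble(bin_lo = edges[1:3], bin_hi = edges[2:4],
                   fraction = 2 * frac6[1:3])
  }
}

#' Chi-squared test of an angle sample against its random null
#'
#' Bins the observed angles and computes `chi2 = sum((O - E)^2 / E)` against
#' the analytic expectation: the `sin(theta)/2` null for tilt angles (six-bin
#' or folded three-bin model) or the uniform null for swivel angles
#' (coplanar vectors populate each bin equally). Significance is judged
#' against the chi-squared critical value at `alpha` with `bins - 1` degrees
#' of freedom; the standard validity flag requires every expected count to be
#' at least 5.
#'
#' @param observed Numeric vector of angles in degrees.
#' @param model `"tilt-random-6bin"`, `"tilt-random-3bin"` or
#'   `"swivel-uniform"`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `chi2_angles`: `statistic`, `df`, `critical`,
#'   `significant`, `valid`, and the per-bin `table`; has `tidy()`/`glance()`
#'   methods.
#' @export
chi2_angles <- function(observed,
                        model = c("tilt-random-6bin", "tilt-random-3bin",
                                  "swivel-uniform"),
                        alpha = 0.05) {
  model <- match.arg(model)
  observed <- observed[!is.na(observed)]
  abort_if(length(observed) == 0, "empty angle sample")
  if (model == "swivel-uniform") {
    bins <- tibble::tibble(bin_lo = seq(0, 300, 60), bin_hi = seq(60, 360, 60),
                           fraction = rep(1 / 6, 6))
    x <- observed %% 360
  } else if (model == "tilt-random-6bin") {
    bins <- random_tilt_fractions("6bin-30")
    x <- observed
  } else {
    bins <- random_tilt_fractions("3bin-30-folded")
    x <- ifelse(observed > 90, 180 - observed, observed)
  }
  counts <- vapply(seq_len(nrow(bins)), function(i) {
    hi_open <- i < nrow(bins)
    sum(x >= bins$bin_lo[i] & (if (hi_open) x < bins$bin_hi[i]
                               else x <= bins$bin_hi[i]))
  }, numeric(1))
  n <- length(x)
  expected <- n * bins$fraction
  statistic <- sum((counts - expected)^2 / expected)
  df <- nrow(bins) - 1
  critical <- stats::qchisq(1 - alpha, df)
  out <- list(
    statistic = statistic,
    df = df,
    critical = critical,
    alpha = alpha,
    significant = statistic > critical,
    valid = all(expected >= 5),
    n = n,
    model = model,
    table = dplyr::mutate(bins, observed = counts, expected = expected)
  )
  class(out) <- "chi2_angles"
  out
}

#' @export
print.chi2_angles <- function(x, ...) {
  cat(sprintf(
    "chi-squared vs %s null: X2 = %.2f (df = %d, critical %.3f at alpha = %g)%s\n",
    x$model, x$statistic, x$df, x$critical, x$alpha,
    if (x$significant) " *" else ""))
  if (!x$valid) cat("  note: some expected bin counts < 5\n")
  invisible(x)
}

#' @method tidy chi2_angles
#' @export
tidy.chi2_angles <- function(x, ...) x$table

#' @method glance chi2_angles
#' @export
glance.chi2_angles <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, critical = x$critical,
                 significant = x$significant, valid = x$valid, n = x$n)
}

#' Composition class of a three-residue clique
#'
#' C1: all three residues distinct (ordered R1 > R2 > R3 by side-chain
#' volume); C2: exactly two identical (the unique residue is R1); C3: all
#' identical. Residues must belong to the recognised alphabet (by default the
#' seven hydrophobics: Ala, Val, Leu, Ile, Phe, Tyr, Trp).
#'
#' @param residues Character vector of three 3-letter residue names.
#' @param alphabet Permitted residue names.
#' @param volumes Side-chain volume table for C1 ordering.
#' @return Object of class `composition_class`: list with `class` and
#'   `residues` (ordered R1, R2, R3).
#' @export
composition_class <- function(residues,
                              alphabet = hydrophobic_residues(),
                              volumes = side_chain_volumes()) {
  residues <- toupper(residues)
  abort_if(length(residues) != 3, "need exactly three residues")
  unknown <- setdiff(residues, alphabet)
  abort_if(length(unknown) > 0,
           paste("unknown residue name(s):", paste(unknown, collapse = ", ")))
  tab <- table(residues)
  if (length(tab) == 3) {
    cls <- "C1"
    ordered <- residues[order(-volumes[residues], residues)]
  } else if (length(tab) == 2) {
    cls <- "C2"
    unique_res <- names(tab)[tab == 1]
    ordered <- c(unique_res, residues[residues != unique_res])
  } else {
    cls <- "C3"
    ordered <- residues
  }
  structure(list(class = cls, residues = ordered),
            class = "composition_class")
}

#' Number of triplet compositions per class over a k-residue alphabet
#'
#' C1 offers `choose(k, 3)` combinations, C2 `k * (k - 1)` and C3 `k`; for
#' the seven hydrophobic residues these are 35, 42 and 7.
#'
#' @param k Alphabet size.
#' @return Tibble with columns `class` and `combinations`.
#' @export
composition_combinations <- function(k) {
  tibble::tibble(
    class = c("C1", "C2", "C3"),
    combinations = c(choose(k, 3), k * (k - 1), k)
  )
}

#' The seven-residue hydrophobic alphabet
#' @return Character vector of 3-letter codes.
#' @export
hydrophobic_residues <- function() {
  c("ALA", "VAL", "LEU", "ILE", "PHE", "TYR", "TRP")
}

#' Side-chain volume table used for C1 ordering
#'
#' Mean residue volumes (cubic Angstrom) from standard crystallographic
#' compilations; only the relative order matters here. The Leu/Ile near-tie
#' is broken deterministically (alphabetically) wherever volumes coincide.
#'
#' @return Named numeric vector (3-letter codes).
#' @export
side_chain_volumes <- function() {
  c(GLY = 60.1, ALA = 88.6, SER = 89.0, CYS = 108.5, ASP = 111.1,
    PRO = 112.7, ASN = 114.1, THR = 116.1, GLU = 138.4, VAL = 140.0,
    GLN = 143.8, HIS = 153.2, MET = 162.9, ILE = 166.7, LEU = 166.7,
    LYS = 168.6, ARG = 173.4, PHE = 189.9, TYR = 193.6, TRP = 227.8)
}

#' Local / non-local sequence separation of clique contacts
#'
#' Two clique-forming residues are in local contact when separated by at most
#' `threshold` contiguous residues along the chain, non-local otherwise.
#'
#' @param positions Integer vector of three chain positions.
#' @param threshold Maximum local separation (default 10).
#' @param chain Optional chain ids (must all be equal).
#' @return Tibble with one row per residue pair: `res_i`, `res_j`,
#'   `separation`, `locality`.
#' @export
sequence_separation <- function(positions, threshold = 10, chain = NULL) {
  abort_if(length(positions) != 3, "expected three chain positions")
  if (!is.null(chain)) {
    abort_if(length(unique(chain)) != 1,
             "clique residues lie on different chains")
  }
  pairs <- utils::combn(3, 2)
  sep <- abs(positions[pairs[1, ]] - positions[pairs[2, ]])
  tibble::tibble(
    res_i = positions[pairs[1, ]],
    res_j = positions[pairs[2, ]],
    separation = sep,
    locality = ifelse(sep <= threshold, "local", "non-local")
  )
}
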