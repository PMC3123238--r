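#' Surface complementarity score between two dot-surface points
#'
#' `S(a, b) = -(n_a . n_b) * exp(-w * d_ab^2)` with `n_a`, `n_b` the unit
#' normals, `d_ab` the point separation and `w` a scaling factor (0.5).
#' Facing complementary surfaces carry opposing outward normals, so perfectly
#' apposed anti-parallel points score +1, coincident parallel normals score
#' -1, and the score decays to 0 with distance. Symmetric in its arguments.
#'
#' @param a,b Surface points: lists with `position` (3-vector) and `normal`
#'   (unit 3-vector), or single rows of a [dot_surface()] tibble.
#' @param w Gaussian distance-decay scale (default 0.5, inverse square
#'   Angstrom).
#' @return Score in `[-1, 1]`.
#' @export
point_score <- function(a, b, w = 0.5) {
  a <- as_surface_point(a)
  b <- as_surface_point(b)
  abort_if(abs(vnorm(a$normal) - 1) > 1e-6 || abs(vnorm(b$normal) - 1) > 1e-6,
           "surface point normals must be unit vectors")
  d2 <- sum((a$position - b$position)^2)
  -sum(a$normal * b$normal) * exp(-w * d2)
}

as_surface_point <- function(p) {
  if (is.list(p) && !is.data.frame(p) && all(c("position", "normal") %in% names(p))) {
    return(p)
  }
  if (is.data.frame(p) && nrow(p) == 1) {
    return(list(position = c(p$x, p$y, p$z), normal = c(p$nx, p$ny, p$nz)))
  }
  stop("expected a surface point (position + normal) or one surface row",
       call. = FALSE)
}

#' Directed patch scores Sm and Ov for every residue pair
#'
#' For each side-chain surface point `a` of a target residue A, its nearest
#' neighbour `b` among the surface points of all other residues (main chain
#' included as environment) is located within `nn_cutoff`; matched points are
#' partitioned into patches by the neighbour residue. The patch
#' complementarity `Sm^(A->B)` is the median of the point scores of the patch
#' facing B, and the overlap `Ov^(A->B) = N_AB / N_A` with `N_A` the total
#' number of side-chain surface points of A. Points with no neighbour within
#' the cutoff contribute to no patch, so overlaps over all neighbours of a
#' target sum to at most 1. Nearest-neighbour ties break deterministically to
#' the lowest (atom serial, point index).
#'
#' @param surface A [dot_surface()] tibble.
#' @param nn_cutoff Nearest-neighbour search radius in Angstrom (default 3.5).
#' @param w Point-score scale passed to the score kernel.
#' @param targets Optional residue keys to score (default: all residues with
#'   side-chain points).
#' @return Tibble: `target`, `neighbor`, `sm`, `ov`, `n_ab`, `n_a`, plus
#'   `resid_target`, `resid_neighbor`.
#' @export
patch_scores <- function(surface, nn_cutoff = 3.5, w = 0.5, targets = NULL) {
  abort_if(nrow(surface) == 0, "empty surface")
  surface <- surface[order(surface$atom_serial, surface$point_index), ,
                     drop = FALSE]
  resid_of <- surface |>
    dplyr::distinct(.data$residue, .data$resid)
  keys <- unique(surface$residue[surface$is_side_chain])
  if (!is.null(targets)) keys <- intersect(as.character(targets), keys)
  abort_if(length(keys) == 0, "no target residue has side-chain surface points")
  coords <- as.matrix(surface[, c("x", "y", "z")])
  normals <- as.matrix(surface[, c("nx", "ny", "nz")])
  out <- vector("list", length(keys))
  for (ti in seq_along(keys)) {
    key <- keys[ti]
    t_idx <- which(surface$residue == key & surface$is_side_chain)
    e_idx <- which(surface$residue != key)
    n_a <- length(t_idx)
    if (length(e_idx) == 0) next
    nn <- nearest_within(coords[t_idx, , drop = FALSE],
                         coords[e_idx, , drop = FALSE], nn_cutoff)
    hit <- which(!is.na(nn$index))
    if (!length(hit)) next
    b_idx <- e_idx[nn$index[hit]]
    s <- -rowSums(normals[t_idx[hit], , drop = FALSE] *
                    normals[b_idx, , drop = FALSE]) *
      exp(-w * nn$dist[hit]^2)
    patch <- tibble::tibble(neighbor = surface$residue[b_idx], s = s) |>
      dplyr::group_by(.data$neighbor) |>
      dplyr::summarise(sm = stats::median(.data$s), n_ab = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(target = key, n_a = n_a, ov = .data$n_ab / .data$n_a)
    out[[ti]] <- patch
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(target = character(), neighbor = character(),
                          sm = numeric(), ov = numeric(), n_ab = integer(),
                          n_a = integer(), resid_target = character(),
                          resid_neighbor = character()))
  }
  res |>
    dplyr::left_join(dplyr::rename(resid_of, target = "residue",
                                   resid_target = "resid"), by = "target") |>
    dplyr::left_join(dplyr::rename(resid_of, neighbor = "residue",
                                   resid_neighbor = "resid"),
                     by = "neighbor") |>
    dplyr::select("target", "neighbor", "sm", "ov", "n_ab", "n_a",
                  "resid_target", "resid_neighbor")
}

# first (lowest-index) nearest neighbour of each query among refs, within
# cutoff; chunked to bound memory
nearest_within <- function(query, refs, cutoff) {
  nq <- nrow(query)
  idx <- rep(NA_integer_, nq)
  dist <- rep(NA_real_, nq)
  chunk <- max(1L, floor(4e6 / max(1, nrow(refs))))
  for (start in seq(1L, nq, by = chunk)) {
    rows <- start:min(nq, start + chunk - 1L)
    d2 <- outer(rowSums(query[rows, , drop = FALSE]^2),
                rowSums(refs^2), `+`) -
      2 * query[rows, , drop = FALSE] %*% t(refs)
    j <- max.col(-d2, ties.method = "first")
    best <- d2[cbind(seq_along(rows), j)]
    ok <- best <= cutoff^2 + 1e-12
    idx[rows[ok]] <- j[ok]
    dist[rows[ok]] <- sqrt(pmax(0, best[ok]))
  }
  list(index = idx, dist = dist)
}

#' Commutative surface contacts between residue pairs
#'
#' Two residues are in surface contact when their directed interactions are
#' mutually reciprocal: `Sm` and `Ov` pass the cutoffs in both directions
#' (A->B and B->A). For a contact, `Sm` and `Ov` are the means of the two
#' directed values and the edge weight is `sqrt(Sm^2 + Ov^2)` — the magnitude
#' of two mutually orthogonal components.
#'
#' @param patches Directed patch tibble from [patch_scores()].
#' @param sm_cut Surface-complementarity cutoff (default 0.4).
#' @param ov_cut Overlap cutoff (default 0.08).
#' @return Contact tibble: `res_a`, `res_b`, `sm`, `ov`, `weight`,
#'   `resid_a`, `resid_b` (one row per unordered pair).
#' @export
residue_contacts <- function(patches, sm_cut = 0.4, ov_cut = 0.08) {
  empty <- tibble::tibble(res_a = character(), res_b = character(),
                          sm = numeric(), ov = numeric(), weight = numeric(),
                          resid_a = character(), resid_b = character())
  if (is.null(patches) || nrow(patches) == 0) return(empty)
  pass <- patches[patches$sm >= sm_cut & patches$ov >= ov_cut, , drop = FALSE]
  if (nrow(pass) == 0) return(empty)
  pass$key <- paste(pmin(pass$target, pass$neighbor),
                    pmax(pass$target, pass$neighbor))
  both <- split(pass, pass$key)
  rows <- purrr::map(both, function(d) {
    if (nrow(d) != 2) return(NULL) # only one direction passed
    tibble::tibble(
      res_a = min(d$target), res_b = max(d$target),
      sm = mean(d$sm), ov = mean(d$ov),
      resid_a = d$resid_target[which.min(d$target)],
      resid_b = d$resid_target[which.max(d$target)]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out$weight <- edge_weight(out$sm, out$ov)
  dplyr::select(out, "res_a", "res_b", "sm", "ov", "weight",
                "resid_a", "resid_b")
}

#' Surface-contact edge weight
#'
#' `sqrt(Sm^2 + Ov^2)`, treating complementarity and overlap as two mutually
#' orthogonal components of the association.
#'
#' @param sm,ov Contact complementarity and overlap.
#' @return Non-negative weight.
#' @export
edge_weight <- function(sm, ov) sqrt(sm^2 + ov^2)
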