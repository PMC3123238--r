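#' Build all-residue point-atom contact networks (APCN)
#'
#' Connects two residues whenever any pair of atoms on their two side chains
#' lies within (strictly less than) `atom_cutoff` of each other; the edge
#' weight is the number of such atomic contacts. Nodes are residues with
#' burial ratio at most `burial_max` (glycine, having no side chain beyond
#' CA, is never a node), and only connected components with at least
#' `min_size` nodes are returned — no standalone nodes are considered.
#'
#' @param atoms Atom tibble from [read_structure()] or [gen_toy_structure()].
#' @param burial Optional burial tibble from [burial_ratios()]; when supplied,
#'   residues with `burial > burial_max` are excluded from the node set.
#' @param atom_cutoff Inter-atomic contact cutoff in Angstrom (default 3.8,
#'   strict `<`).
#' @param burial_max Maximum burial ratio for a node (default 0.3).
#' @param min_size Smallest component retained (default 3).
#' @return A list of igraph networks; vertex attribute `resid` holds the
#'   3-letter residue name, edge attribute `weight` the atomic contact count.
#' @export
build_apcn <- function(atoms, burial = NULL, atom_cutoff = 3.8,
                       burial_max = 0.3, min_size = 3) {
  sc <- atoms[atoms$is_side_chain & atoms$resid != "GLY", , drop = FALSE]
  if (!is.null(burial)) {
    keep <- burial$residue[burial$burial <= burial_max]
    sc <- sc[residue_key(sc$resno, sc$insert) %in% keep, , drop = FALSE]
  }
  if (nrow(sc) == 0) return(list())
  key <- residue_key(sc$resno, sc$insert)
  coords <- as.matrix(sc[, c("x", "y", "z")])
  pr <- pairs_within(coords, atom_cutoff, strict = TRUE)
  if (nrow(pr) == 0) return(list())
  ra <- key[pr[, 1]]
  rb <- key[pr[, 2]]
  inter <- ra != rb
  if (!any(inter)) return(list())
  ed <- tibble::tibble(
    res_a = pmin(ra[inter], rb[inter]),
    res_b = pmax(ra[inter], rb[inter])
  ) |>
    dplyr::count(.data$res_a, .data$res_b, name = "weight")
  resid_of <- stats::setNames(sc$resid, key)
  networks_from_edges(ed, resid_of, min_size = min_size)
}

#' Build all-residue surface contact networks (ASCN)
#'
#' Turns a table of commutative surface contacts (see [residue_contacts()])
#' into undirected weighted networks: components of at least `min_size`
#' residues, edge weight `sqrt(Sm^2 + Ov^2)` carried over from the contact
#' table.
#'
#' @param contacts Contact tibble with columns `res_a`, `res_b`, `weight`
#'   (and optionally `sm`, `ov`, `resid_a`, `resid_b`).
#' @param min_size Smallest component retained (default 3).
#' @return A list of igraph networks with edge attributes `weight` and, when
#'   present in `contacts`, `sm` and `ov`.
#' @export
build_ascn <- function(contacts, min_size = 3) {
  if (is.null(contacts) || nrow(contacts) == 0) return(list())
  resid_of <- NULL
  if (all(c("resid_a", "resid_b") %in% names(contacts))) {
    resid_of <- stats::setNames(
      c(contacts$resid_a, contacts$resid_b),
      c(contacts$res_a, contacts$res_b))
  }
  networks_from_edges(contacts, resid_of, min_size = min_size)
}

networks_from_edges <- function(edges, resid_of = NULL, min_size = 3) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(resid_of)) {
    igraph::V(g)$resid <- unname(resid_of[igraph::V(g)$name])
  }
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_size)
  out <- lapply(keep, function(k) {
    igraph::induced_subgraph(g, which(comp$membership == k))
  })
  # deterministic order: by decreasing size, then first residue key
  if (length(out) > 1) {
    sizes <- vapply(out, igraph::vcount, numeric(1))
    first <- vapply(out, function(x) sort(igraph::V(x)$name)[1], "")
    out <- out[order(-sizes, first)]
  }
  out
}

#' Per-node network statistics
#'
#' Degree, strength (sum of incident edge weights), unweighted clustering
#' coefficient `C_i = |{e_jh}| / choose(k_i, 2)` and the strength-normalised
#' weighted clustering coefficient of Barrat and co-workers, which reduces to
#' `C_i` when all weights are equal. Both coefficients are 0 for nodes of
#' degree below 2.
#'
#' @param net An igraph network with edge attribute `weight`.
#' @return A tibble with columns `node`, `degree`, `strength`, `c_unweighted`,
#'   `c_weighted`.
#' @export
node_stats <- function(net) {
  w <- igraph::E(net)$weight %||% rep(1, igraph::ecount(net))
  cu <- igraph::transitivity(net, type = "local", isolates = "zero")
  cw <- igraph::transitivity(net, type = "barrat", weights = w,
                             isolates = "zero")
  # igraph's barrat variant returns NaN for degree-1 nodes
  cw[!is.finite(cw)] <- 0
  tibble::tibble(
    node = igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net))),
    degree = as.numeric(igraph::degree(net)),
    strength = as.numeric(igraph::strength(net, weights = w)),
    c_unweighted = cu,
    c_weighted = cw
  )
}

#' Whole-graph statistics
#'
#' Link density `L_d = |E| / choose(n, 2)`, maximal clique size (see
#' [max_clique_size()]) and mean unweighted/weighted clustering.
#'
#' @param net An igraph network.
#' @return A one-row tibble: `size`, `edges`, `link_density`, `n_c`,
#'   `mean_c`, `mean_cw`.
#' @export
graph_stats <- function(net) {
  ns <- node_stats(net)
  n <- igraph::vcount(net)
  tibble::tibble(
    size = n,
    edges = igraph::ecount(net),
    link_density = igraph::ecount(net) / choose(n, 2),
    n_c = max_clique_size(net),
    mean_c = mean(ns$c_unweighted),
    mean_cw = mean(ns$c_weighted)
  )
}

#' Maximal clique size by progressive growth from triplets
#'
#' Searches every closed triplet (3-clique) and grows it by repeatedly adding
#' nodes adjacent to all current clique members, exploring all extension
#' orders, until convergence; the largest clique order reached is returned.
#' Graphs without any triangle have no clique order (returns `NA`).
#'
#' @param net igraph network or adjacency matrix.
#' @return Integer `n_c >= 3`, or `NA` when no triangle exists.
#' @export
max_clique_size <- function(net) {
  m <- as_adj(net)
  n <- nrow(m)
  if (n < 3) return(NA_integer_)
  best <- NA_integer_
  # cliques are explored with vertices in increasing index order; every
  # clique contains its lexicographically smallest triangle, so starting at
  # ordered triplets and extending upward covers all of them
  extend <- function(size, cands) {
    if (is.na(best) || size > best) best <<- size
    for (idx in seq_along(cands)) {
      v <- cands[idx]
      nxt <- cands[cands > v & m[v, cands] > 0]
      extend(size + 1L, nxt)
    }
  }
  for (i in seq_len(n - 2)) {
    ni <- which(m[i, ] > 0)
    ni <- ni[ni > i]
    for (j in ni) {
      common <- which(m[i, ] > 0 & m[j, ] > 0)
      for (k in common[common > j]) {
        cands <- common[common > k & m[k, common] > 0]
        extend(3L, cands)
      }
    }
  }
  as.integer(best)
}

#' Link-density-matched random graph
#'
#' Connects every unordered node pair independently with probability `l_d`,
#' assigning each realised edge a weight drawn uniformly from `weight_pool`
#' (typically the empirical weight multiset of the source network). With the
#' same `seed` the identical graph is reproduced.
#'
#' @param n Number of nodes.
#' @param l_d Link density in `[0, 1]`.
#' @param weight_pool Numeric pool to sample edge weights from (default 1).
#' @param seed Optional integer seed (local to this call).
#' @return An igraph network with edge attribute `weight`.
#' @export
random_graph <- function(n, l_d, weight_pool = 1, seed = NULL) {
  abort_if(l_d < 0 || l_d > 1, "link density must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on_edge <- stats::runif(nrow(pairs)) < l_d
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (any(on_edge)) {
    e <- pairs[on_edge, , drop = FALSE]
    g <- igraph::add_edges(g, as.vector(t(e)))
    igraph::E(g)$weight <- sample(weight_pool, sum(on_edge), replace = TRUE)
  }
  g
}

#' Fit a power law to a network-size distribution
#'
#' The frequency of contact networks of size x decays approximately as
#' `f(x) = k * x^-n`. The exponent is estimated by ordinary least squares on
#' the log-log frequency table, dropping zero-count sizes.
#'
#' @param sizes Integer vector of network sizes (or list of igraph networks).
#' @return An object of class `packnet_powerlaw` with elements `exponent`,
#'   `k`, `fit` (the underlying `lm`) and `data`; has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
size_distribution <- function(sizes) {
  if (is.list(sizes)) sizes <- vapply(sizes, igraph::vcount, numeric(1))
  tab <- table(sizes)
  abort_if(length(tab) < 2, "need at least two distinct network sizes to fit")
  df <- tibble::tibble(
    size = as.numeric(names(tab)),
    frequency = as.numeric(tab)
  )
  fit <- stats::lm(log(frequency) ~ log(size), data = df)
  out <- list(
    exponent = -unname(stats::coef(fit)[2]),
    k = exp(unname(stats::coef(fit)[1])),
    fit = fit,
    data = df
  )
  class(out) <- "packnet_powerlaw"
  out
}

#' @export
print.packnet_powerlaw <- function(x, ...) {
  cat("Power-law fit f(x) = k * x^-n\n")
  cat(sprintf("  n = %.3f, k = %.3f (%d sizes, %d networks)\n",
              x$exponent, x$k, nrow(x$data), sum(x$data$frequency)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy packnet_powerlaw
#' @export
tidy.packnet_powerlaw <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("k", "exponent"),
    estimate = c(x$k, x$exponent),
    std.error = c(NA_real_, s[2, 2])
  )
}

#' @method glance packnet_powerlaw
#' @export
glance.packnet_powerlaw <- function(x, ...) {
  tibble::tibble(
    exponent = x$exponent,
    k = x$k,
    r.squared = summary(x$fit)$r.squared,
    n_sizes = nrow(x$data),
    n_networks = sum(x$data$frequency)
  )
}

#' Propensity of a motif family (or network size) for a protein class
#'
#' `P = (N_fC / N_f) / (N_C / N)`: the fraction of family-f motifs found in
#' class-C chains, normalised by the fraction of chains in that class. The
#' identical form applies to the size propensity `P(S/C)` with network-size
#' counts in place of family counts.
#'
#' @param n_fc Motifs of family f in class C.
#' @param n_f Motifs of family f in all classes.
#' @param n_c Chains in class C.
#' @param n Total chains.
#' @return Propensity value(s); 1 means no enrichment.
#' @export
propensity <- function(n_fc, n_f, n_c, n) {
  abort_if(any(n_f <= 0) || any(n_c <= 0) || any(n <= 0),
           "propensity denominators must be positive")
  (n_fc / n_f) / (n_c / n)
}

#' Contact network edge table
#'
#' @param net An igraph network.
#' @return Edge tibble (`res_a`, `res_b`, `weight`, plus `sm`/`ov` when set).
#' @export
network_edges <- function(net) {
  e <- igraph::as_data_frame(net, what = "edges")
  names(e)[1:2] <- c("res_a", "res_b")
  tibble::as_tibble(e)
}

# all index pairs (i < j) with euclidean distance < cutoff (strict) or
# <= cutoff; simple uniform-grid cell list, O(pairs) not O(n^2)
pairs_within <- function(coords, cutoff, strict = TRUE) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cell <- floor(coords / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  cellmat <- unique(cell)
  keyu <- paste(cellmat[, 1], cellmat[, 2], cellmat[, 3])
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0)
  out_j <- integer(0)
  for (b in seq_len(nrow(cellmat))) {
    here <- buckets[[keyu[b]]]
    nb_keys <- paste(cellmat[b, 1] + offs[, 1], cellmat[b, 2] + offs[, 2],
                     cellmat[b, 3] + offs[, 3])
    cand <- unlist(buckets[intersect(nb_keys, keyu)], use.names = FALSE)
    cand <- cand[cand > min(here) | cand %in% here]
    if (length(cand) < 2) next
    for (i in here) {
      js <- cand[cand > i]
      if (!length(js)) next
      d2 <- (coords[js, 1] - coords[i, 1])^2 +
        (coords[js, 2] - coords[i, 2])^2 +
        (coords[js, 3] - coords[i, 3])^2
      hit <- if (strict) d2 < cutoff^2 else d2 <= cutoff^2
      if (any(hit)) {
        out_i <- c(out_i, rep.int(i, sum(hit)))
        out_j <- c(out_j, js[hit])
      }
    }
  }
  cbind(out_i, out_j)
}
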