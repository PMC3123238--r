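#' Canonical motif identifier of a connected graph
#'
#' Encodes a small connected graph as a delimiter-separated number string
#' that is invariant under node relabelling: each node contributes a numeric
#' string of length `d + 1` holding its own degree followed by the degrees of
#' its direct neighbours sorted in descending order; the node strings are then
#' sorted in descending order (as integer sequences, element by element) and
#' concatenated with `"-"`.
#'
#' Two graphs with different identifiers are never isomorphic. The converse
#' (identifier equality implying isomorphism) holds for every connected graph
#' that has been checked exhaustively (all orders up to 7); see
#' [exact_isomorphic()] for the oracle used to guard it. Setting
#' `canonical = TRUE` appends a canonical edge-list encoding, making the
#' string a complete invariant at any order.
#'
#' @param g An igraph object or symmetric 0/1 adjacency matrix; must be
#'   connected with at least 2 nodes.
#' @param canonical Append a canonical adjacency encoding (default `FALSE`).
#' @return A single string, e.g. `"211-12-12"` for the 3-node path.
#' @examples
#' motif_identifier(igraph::make_ring(3))   # "222-222-222"
#' motif_identifier(adj_path(3))            # "211-12-12"
#' @export
motif_identifier <- function(g, canonical = FALSE) {
  m <- as_adj(g)
  n <- nrow(m)
  abort_if(n < 2, "motif identifier requires at least 2 nodes")
  abort_if(!adj_connected(m), "motif identifier is defined for connected graphs only")
  deg <- rowSums(m)
  strs <- lapply(seq_len(n), function(i) {
    c(deg[i], sort(deg[m[i, ] > 0], decreasing = TRUE))
  })
  ord <- order_int_sequences(strs)
  id <- paste(vapply(strs[ord], paste0, "", collapse = ""), collapse = "-")
  if (canonical) id <- paste0(id, "#", canonical_edge_code(m))
  id
}

# descending order of a list of integer vectors (elementwise lexicographic);
# vectors of unequal length always differ in their first element (the degree),
# so padding is never reached in a decisive comparison
order_int_sequences <- function(strs) {
  len <- max(lengths(strs))
  padded <- t(vapply(strs, function(s) c(s, rep(-1L, len - length(s))), numeric(len)))
  do.call(order, c(lapply(seq_len(len), function(j) -padded[, j]), list()))
}

# canonical (lexicographically minimal) edge-list code via igraph's BLISS
# canonical permutation; used only as the collision fallback
canonical_edge_code <- function(m) {
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  p <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, p)
  e <- igraph::as_edgelist(gc, names = FALSE)
  e <- t(apply(e, 1, sort))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste(paste0(e[, 1], ".", e[, 2]), collapse = ",")
}

#' Exact graph isomorphism by backtracking search
#'
#' Adjacency-preserving bijection search with degree-sequence pruning and
#' degree-class-restricted candidate sets. Serves as the independent oracle
#' for the validity of [motif_identifier()].
#'
#' @param g1,g2 igraph objects or adjacency matrices, at most 10 nodes each.
#' @return `TRUE` iff an adjacency-preserving bijection between the vertex
#'   sets exists.
#' @examples
#' exact_isomorphic(adj_path(4), adj_path(4)[c(2, 4, 1, 3), c(2, 4, 1, 3)])
#' @export
exact_isomorphic <- function(g1, g2) {
  a <- as_adj(g1)
  b <- as_adj(g2)
  n <- nrow(a)
  if (n != nrow(b)) return(FALSE)
  abort_if(n > 10, "exact isomorphism search is limited to 10 nodes")
  if (n == 0) return(TRUE)
  da <- sort(rowSums(a))
  db <- sort(rowSums(b))
  if (!identical(da, db)) return(FALSE)
  dega <- rowSums(a)
  degb <- rowSums(b)
  # order source vertices by decreasing degree to fail fast
  ord <- order(-dega)
  map <- integer(n)
  used <- logical(n)
  extend <- function(k) {
    if (k > n) return(TRUE)
    v <- ord[k]
    for (w in which(!used & degb == dega[v])) {
      ok <- TRUE
      for (j in seq_len(k - 1)) {
        u <- ord[j]
        if (a[v, u] != b[w, map[u]]) { ok <- FALSE; break }
      }
      if (ok) {
        map[v] <<- w
        used[w] <<- TRUE
        if (extend(k + 1)) return(TRUE)
        used[w] <<- FALSE
      }
    }
    FALSE
  }
  extend(1L)
}

#' Exhaustively enumerate connected motifs of a given order
#'
#' Generates every connected unlabelled graph on `n` nodes (optionally under a
#' maximum-degree cap) exactly once, by exhaustive vertex extension: every
#' connected graph on `n` nodes arises from a connected graph on `n - 1` nodes
#' by attaching one new vertex to a non-empty vertex subset (every connected
#' graph has a non-cut vertex). Candidates are de-duplicated by motif
#' identifier, with each identifier bucket verified by [exact_isomorphic()];
#' a bucket holding non-isomorphic graphs (an identifier collision) triggers a
#' warning and the colliding motifs are separated by their canonical fallback
#' identifiers.
#'
#' @param n Number of nodes, 2 to 8.
#' @param max_degree Optional cap on node degree (`Inf` for none).
#' @return A tibble with columns `identifier`, `size`, `max_degree` (the
#'   realised maximum degree) and `adjacency` (list-column of matrices).
#' @examples
#' nrow(enumerate_motifs(4)) # 6
#' @export
enumerate_motifs <- function(n, max_degree = Inf) {
  abort_if(n < 2 || n > 8, "exhaustive enumeration supports n between 2 and 8")
  graphs <- list(adj_from_edges(2L, list(c(1L, 2L)))) # K2
  if (max_degree < 1) graphs <- list()
  s <- 2L
  while (s < n) {
    s <- s + 1L
    bucket <- new.env(parent = emptyenv())
    out <- list()
    for (g in graphs) {
      deg <- rowSums(g)
      attachable <- which(deg < max_degree)
      if (!length(attachable)) next
      subsets <- all_nonempty_subsets(attachable, max_size = min(length(attachable), max_degree))
      for (S in subsets) {
        cand <- rbind(cbind(g, 0L), 0L)
        cand[s, S] <- 1L
        cand[S, s] <- 1L
        id <- motif_identifier(cand)
        hit <- bucket[[id]]
        if (is.null(hit)) {
          bucket[[id]] <- list(cand)
          out[[length(out) + 1L]] <- cand
        } else {
          iso <- any(vapply(hit, exact_isomorphic, logical(1), g2 = cand))
          if (!iso) {
            warning("motif identifier collision at n = ", s, ": ", id,
                    "; separating by canonical fallback", call. = FALSE)
            bucket[[id]] <- c(hit, list(cand))
            out[[length(out) + 1L]] <- cand
          }
        }
      }
    }
    graphs <- out
  }
  ids <- vapply(graphs, motif_identifier, "")
  if (anyDuplicated(ids)) {
    dup <- ids %in% ids[duplicated(ids)]
    ids[dup] <- vapply(graphs[dup], motif_identifier, "", canonical = TRUE)
  }
  ord <- order(ids, decreasing = TRUE)
  tibble::tibble(
    identifier = ids[ord],
    size = n,
    max_degree = vapply(graphs[ord], function(m) max(rowSums(m)), numeric(1)),
    adjacency = graphs[ord]
  )
}

all_nonempty_subsets <- function(x, max_size = length(x)) {
  out <- list()
  for (k in seq_len(min(max_size, length(x)))) {
    cmb <- utils::combn(x, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Diagonal edges of an n-clique
#'
#' A clique on `n` nodes has `choose(n, 2) - n` diagonal (non-ring) edges;
#' consequently any closed-ring topology of order `n > 4` observed with a
#' maximal clique below `n` carries at most `choose(n, 2) - n - 1` diagonals.
#'
#' @param n Clique order, at least 3.
#' @return Integer count of diagonal edges.
#' @export
clique_diagonal_edges <- function(n) {
  abort_if(any(n < 3), "clique diagonal count is defined for n >= 3")
  choose(n, 2) - n
}

#' Are two motifs related by a path?
#'
#' `g_n1` (on `n + 1` nodes) descends from `g_n` (on `n` nodes) by a path when
#' deleting some degree-1 node of `g_n1` yields a graph isomorphic to `g_n`:
#' the added node has degree one and raises the degree of exactly one
#' pre-existing node.
#'
#' @param g_n,g_n1 Graphs with `|g_n1| = |g_n| + 1`.
#' @return `TRUE` iff such a degree-1 deletion exists.
#' @export
path_related <- function(g_n, g_n1) {
  a <- as_adj(g_n)
  b <- as_adj(g_n1)
  abort_if(nrow(b) != nrow(a) + 1, "path relation requires sizes n and n + 1")
  leaves <- which(rowSums(b) == 1)
  for (v in leaves) {
    if (exact_isomorphic(adj_delete_vertex(b, v), a)) return(TRUE)
  }
  FALSE
}

#' Load the packing-motif family catalog
#'
#' The catalog seeds each family with its core topology (f1 open chains, f2
#' triplet cliques, f3a/f3b four-rings with 0/1 diagonal, f4a/f4b/f4c five-
#' and six-rings, f5 edge-fused triplet strips, f6a/f6b node-/edge-connected
#' triplets, f7 node-linked four-rings, f8a embedded 4-cliques with
#' branching, f8b other non-planar graphs, f8c theta-like double-path
#' closures) plus the fused-triplet exception identifiers retained in f4a and
#' f4b. It is an editable JSON data file.
#'
#' @param path Optional path to an alternative catalog JSON file.
#' @return A tibble with columns `family`, `identifier`, `role`
#'   (`"core"`/`"exception"`), `size` and `adjacency` (list-column; `NULL`
#'   for identifier-only exception entries).
#' @export
motif_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "motif_families.json", package = "packnet")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(raw, function(entry) {
    adjacency <- NULL
    if (!is.null(entry$edges)) {
      adjacency <- adj_from_edges(entry$n, purrr::map(entry$edges, unlist))
    }
    tibble::tibble(
      family = entry$family,
      identifier = entry$identifier,
      role = entry$role,
      size = entry$n,
      adjacency = list(adjacency)
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify a motif into a packing family
#'
#' A motif belongs to the family of the core topology it can be reduced to by
#' successively deleting degree-1 nodes (the inverse of the path relation that
#' grows a family by linear branching); a missing intermediate along the chain
#' does not interrupt membership. Exception identifiers listed in the catalog
#' are honoured before the reduction. When no catalog family is reachable the
#' motif opens a new family, reported as `"new"`.
#'
#' @param motif igraph or adjacency matrix, connected.
#' @param catalog A catalog tibble from [motif_catalog()].
#' @return A single family id string (e.g. `"f2"`), or `"new"`.
#' @examples
#' classify_family(adj_path(4)) # "f1"
#' @export
classify_family <- function(motif, catalog = motif_catalog()) {
  m <- as_adj(motif)
  abort_if(!adj_connected(m), "family classification requires a connected motif")
  # family priority = catalog order (f1 first); used only to break ties when
  # several cores are reachable by degree-1 reduction
  fam_rank <- stats::setNames(seq_along(unique(catalog$family)), unique(catalog$family))
  # an identifier match against a catalog entry carrying an adjacency matrix
  # is verified by exact isomorphism (base identifiers are not collision-free
  # from order 6 upward); identifier-only exception entries are trusted
  catalog_family <- function(mm, id) {
    hits <- which(catalog$identifier == id)
    for (h in hits) {
      adj <- catalog$adjacency[[h]]
      if (is.null(adj) || exact_isomorphic(mm, adj)) return(catalog$family[h])
    }
    NULL
  }
  seen <- new.env(parent = emptyenv())
  best <- NULL
  consider <- function(fam) {
    if (is.null(best) || fam_rank[[fam]] < fam_rank[[best]]) best <<- fam
  }
  reduce <- function(mm) {
    id <- motif_identifier(mm)
    key <- motif_identifier(mm, canonical = TRUE) # collision-safe memo key
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    fam <- catalog_family(mm, id)
    if (!is.null(fam)) {
      consider(fam)
      return(invisible(NULL))
    }
    if (nrow(mm) <= 3) return(invisible(NULL))
    for (v in which(rowSums(mm) == 1)) {
      reduce(adj_delete_vertex(mm, v))
    }
    invisible(NULL)
  }
  reduce(m)
  best %||% "new"
}

#' Find a motif embedded as an induced subgraph
#'
#' Enumerates every node subset of `graph` whose induced subgraph (all edges
#' among the subset retained) is isomorphic to `motif`.
#'
#' @param graph Host graph (igraph or adjacency matrix).
#' @param motif Pattern graph with at most as many nodes as `graph`.
#' @return A list of integer vectors (each an occurrence, node indices of
#'   `graph`), or vertex-name vectors when `graph` is a named igraph.
#' @export
find_induced <- function(graph, motif) {
  gm <- as_adj(graph)
  mm <- as_adj(motif)
  n <- nrow(gm)
  k <- nrow(mm)
  abort_if(k > n, "motif larger than the host graph")
  names_g <- if (igraph::is_igraph(graph) && !is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name
  } else NULL
  target_edges <- sum(mm) / 2
  target_deg <- sort(rowSums(mm))
  hits <- list()
  for (S in utils::combn(n, k, simplify = FALSE)) {
    sub <- gm[S, S, drop = FALSE]
    if (sum(sub) / 2 != target_edges) next
    if (!identical(sort(rowSums(sub)), target_deg)) next
    if (exact_isomorphic(sub, mm)) {
      hits[[length(hits) + 1L]] <- if (is.null(names_g)) S else names_g[S]
    }
  }
  hits
}

#' Resolve a larger graph into catalog motifs
#'
#' Mirrors the two graph-analysis routes for explaining a network in terms of
#' a motif basis set: (1) cutting bridge edges only (never an edge lying on a
#' closed ring) to split the graph into components that are catalog motifs or
#' their family variants, preferring the decomposition with the fewest parts;
#' (2) for parts not resolvable by cutting, reporting maximal catalog core
#' motifs found as induced subgraphs. The decomposition covers all nodes;
#' nodes in neither a mapped component nor an induced occurrence are listed
#' as unexplained.
#'
#' @param graph A connected igraph or adjacency matrix.
#' @param catalog Catalog tibble from [motif_catalog()].
#' @param max_bridge_subsets Search cap on the number of bridge subsets
#'   examined before falling back to cutting all bridges.
#' @return A list with `components` (tibble: nodes, identifier, family),
#'   `induced` (tibble: nodes, identifier, family), `unexplained` (node ids)
#'   and `cut_edges` (two-column matrix of cut bridges).
#' @export
resolve_graph <- function(graph, catalog = motif_catalog(),
                          max_bridge_subsets = 4096) {
  m <- as_adj(graph)
  abort_if(!adj_connected(m), "resolve_graph expects a connected graph")
  nm <- if (igraph::is_igraph(graph) && !is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name
  } else as.character(seq_len(nrow(m)))

  comp_row <- function(nodes, mm) {
    tibble::tibble(
      nodes = list(nm[nodes]),
      identifier = motif_identifier(mm),
      family = classify_family(mm, catalog)
    )
  }

  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  br <- igraph::bridges(g)
  bridge_ends <- if (length(br)) igraph::ends(g, br, names = FALSE) else
    matrix(integer(0), ncol = 2)
  # deterministic bridge order by sorted node ids
  if (nrow(bridge_ends)) {
    bridge_ends <- t(apply(bridge_ends, 1, sort))
    bridge_ends <- bridge_ends[order(bridge_ends[, 1], bridge_ends[, 2]), ,
                               drop = FALSE]
  }
  nb <- nrow(bridge_ends)

  eval_cut <- function(cut_idx) {
    mm <- m
    for (i in cut_idx) {
      mm[bridge_ends[i, 1], bridge_ends[i, 2]] <- 0L
      mm[bridge_ends[i, 2], bridge_ends[i, 1]] <- 0L
    }
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(mm, mode = "undirected"))
    parts <- split(seq_len(nrow(m)), comp$membership)
    fams <- vapply(parts, function(p) {
      if (length(p) < 3) return("new")
      classify_family(m[p, p, drop = FALSE], catalog)
    }, "")
    list(parts = parts, fams = fams, ok = all(fams != "new"))
  }

  chosen <- NULL
  if (nb > 0) {
    tried <- 0
    for (k in seq_len(nb)) {
      for (cut_idx in utils::combn(nb, k, simplify = FALSE)) {
        tried <- tried + 1
        if (tried > max_bridge_subsets) break
        res <- eval_cut(cut_idx)
        if (res$ok) { chosen <- list(cut = cut_idx, res = res); break }
      }
      if (!is.null(chosen) || tried > max_bridge_subsets) break
    }
  }

  # no bridge cut resolves the graph into catalog parts: if the intact graph
  # itself is a catalog motif (or family member), report it whole
  if (is.null(chosen)) {
    whole_fam <- classify_family(m, catalog)
    if (whole_fam != "new") {
      return(list(
        components = comp_row(seq_len(nrow(m)), m),
        induced = tibble::tibble(nodes = list(), identifier = character(),
                                 family = character()),
        unexplained = character(0),
        cut_edges = matrix(character(0), ncol = 2)
      ))
    }
    if (nb > 0) { # fall back: cut all bridges, map what is mappable
      chosen <- list(cut = seq_len(nb), res = eval_cut(seq_len(nb)))
    }
  }

  components <- tibble::tibble(nodes = list(), identifier = character(),
                               family = character())
  explained <- logical(nrow(m))
  cut_edges <- matrix(character(0), ncol = 2)
  if (!is.null(chosen)) {
    for (p in chosen$res$parts) {
      pm <- m[p, p, drop = FALSE]
      if (length(p) >= 3) {
        fam <- classify_family(pm, catalog)
        if (fam != "new") {
          components <- dplyr::bind_rows(components, comp_row(p, pm))
          explained[p] <- TRUE
        }
      }
    }
    cut_edges <- cbind(nm[bridge_ends[chosen$cut, 1]],
                       nm[bridge_ends[chosen$cut, 2]])
  }

  # residual: induced-subgraph search with catalog cores, largest first
  induced <- tibble::tibble(nodes = list(), identifier = character(),
                            family = character())
  if (any(!explained)) {
    cores <- catalog[catalog$role == "core" & !purrr::map_lgl(catalog$adjacency, is.null), ]
    cores <- cores[order(-cores$size), ]
    for (i in seq_len(nrow(cores))) {
      if (!any(!explained)) break
      if (cores$size[i] > nrow(m)) next
      occ <- find_induced(m, cores$adjacency[[i]])
      for (nodes in occ) {
        if (any(!explained[nodes])) {
          induced <- dplyr::bind_rows(induced, tibble::tibble(
            nodes = list(nm[nodes]),
            identifier = cores$identifier[i],
            family = cores$family[i]
          ))
          explained[nodes] <- TRUE
        }
      }
    }
  }

  list(
    components = components,
    induced = induced,
    unexplained = nm[!explained],
    cut_edges = cut_edges
  )
}

#' Census of triplet cliques across a set of networks
#'
#' Counts isolated triplet cliques (networks that are exactly a complete
#' 3-node graph) and triangles embedded as induced subgraphs inside larger
#' networks, with a per-network breakdown.
#'
#' @param nets List of igraph networks.
#' @return A list with `isolated`, `embedded` and `per_network` (tibble with
#'   `id`, `size`, `isolated`, `n_embedded`).
#' @export
count_triplet_cliques <- function(nets) {
  abort_if(!is.list(nets), "expected a list of networks")
  rows <- purrr::imap(nets, function(g, i) {
    n <- igraph::vcount(g)
    ntri <- sum(igraph::count_triangles(g)) / 3
    iso <- n == 3 && igraph::ecount(g) == 3
    tibble::tibble(id = as.character(i), size = n, isolated = iso,
                   n_embedded = if (iso) 0 else ntri)
  })
  per <- dplyr::bind_rows(rows)
  list(
    isolated = sum(per$isolated),
    embedded = sum(per$n_embedded),
    per_network = per
  )
}

#' Convenience constructors for small abstract graphs
#'
#' `adj_path(n)`, `adj_cycle(n)`, `adj_complete(n)` and `adj_star(n)` return
#' adjacency matrices of the elementary topologies used throughout the motif
#' vocabulary (open chains, rings, cliques, stars).
#'
#' @param n Number of nodes.
#' @return A symmetric 0/1 adjacency matrix.
#' @export
adj_path <- function(n) {
  adj_from_edges(n, purrr::map(seq_len(n - 1), ~ c(.x, .x + 1)))
}

#' @rdname adj_path
#' @export
adj_cycle <- function(n) {
  edges <- c(purrr::map(seq_len(n - 1), ~ c(.x, .x + 1)), list(c(n, 1)))
  adj_from_edges(n, edges)
}

#' @rdname adj_path
#' @export
adj_complete <- function(n) {
  m <- matrix(1L, n, n)
  diag(m) <- 0L
  m
}

#' @rdname adj_path
#' @export
adj_star <- function(n) {
  adj_from_edges(n, purrr::map(seq_len(n - 1) + 1, ~ c(1, .x)))
}
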