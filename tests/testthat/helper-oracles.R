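# Independent oracles and shared fixtures.

# exhaustive edge-subset enumeration of connected unlabelled graphs on n
# nodes (modulo isomorphism via igraph's VF2) — the brute-force oracle for
# enumerate_motifs at small n
oracle_count_connected <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  reps <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) < n - 1) next
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(pairs[sel, , drop = FALSE])))
    if (!igraph::is_connected(g)) next
    new <- TRUE
    for (r in reps) {
      if (igraph::isomorphic(g, r)) { new <- FALSE; break }
    }
    if (new) reps[[length(reps) + 1L]] <- g
  }
  length(reps)
}

# brute-force maximum clique by scanning all vertex subsets (largest first)
oracle_max_clique <- function(adj) {
  n <- nrow(adj)
  for (k in rev(seq_len(n))) {
    if (k < 3) return(NA_integer_)
    for (S in utils::combn(n, k, simplify = FALSE)) {
      sub <- adj[S, S, drop = FALSE]
      if (all(sub[upper.tri(sub)] == 1)) return(k)
    }
  }
  NA_integer_
}

random_connected_adj <- function(n, p = 0.4) {
  repeat {
    m <- matrix(0L, n, n)
    up <- which(upper.tri(m))
    on <- up[stats::runif(length(up)) < p]
    m[on] <- 1L
    m <- m + t(m)
    if (packnet:::adj_connected(m)) return(m)
  }
}

random_relabel <- function(adj) {
  p <- sample(nrow(adj))
  adj[p, p, drop = FALSE]
}

# expensive shared fixtures, computed once per test run
.fixtures <- new.env(parent = emptyenv())

packed_toy <- function() {
  if (is.null(.fixtures$toy)) .fixtures$toy <- gen_toy_structure("packed-core", seed = 1)
  .fixtures$toy
}

packed_toy_surface <- function() {
  if (is.null(.fixtures$surf)) .fixtures$surf <- dot_surface(packed_toy())
  .fixtures$surf
}

packed_toy_patches <- function() {
  if (is.null(.fixtures$patches)) {
    .fixtures$patches <- patch_scores(packed_toy_surface())
  }
  .fixtures$patches
}

packed_toy_contacts <- function() {
  if (is.null(.fixtures$contacts)) {
    .fixtures$contacts <- residue_contacts(packed_toy_patches())
  }
  .fixtures$contacts
}

# minimal PDB text fixture writer (fixed-column ATOM records)
write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, altloc = " ", element = "C") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resid, chain, resno, x, y, z, occ, 0,
          element)
}
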