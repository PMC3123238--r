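test_that("identifiers reproduce the canonical printed strings", {
  expect_equal(motif_identifier(adj_path(3)), "211-12-12")
  expect_equal(motif_identifier(adj_complete(3)), "222-222-222")
  expect_equal(motif_identifier(adj_path(4)), "221-221-12-12")
  expect_equal(motif_identifier(adj_star(4)), "3111-13-13-13")
  tri_pendant <- packnet:::adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3),
                                                  c(1, 4)))
  expect_equal(motif_identifier(tri_pendant), "3221-232-232-13")
  expect_equal(motif_identifier(adj_cycle(4)), "222-222-222-222")
  ring_diag <- packnet:::adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4),
                                                c(4, 1), c(1, 3)))
  expect_equal(motif_identifier(ring_diag), "3322-3322-233-233")
  expect_error(motif_identifier(rbind(c(0, 0), c(0, 0))), "connected")
})

test_that("identifier is invariant under node relabelling", {
  set.seed(21)
  for (i in 1:300) {
    m <- random_connected_adj(sample(4:8, 1), stats::runif(1, 0.3, 0.7))
    id <- motif_identifier(m)
    for (j in 1:5) {
      expect_identical(motif_identifier(random_relabel(m)), id)
    }
  }
})

test_that("exact isomorphism distinguishes equal-degree-sequence trees", {
  p4 <- adj_path(4)
  expect_true(exact_isomorphic(p4, random_relabel(p4)))
  expect_false(exact_isomorphic(p4, adj_star(4)))
  # spider vs caterpillar: same degree sequence (3,2,2,1,1,1), not isomorphic
  spider <- packnet:::adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 4),
                                             c(4, 5), c(1, 6)))
  caterpillar <- packnet:::adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4),
                                                  c(4, 5), c(2, 6)))
  expect_equal(sort(rowSums(spider)), sort(rowSums(caterpillar)))
  expect_false(exact_isomorphic(spider, caterpillar))
  # agrees with igraph's VF2 on random pairs
  set.seed(5)
  for (i in 1:100) {
    a <- random_connected_adj(6, 0.5)
    b <- if (i %% 2 == 0) random_relabel(a) else random_connected_adj(6, 0.5)
    expect_equal(
      exact_isomorphic(a, b),
      igraph::isomorphic(
        igraph::graph_from_adjacency_matrix(a, mode = "undirected"),
        igraph::graph_from_adjacency_matrix(b, mode = "undirected")))
  }
})

test_that("motif enumeration is exhaustive and matches the subset oracle", {
  expect_equal(nrow(enumerate_motifs(3)), 2)
  expect_equal(nrow(enumerate_motifs(4)), 6)
  expect_equal(nrow(enumerate_motifs(5)), 21)
  expect_equal(oracle_count_connected(4), 6)
  expect_equal(oracle_count_connected(5), 21)
  # degree caps restrict the census: n=4 under max degree 2 leaves only the
  # path and the ring
  capped <- enumerate_motifs(4, max_degree = 2)
  expect_setequal(capped$identifier, c("221-221-12-12", "222-222-222-222"))
  expect_error(enumerate_motifs(12), "between")
})

test_that("clique diagonal-edge count follows choose(n,2) - n", {
  expect_equal(clique_diagonal_edges(3), 0)
  expect_equal(clique_diagonal_edges(4), 2)
  expect_equal(clique_diagonal_edges(6), 9)
  expect_error(clique_diagonal_edges(2), "n >= 3")
})

test_that("path relation requires a removable degree-1 node", {
  expect_true(path_related(adj_path(3), adj_path(4)))
  expect_false(path_related(adj_complete(3), adj_complete(4)))
  tri_pendant <- packnet:::adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3),
                                                  c(1, 4)))
  expect_true(path_related(adj_complete(3), tri_pendant))
  expect_error(path_related(adj_path(3), adj_path(5)), "sizes")
})

test_that("family classification follows lineages, exceptions and collisions", {
  catalog <- motif_catalog()
  expect_equal(classify_family(adj_path(4), catalog), "f1")
  tri_pendant <- packnet:::adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3),
                                                  c(1, 4)))
  expect_equal(classify_family(tri_pendant, catalog), "f2")
  expect_equal(classify_family(adj_cycle(4), catalog), "f3a")
  expect_equal(classify_family(adj_cycle(5), catalog), "f4a")
  # deep lineage: P7 reduces through missing intermediates to the f1 core
  expect_equal(classify_family(adj_path(7), catalog), "f1")
  # identifier collision across families: the two-triangles-plus-bridge core
  # (f6b) and the six-ring with a long diagonal (f4c) share a base
  # identifier; adjacency verification keeps them apart
  f6b <- packnet:::adj_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                                          c(4, 5), c(4, 6), c(5, 6)))
  c6_diag <- packnet:::adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4),
                                              c(4, 5), c(5, 6), c(6, 1),
                                              c(1, 4)))
  expect_equal(motif_identifier(f6b), motif_identifier(c6_diag))
  expect_equal(classify_family(f6b, catalog), "f6b")
  expect_equal(classify_family(c6_diag, catalog), "f4c")
  # a 7-ring matches no core or lineage: new family
  expect_equal(classify_family(adj_cycle(7), catalog), "new")
  # named igraph inputs (residue-keyed contact networks) classify identically
  g <- igraph::graph_from_adjacency_matrix(adj_complete(3),
                                           mode = "undirected")
  igraph::V(g)$name <- c("12", "57", "104")
  expect_equal(classify_family(g, catalog), "f2")
})

test_that("induced subgraph search finds each occurrence once", {
  expect_length(find_induced(adj_complete(4), adj_complete(3)), 4)
  expect_length(find_induced(adj_cycle(5), adj_complete(3)), 0)
  # only contiguous 3-subsets of P4 induce a path
  occ <- find_induced(adj_path(4), adj_path(3))
  expect_length(occ, 2)
  expect_setequal(lapply(occ, sort), list(1:3, 2:4))
})

test_that("graph resolution cuts only bridges and covers all nodes", {
  catalog <- motif_catalog()
  # two triangles joined by one bridge -> two f2 components
  two_tri <- packnet:::adj_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                              c(4, 5), c(4, 6), c(5, 6),
                                              c(3, 4)))
  dec <- resolve_graph(two_tri, catalog)
  expect_equal(nrow(dec$components), 2)
  expect_equal(dec$components$family, c("f2", "f2"))
  expect_equal(nrow(dec$cut_edges), 1)
  expect_length(dec$unexplained, 0)
  # every cut edge must be a bridge of the original graph
  g <- igraph::graph_from_adjacency_matrix(two_tri, mode = "undirected")
  br <- igraph::ends(g, igraph::bridges(g))
  expect_true(all(apply(dec$cut_edges, 1, function(e) {
    any(apply(br, 1, function(b) setequal(b, e)))
  })))

  # triangle with a 3-node pendant path: cut the single bridge -> K3 + P3
  tri_tail <- packnet:::adj_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                               c(3, 4), c(4, 5), c(5, 6)))
  dec2 <- resolve_graph(tri_tail, catalog)
  expect_setequal(dec2$components$family, c("f2", "f1"))
  expect_equal(nrow(dec2$cut_edges), 1)

  # a bridgeless five-ring is itself the f4a core
  dec3 <- resolve_graph(adj_cycle(5), catalog)
  expect_equal(dec3$components$family, "f4a")
  expect_length(dec3$unexplained, 0)

  # bridgeless non-catalog graph resolves via induced subgraphs
  c7 <- adj_cycle(7)
  dec4 <- resolve_graph(c7, catalog)
  expect_equal(nrow(dec4$components), 0)
  expect_gt(nrow(dec4$induced), 0)
})

test_that("triplet-clique census separates isolated from embedded", {
  k3 <- igraph::graph_from_adjacency_matrix(adj_complete(3),
                                            mode = "undirected")
  k4 <- igraph::graph_from_adjacency_matrix(adj_complete(4),
                                            mode = "undirected")
  tri_pendant <- igraph::graph_from_adjacency_matrix(
    packnet:::adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3), c(1, 4))),
    mode = "undirected")
  out <- count_triplet_cliques(list(k3, k4, tri_pendant))
  expect_equal(out$isolated, 1)
  expect_equal(out$embedded, 4 + 1)
  expect_equal(out$per_network$n_embedded, c(0, 4, 1))
})
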