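graph_of <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = vapply(edges, `[`, "", 1),
               to = vapply(edges, `[`, "", 2)),
    directed = FALSE, vertices = nodes)
  g
}

identity_map <- function(nodes) data.frame(template = nodes,
                                           homologue = nodes)

test_that("conserved links honour the threshold and unaligned nodes", {
  tmpl <- graph_of(list(c("5", "9"), c("9", "14"), c("5", "14")))
  nodes <- c("5", "9", "14")
  # all homologues keep every link: everything retained at lp = 1
  homs <- list(tmpl, tmpl, tmpl)
  maps <- list(identity_map(nodes), identity_map(nodes), identity_map(nodes))
  sig <- conserved_links(tmpl, homs, maps)
  expect_equal(sig$n_links, 3)
  expect_equal(sig$links$lp, rep(1, 3))

  # a link present in 7 of 10 homologues is dropped at threshold 0.8
  with_link <- replicate(7, tmpl, simplify = FALSE)
  without <- replicate(3, graph_of(list(c("9", "14"), c("5", "14"))),
                       simplify = FALSE)
  sig2 <- conserved_links(tmpl, c(with_link, without),
                          replicate(10, identity_map(nodes),
                                    simplify = FALSE))
  expect_equal(sig2$n_links, 2)
  expect_false(any(sig2$links$res_a == "5" & sig2$links$res_b == "9"))

  # an unaligned endpoint counts as absent in that homologue
  gap_map <- data.frame(template = nodes, homologue = c("-", "9", "14"))
  sig3 <- conserved_links(tmpl, list(tmpl, tmpl),
                          list(identity_map(nodes), gap_map), threshold = 0.8)
  expect_equal(sig3$n_links, 1) # only 9-14 survives both homologues
})

test_that("subgraph extraction zero-pads absent nodes and stays induced", {
  tmpl <- graph_of(list(c("1", "2"), c("2", "3"), c("3", "4")))
  sig <- conserved_links(tmpl, list(tmpl), list(identity_map(as.character(1:4))))
  # identical candidate: subgraph equals the signature links
  sub <- extract_subgraph(tmpl, sig)
  expect_equal(sub, signature_adjacency(sig))
  # two signature nodes missing: their rows and columns are all zero
  cand <- graph_of(list(c("1", "2")))
  sub2 <- extract_subgraph(cand, sig)
  expect_true(all(sub2[c("3", "4"), ] == 0))
  expect_true(all(sub2[, c("3", "4")] == 0))
  expect_equal(sub2["1", "2"], 1L)
  # extra candidate links among signature nodes are included (induced)
  cand3 <- graph_of(list(c("1", "2"), c("2", "3"), c("3", "4"), c("1", "4")))
  sub3 <- extract_subgraph(cand3, sig)
  expect_equal(sub3["1", "4"], 1L)
})

test_that("snet is the conserved fraction, including the printed minimum", {
  set.seed(2)
  tmpl <- gen_random_graph(36, edge_count = 31, connected = FALSE, seed = 10)
  nodes <- igraph::V(tmpl)$name
  sig <- conserved_links(tmpl, list(tmpl), list(identity_map(nodes)))
  expect_equal(sig$n_links, 31)
  expect_equal(snet(sig, extract_subgraph(tmpl, sig)), 1)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  igraph::V(empty)$name <- character(0)
  expect_equal(snet(sig, extract_subgraph(empty, sig)), 0)
  # candidate conserving exactly 4 of 31 links
  keep <- sig$links[1:4, ]
  cand <- graph_of(purrr::map(seq_len(4), function(i) {
    c(keep$res_a[i], keep$res_b[i])
  }))
  expect_equal(round(snet(sig, extract_subgraph(cand, sig)), 3), 0.129)
})

test_that("dnet handles the trivial and degenerate cases", {
  a <- adj_complete(3)
  expect_equal(dnet(a, a), 0)
  b <- a; b[1, 2] <- b[2, 1] <- 0L
  expect_equal(dnet(a, b), 1 / 3)
  z <- matrix(0L, 3, 3)
  expect_equal(dnet(z, z), 0) # both empty: distance defined as 0
  disjoint1 <- packnet:::adj_from_edges(4, list(c(1, 2)))
  disjoint2 <- packnet:::adj_from_edges(4, list(c(3, 4)))
  expect_equal(dnet(disjoint1, disjoint2), 1)
  expect_error(dnet(a, matrix(0L, 4, 4)), "dimension")
})

test_that("dnet satisfies the metric axioms on random graph triples", {
  set.seed(14)
  rnd_adj <- function() {
    m <- matrix(0L, 7, 7)
    up <- which(upper.tri(m))
    m[up[stats::runif(length(up)) < 0.4]] <- 1L
    m + t(m)
  }
  for (i in 1:1000) {
    a <- rnd_adj(); b <- rnd_adj(); c <- rnd_adj()
    dab <- dnet(a, b); dbc <- dnet(b, c); dac <- dnet(a, c)
    expect_gte(dab, 0)
    expect_equal(dab, dnet(b, a))
    expect_equal(dnet(a, a), 0)
    if (dab == 0) expect_identical(a, b)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("degrading a candidate decreases snet and increases dnet", {
  tmpl <- gen_random_graph(20, edge_count = 25, connected = FALSE, seed = 4)
  nodes <- igraph::V(tmpl)$name
  sig <- conserved_links(tmpl, list(tmpl), list(identity_map(nodes)))
  sig_adj <- signature_adjacency(sig)
  cand <- tmpl
  prev_snet <- snet(sig, extract_subgraph(cand, sig))
  prev_dnet <- dnet(sig_adj, extract_subgraph(cand, sig))
  for (k in 1:10) {
    cand <- igraph::delete_edges(cand, 1)
    s <- snet(sig, extract_subgraph(cand, sig))
    d <- dnet(sig_adj, extract_subgraph(cand, sig))
    expect_lt(s, prev_snet)
    expect_gte(d, prev_dnet)
    prev_snet <- s
    prev_dnet <- d
  }
})

test_that("candidate scoring reports population statistics", {
  tmpl <- gen_random_graph(15, edge_count = 20, connected = FALSE, seed = 6)
  nodes <- igraph::V(tmpl)$name
  sig <- conserved_links(tmpl, list(tmpl), list(identity_map(nodes)))
  # identical candidates: mean snet 1, sd 0, dnet 0
  sc <- score_candidates(sig, list(a = tmpl, b = tmpl))
  expect_equal(sc$summary$mean[sc$summary$measure == "snet"], 1)
  expect_equal(sc$summary$sd, c(0, 0))
  expect_equal(sc$summary$mean[sc$summary$measure == "dnet"], 0)
  expect_s3_class(tidy(sc), "tbl_df")
  expect_equal(nrow(glance(sc)), 1)

  # empty candidates: snet 0, dnet 1
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  igraph::V(empty)$name <- character(0)
  sc0 <- score_candidates(sig, list(e = empty))
  expect_equal(sc0$scores$snet, 0)
  expect_equal(sc0$scores$dnet, 1)

  # random candidates at density p conserve about p of the signature links
  ld <- 0.3
  rnd <- purrr::map(1:150, function(s) {
    g <- random_graph(length(nodes), ld, seed = 100 + s)
    igraph::V(g)$name <- nodes
    g
  })
  scr <- score_candidates(sig, rnd)
  expect_lt(abs(mean(scr$scores$snet) - ld), 0.03)
})

test_that("snet and dnet are anti-correlated on graded homologue series", {
  tmpl <- gen_random_graph(18, edge_count = 24, connected = FALSE, seed = 9)
  nodes <- igraph::V(tmpl)$name
  sig <- conserved_links(tmpl, list(tmpl), list(identity_map(nodes)))
  graded <- purrr::map(seq(0, 20, by = 4), function(k) {
    g <- tmpl
    if (k > 0) g <- igraph::delete_edges(g, seq_len(k))
    g
  })
  sc <- score_candidates(sig, graded)
  expect_lt(stats::cor(sc$scores$snet, sc$scores$dnet), -0.9)
})

test_that("residue maps round-trip through the two-column format", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("10\t12", "11\t13", "12\t-"), path)
  mp <- read_residue_map(path)
  expect_equal(mp$homologue, c("12", "13", NA))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("10\t12", "11\t12"), bad)
  expect_error(read_residue_map(bad), "one-to-one")
})

test_that("fold signatures round-trip through JSON", {
  tmpl <- graph_of(list(c("1", "2"), c("2", "3")))
  sig <- conserved_links(tmpl, list(tmpl),
                         list(identity_map(as.character(1:3))))
  path <- tempfile(fileext = ".json")
  write_fold_signature(sig, path)
  back <- read_fold_signature(path)
  expect_equal(back$links$res_a, sig$links$res_a)
  expect_equal(back$nodes, sig$nodes)
  expect_equal(back$n_links, sig$n_links)
})
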