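# Small graph plumbing shared by the motif / network / fold modules.
# Graphs circulate either as igraph objects (networks with residue names)
# or as dense symmetric 0/1 adjacency matrices (small abstract motifs).

as_adj <- function(g) {
  if (igraph::is_igraph(g)) {
    m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    m[m > 0] <- 1L
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    return(m)
  }
  if (is.matrix(g)) {
    abort_if(nrow(g) != ncol(g), "adjacency matrix must be square")
    m <- g
    m[m != 0] <- 1L
    storage.mode(m) <- "integer"
    abort_if(!isTRUE(all.equal(m, t(m), check.attributes = FALSE)),
             "adjacency matrix must be symmetric")
    abort_if(any(diag(m) != 0), "adjacency matrix must have a zero diagonal")
    return(m)
  }
  stop("expected an igraph object or an adjacency matrix", call. = FALSE)
}

adj_from_edges <- function(n, edges) {
  m <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(as.integer(unlist(edges)), ncol = 2, byrow = TRUE)
    m[e] <- 1L
    m[e[, 2:1, drop = FALSE]] <- 1L
  }
  m
}

adj_connected <- function(m) {
  n <- nrow(m)
  if (n <= 1) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(m[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

adj_delete_vertex <- function(m, v) m[-v, -v, drop = FALSE]

# deterministic edge list (i < j) from an adjacency matrix
adj_edges <- function(m) {
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
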