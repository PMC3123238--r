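#' Conserved-link fold signature from a template network and homologues
#'
#' For every link of the template's surface contact network, the conservation
#' fraction `lp` is the fraction of homologues in which both endpoint
#' residues are mapped (aligned) and connected; an unaligned endpoint counts
#' as an absent link in that homologue. Links with `lp >= threshold`
#' constitute the fold-specific subgraph.
#'
#' @param template_net igraph network of the template structure (vertex
#'   names are template residue ids; optional edge attributes `sm`, `ov`).
#' @param homologue_nets List of igraph networks for the homologues.
#' @param maps List of residue maps (one per homologue), each a two-column
#'   data frame `template`/`homologue` (see [read_residue_map()]); `NA` or
#'   `"-"` marks a gap.
#' @param threshold Minimum conservation fraction (default 0.8).
#' @return An object of class `fold_signature`: list with `links` (tibble
#'   `res_a`, `res_b`, `lp`, and `sm`/`ov` when available), `nodes` (template
#'   residue ids, template order) and `n_links`.
#' @export
conserved_links <- function(template_net, homologue_nets, maps,
                            threshold = 0.8) {
  abort_if(igraph::ecount(template_net) == 0, "template network has no links")
  abort_if(length(homologue_nets) != length(maps),
           "need one residue map per homologue network")
  te <- network_edges(template_net)
  lp <- matrix(0, nrow(te), length(homologue_nets))
  for (h in seq_along(homologue_nets)) {
    map <- normalize_map(maps[[h]])
    hn <- homologue_nets[[h]]
    hv <- igraph::V(hn)$name
    ma <- map$homologue[match(te$res_a, map$template)]
    mb <- map$homologue[match(te$res_b, map$template)]
    ok <- !is.na(ma) & !is.na(mb) & ma %in% hv & mb %in% hv
    if (any(ok)) {
      lp[ok, h] <- are_adjacent_multi(hn, ma[ok], mb[ok])
    }
  }
  te$lp <- rowMeans(lp)
  links <- te[te$lp >= threshold, , drop = FALSE]
  keep <- c("res_a", "res_b", "lp", intersect(c("sm", "ov"), names(links)))
  links <- links[, keep, drop = FALSE]
  nodes <- igraph::V(template_net)$name
  nodes <- nodes[nodes %in% c(links$res_a, links$res_b)]
  out <- list(links = tibble::as_tibble(links), nodes = nodes,
              n_links = nrow(links))
  class(out) <- "fold_signature"
  out
}

# vectorised edge test (igraph's are_adjacent takes single pairs)
are_adjacent_multi <- function(g, a, b) {
  el <- igraph::as_edgelist(g)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  paste(pmin(a, b), pmax(a, b)) %in% key
}

normalize_map <- function(map) {
  map <- as.data.frame(map)
  names(map)[1:2] <- c("template", "homologue")
  map$template <- as.character(map$template)
  map$homologue <- as.character(map$homologue)
  map$homologue[map$homologue %in% c("-", "")] <- NA_character_
  abort_if(anyDuplicated(stats::na.omit(map$homologue)) > 0 ||
             anyDuplicated(map$template) > 0,
           "residue map must be one-to-one on mapped residues")
  map
}

#' @export
print.fold_signature <- function(x, ...) {
  cat(sprintf("Fold signature: %d conserved links over %d nodes\n",
              x$n_links, length(x$nodes)))
  invisible(x)
}

#' Signature-ordered subgraph adjacency of a candidate network
#'
#' Builds the adjacency matrix of the candidate's induced subgraph over the
#' signature nodes, rows and columns in template residue order; nodes absent
#' from the candidate (unmapped or missing) give zero-padded rows/columns.
#' All links of the candidate among present signature nodes are included
#' (induced definition), not only links of the signature.
#'
#' @param candidate_net igraph network of the candidate; vertex names use
#'   template residue numbering directly, or are translated via `map`.
#' @param signature A `fold_signature`.
#' @param map Optional residue map (template to candidate) as in
#'   [conserved_links()].
#' @return A symmetric 0/1 matrix with signature nodes as dimnames.
#' @export
extract_subgraph <- function(candidate_net, signature, map = NULL) {
  nodes <- signature$nodes
  k <- length(nodes)
  m <- matrix(0L, k, k, dimnames = list(nodes, nodes))
  cand_names <- if (is.null(map)) {
    stats::setNames(nodes, nodes)
  } else {
    mp <- normalize_map(map)
    stats::setNames(mp$homologue[match(nodes, mp$template)], nodes)
  }
  present <- !is.na(cand_names) & cand_names %in% igraph::V(candidate_net)$name
  if (sum(present) >= 2) {
    sub <- igraph::induced_subgraph(candidate_net,
                                    unname(cand_names[present]))
    el <- igraph::as_edgelist(sub)
    if (nrow(el)) {
      back <- stats::setNames(nodes[present], cand_names[present])
      ia <- back[el[, 1]]
      ib <- back[el[, 2]]
      m[cbind(ia, ib)] <- 1L
      m[cbind(ib, ia)] <- 1L
    }
  }
  m
}

#' Fold-similarity measure snet
#'
#' The fraction `N_t / N_s` of the signature's conserved links found in the
#' candidate subgraph.
#'
#' @param signature A `fold_signature`.
#' @param subgraph Adjacency matrix from [extract_subgraph()].
#' @return Value in `[0, 1]`.
#' @export
snet <- function(signature, subgraph) {
  abort_if(signature$n_links == 0, "empty signature")
  l <- signature$links
  present <- subgraph[cbind(l$res_a, l$res_b)] > 0
  sum(present) / signature$n_links
}

#' Topological distance dnet between two same-ordered subgraphs
#'
#' Counts links present in one graph and absent in the other, normalised by
#' the number of links present in either: `|E delta E'| / |E union E'|`. Two
#' identical empty graphs have distance 0. `dnet` is a metric on graphs over
#' a fixed ordered node set.
#'
#' @param a,a_prime Symmetric 0/1 adjacency matrices of identical dimension
#'   and node order.
#' @return Value in `[0, 1]`.
#' @export
dnet <- function(a, a_prime) {
  abort_if(!all(dim(a) == dim(a_prime)), "adjacency dimensions differ")
  ut <- upper.tri(a)
  ea <- a[ut] > 0
  eb <- a_prime[ut] > 0
  union_n <- sum(ea | eb)
  if (union_n == 0) return(0)
  sum(xor(ea, eb)) / union_n
}

#' Score candidate networks against a fold signature
#'
#' Computes `snet` and `dnet` for each candidate and population statistics
#' (mean, standard deviation, min, max); when a reference group is given the
#' discrimination margin is reported in units of the decoy standard
#' deviation.
#'
#' @param signature A `fold_signature`.
#' @param candidate_nets Named list of candidate igraph networks.
#' @param maps Optional list of residue maps (template to candidate), one per
#'   candidate or `NULL` for template numbering.
#' @return A list with `scores` (tibble `id`, `snet`, `dnet`) and `summary`
#'   (tibble of mean/sd/min/max per measure); class `fold_scores` with
#'   [generics::tidy()]/[generics::glance()] methods.
#' @export
score_candidates <- function(signature, candidate_nets, maps = NULL) {
  abort_if(length(candidate_nets) == 0, "need at least one candidate")
  sig_adj <- signature_adjacency(signature)
  ids <- names(candidate_nets) %||% as.character(seq_along(candidate_nets))
  rows <- purrr::imap(candidate_nets, function(g, i) {
    mp <- if (is.null(maps)) NULL else maps[[i]]
    sub <- extract_subgraph(g, signature, map = mp)
    tibble::tibble(snet = snet(signature, sub), dnet = dnet(sig_adj, sub))
  })
  scores <- dplyr::bind_rows(rows)
  scores <- dplyr::bind_cols(tibble::tibble(id = ids), scores)
  summary <- tibble::tibble(
    measure = c("snet", "dnet"),
    mean = c(mean(scores$snet), mean(scores$dnet)),
    sd = c(stats::sd(scores$snet), stats::sd(scores$dnet)),
    min = c(min(scores$snet), min(scores$dnet)),
    max = c(max(scores$snet), max(scores$dnet))
  )
  summary$sd[is.na(summary$sd)] <- 0
  out <- list(scores = scores, summary = summary, signature = signature)
  class(out) <- "fold_scores"
  out
}

#' Adjacency matrix of the signature itself (template subgraph)
#'
#' @param signature A `fold_signature`.
#' @return Symmetric 0/1 matrix over the signature nodes.
#' @export
signature_adjacency <- function(signature) {
  nodes <- signature$nodes
  m <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  l <- signature$links
  m[cbind(l$res_a, l$res_b)] <- 1L
  m[cbind(l$res_b, l$res_a)] <- 1L
  m
}

#' @export
print.fold_scores <- function(x, ...) {
  cat(sprintf("Fold-compatibility scores for %d candidates\n",
              nrow(x$scores)))
  print(x$summary)
  invisible(x)
}

#' @method tidy fold_scores
#' @export
tidy.fold_scores <- function(x, ...) x$scores

#' @method glance fold_scores
#' @export
glance.fold_scores <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "measure",
                     values_from = c("mean", "sd", "min", "max"))
}

#' Read a residue correspondence map
#'
#' Two-column whitespace/tab-separated table, template residue id then
#' homologue residue id, `"-"` marking a gap. Any structural aligner's output
#' can be reduced to this form.
#'
#' @param path File path.
#' @return Tibble with character columns `template`, `homologue` (`NA` for
#'   gaps).
#' @export
read_residue_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          col.names = c("template", "homologue"))
  tibble::as_tibble(normalize_map(df))
}

#' Write / read a fold signature as JSON
#'
#' @param signature A `fold_signature`.
#' @param path File path.
#' @return `read_fold_signature()` returns the `fold_signature`;
#'   `write_fold_signature()` returns `path` invisibly.
#' @export
write_fold_signature <- function(signature, path) {
  jsonlite::write_json(
    list(nodes = signature$nodes, links = signature$links),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_signature
#' @export
read_fold_signature <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(links = tibble::as_tibble(raw$links),
              nodes = as.character(raw$nodes),
              n_links = nrow(raw$links))
  class(out) <- "fold_signature"
  out
}
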