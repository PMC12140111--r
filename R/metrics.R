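#' Average shortest path length
#'
#' Mean, over all unordered node pairs, of the minimum number of edges
#' between them (unweighted breadth-first distances). The global
#' interconnectivity measure: higher values mean a more spread-out
#' semantic network.
#'
#' @param g connected igraph network.
#' @return numeric scalar, >= 1 for any graph with an edge.
#' @export
net_aspl <- function(g) {
  if (!igraph::is_connected(g)) stop("ASPL undefined on disconnected graph")
  igraph::mean_distance(g, directed = FALSE, unconnected = FALSE)
}

#' Mean local clustering coefficient
#'
#' The Watts-Strogatz local coefficient, averaged over all nodes: for a
#' node of degree `d >= 2` with `T` triangles through it the local value
#' is `2T / (d (d - 1))`; nodes of degree below two contribute zero (the
#' denominator stays at n). Local interconnectivity: the chance that two
#' neighbours of a node are themselves neighbours.
#'
#' @param g igraph network with at least one node.
#' @return numeric scalar in \[0, 1\].
#' @export
net_clustering <- function(g) {
  stopifnot(igraph::vcount(g) >= 1)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Newman modularity via deterministic Louvain
#'
#' Detects communities by multilevel (Louvain) modularity optimization
#' with a deterministic node sweep: lexicographic vertex order when
#' `seed = 0`, a seeded permutation otherwise. Returns the modularity
#' `Q = sum_c [ e_c / m - (d_c / (2m))^2 ]` of the detected partition —
#' the compartmentalization of the network into sub-networks.
#'
#' @param g igraph network with at least one edge.
#' @param seed integer; 0 (default) keeps the lexicographic sweep order,
#'   any other value permutes it reproducibly.
#' @return list with `q` (numeric) and `membership` (named integer
#'   vector of community ids).
#' @export
net_modularity <- function(g, seed = 0L) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m < 1) stop("Q undefined on edgeless graph")
  el <- igraph::as_edgelist(g, names = FALSE)
  ord <- seq_len(n)
  if (seed != 0) {
    ord <- withr::with_seed(as.integer(seed), sample.int(n))
  }
  res <- .louvain_cpp(n, el, rep(1, nrow(el)), as.integer(ord))
  memb <- setNames(as.integer(res$membership), igraph::V(g)$name)
  list(q = res$q, membership = memb)
}

#' Recompute Q for a given partition (independent of the optimizer)
#'
#' @param g igraph network.
#' @param membership integer community id per vertex, in vertex order.
#' @return numeric Q.
#' @export
modularity_value <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  stopifnot(m >= 1, length(membership) == igraph::vcount(g))
  intra <- membership[el[, 1]] == membership[el[, 2]]
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(membership)) {
    e_c <- sum(intra & membership[el[, 1]] == c)
    d_c <- sum(deg[membership == c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  unname(q)
}

#' All three network coefficients of a semantic network
#'
#' @param g connected igraph network.
#' @param seed Louvain sweep seed (see [net_modularity()]).
#' @return one-row tibble: `n_nodes`, `n_edges`, `aspl`, `cc`, `q`, with
#'   the community assignment in attribute `"membership"`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' network_metrics(g)  # aspl = 1, cc = 1, q = 0
#' @export
network_metrics <- function(g, seed = 0L) {
  mod <- net_modularity(g, seed = seed)
  out <- tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    aspl = net_aspl(g),
    cc = net_clustering(g),
    q = mod$q
  )
  attr(out, "membership") <- mod$membership
  out
}
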