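#' Cosine co-occurrence association matrix
#'
#' For binary response columns, the cosine of exemplars i and j is
#' `c_ij / sqrt(c_i * c_j)` where `c_ij` counts participants who
#' produced both and `c_i` those who produced i. All values lie in
#' \[0, 1\]: 0 when two exemplars never co-occur in a participant's
#' list, 1 when they always co-occur. Using similarity (rather than a
#' correlation) avoids negative associations between nodes.
#'
#' @param m binary response matrix (participants x exemplars), every
#'   column produced by at least one participant.
#' @return symmetric numeric matrix with unit diagonal, dimnames =
#'   exemplars.
#' @export
cosine_matrix <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 exemplars")
  co <- crossprod(m)
  d <- sqrt(diag(co))
  if (any(d == 0)) stop("orphan exemplar")
  a <- co / outer(d, d)
  diag(a) <- 1
  a
}

#' Triangulated Maximally Filtered Graph
#'
#' Filters an association matrix to an unweighted, undirected, connected
#' planar graph with exactly `3n - 6` edges: the four nodes with the
#' highest sum of associations to all others form the seed tetrahedron,
#' then each remaining node is inserted, best first, into the triangular
#' face where its summed association to the three corners is largest,
#' gaining exactly three edges. Weights guide the topology only; the
#' returned graph is unweighted. Ties are broken by lowest node index in
#' the (lexicographic) label order, so the construction is
#' deterministic.
#'
#' For fewer than five nodes the complete graph is returned (`K4` is the
#' TMFG of any 4-node matrix); fewer than four nodes is an error unless
#' `strict = FALSE`, the pipeline mode in which degenerate bootstrap
#' resamples fall back to the complete graph.
#'
#' @param a symmetric association matrix with labels as dimnames.
#' @param strict error on n < 4 (default) instead of returning `K_n`.
#' @return an [igraph][igraph::graph_from_edgelist] graph with vertex
#'   names in the matrix's label order; graph attributes `faces` (the
#'   `2n - 4` triangles of the final triangulation, a planarity
#'   certificate) and `seed_nodes`.
#' @export
tmfg <- function(a, strict = TRUE) {
  n <- nrow(a)
  stopifnot(n == ncol(a), !is.null(colnames(a)))
  if (any(!is.finite(a))) stop("non-finite association values")
  labels <- colnames(a)
  if (n < 4) {
    if (strict) stop("TMFG requires >= 4 nodes")
    g <- igraph::make_full_graph(n)
    igraph::V(g)$name <- labels
    return(g)
  }
  res <- .tmfg_cpp(unname(a))
  g <- igraph::graph_from_edgelist(res$edges, directed = FALSE)
  igraph::V(g)$name <- labels
  g <- igraph::set_graph_attr(g, "faces", res$faces)
  g <- igraph::set_graph_attr(g, "seed_nodes", res$seed)
  g
}

#' Estimate a group semantic network from a response matrix
#'
#' Composition of [cosine_matrix()] and [tmfg()]; deterministic given
#' the matrix.
#'
#' @inheritParams cosine_matrix
#' @param strict passed to [tmfg()].
#' @return an igraph semantic network.
#' @export
estimate_group_network <- function(m, strict = TRUE) {
  tmfg(cosine_matrix(m), strict = strict)
}

#' Export a semantic network as an edge list
#'
#' @param g igraph network with named vertices.
#' @param path CSV path (`source,target`); a JSON descriptor with the
#'   label set, node and edge counts is written alongside as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  readr::write_csv(tibble::tibble(source = el[, 1], target = el[, 2]), path)
  jsonlite::write_json(
    list(labels = igraph::V(g)$name,
         n_nodes = igraph::vcount(g),
         n_edges = igraph::ecount(g)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
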