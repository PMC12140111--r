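# Independent reference implementations used as oracles. These recompute
# everything from scratch with naive algorithms and share no code with the
# package internals they check.

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
ref_aspl <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  d <- ifelse(a == 1, 1, Inf)
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  mean(d[upper.tri(d)])
}

# mean local clustering by explicit triangle counting
ref_cc <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  vals <- numeric(n)
  for (v in 1:n) {
    nb <- which(a[v, ] == 1)
    d <- length(nb)
    vals[v] <- if (d < 2) 0 else sum(a[nb, nb]) / (d * (d - 1))
  }
  mean(vals)
}

# every set partition of 1..n as a membership vector (Bell(8) = 4140)
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, i, k) {
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (c in seq_len(k + 1)) {
      memb[i] <- c
      rec(memb, i + 1, max(k, c))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}

# exhaustive-maximum modularity over all partitions (n <= 8)
ref_q_max <- function(g) {
  best <- -Inf
  for (memb in all_partitions(igraph::vcount(g))) {
    q <- modularity_value(g, memb)
    if (q > best) best <- q
  }
  best
}

# Independent greedy TMFG: recomputes every gain from scratch at every
# step (no incremental bookkeeping) and can audit that each choice is the
# exhaustive max-gain one. Returns a sorted edge-pair matrix.
ref_tmfg_edges <- function(a, audit = FALSE) {
  n <- nrow(a)
  diag(a) <- 0
  rs <- rowSums(a)
  seed <- order(-rs, seq_len(n))[1:4]
  edges <- t(combn(sort(seed), 2))
  faces <- combn(sort(seed), 3)
  faces <- lapply(seq_len(ncol(faces)), function(i) faces[, i])
  unplaced <- setdiff(seq_len(n), seed)
  while (length(unplaced) > 0) {
    gains <- sapply(faces, function(f) sapply(unplaced, function(v) sum(a[v, f])))
    gains <- matrix(gains, nrow = length(unplaced))  # rows v, cols face
    mx <- max(gains)
    hit <- which(gains == mx, arr.ind = TRUE)
    # lowest node index, then earliest face
    hit <- hit[order(unplaced[hit[, 1]], hit[, 2]), , drop = FALSE]
    v <- unplaced[hit[1, 1]]
    fi <- hit[1, 2]
    if (audit) {
      stopifnot(sum(a[v, faces[[fi]]]) == mx)  # chosen = exhaustive max
    }
    f <- faces[[fi]]
    edges <- rbind(edges, cbind(pmin(v, f), pmax(v, f)))
    faces[[fi]] <- NULL
    for (drop in 1:3) faces[[length(faces) + 1]] <- sort(c(f[-drop], v))
    unplaced <- setdiff(unplaced, v)
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

sorted_edge_pairs <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# validate the triangulation certificate carried by tmfg(): 2n-4
# triangular faces over existing edges, every edge on exactly two faces;
# together with connectivity this gives Euler characteristic
# n - (3n-6) + (2n-4) = 2, i.e. a sphere triangulation, hence planarity
check_triangulation <- function(g) {
  faces <- igraph::graph_attr(g, "faces")
  n <- igraph::vcount(g)
  if (is.null(faces) || nrow(faces) != 2 * n - 4) return(FALSE)
  fe <- rbind(faces[, c(1, 2)], faces[, c(1, 3)], faces[, c(2, 3)])
  fkey <- paste(pmin(fe[, 1], fe[, 2]), pmax(fe[, 1], fe[, 2]))
  el <- sorted_edge_pairs(g)
  ekey <- paste(el[, 1], el[, 2])
  all(table(fkey) == 2) && setequal(unique(fkey), ekey)
}

# random symmetric similarity matrix in [0,1] with labels
random_similarity <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

# random connected graph for metric oracles
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- sprintf("n%02d", 1:n)
      return(g)
    }
  }
}

# tiny lexicon used across preprocessing tests
toy_lexicon <- function() {
  lexicon(
    raw = c("dog", "dogs", "cat", "cats", "fox", "owl", "hen", "dragon", "table"),
    canonical = c("dog", "dog", "cat", "cat", "fox", "owl", "hen", "dragon", "table"),
    status = c("ok", "ok", "ok", "ok", "ok", "ok", "ok", "fictional", "non_category")
  )
}

long_fluency <- function(lists, groups = NULL) {
  ids <- names(lists)
  if (is.null(groups)) groups <- rep("A", length(ids))
  dplyr::bind_rows(purrr::map2(ids, seq_along(ids), function(id, i) {
    tibble::tibble(participant_id = id, group = groups[i],
                   position = seq_along(lists[[id]]), response = lists[[id]])
  }))
}

small_cleaned <- function(lists, groups) {
  tibble::tibble(
    participant_id = names(lists),
    group = groups,
    tokens = unname(lists),
    n_cleaned = unname(lengths(lists)),
    exclusions = rep(list(tibble::tibble(raw = character(0),
                                         reason = character(0))),
                     length(lists))
  )
}
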