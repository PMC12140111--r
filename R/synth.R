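#' Configuration of a synthetic fluency world
#'
#' The generator emulates the study design the package targets: two
#' groups of 38 children naming animals, with group mean cleaned-list
#' lengths of about 13 (SD 3.5) versus 18 (SD 5.2), a shared vocabulary
#' of order 100-250 exemplars organized into semantic sub-categories,
#' singleton responses, occasional intrusions/perseverations/
#' misspellings, and SES / non-verbal-intelligence covariates on 0-100
#' scales. Semantic memory is modelled as a connected stochastic block
#' model (categories = blocks); retrieval as a censored random walk with
#' restarts; group differences are induced by deleting/rewiring
#' within-block edges of a group's latent graph and by the list-length
#' difference, each independently zeroable.
#'
#' @param v vocabulary size (default 100; must be a multiple of `k`).
#' @param k number of semantic categories (default 5).
#' @param p_in,p_out within/between-category latent edge probabilities
#'   (defaults 0.35 / 0.03; `p_in > p_out`).
#' @param n_per_group participants per group (default 38).
#' @param groups two group labels, lexicographic order is the reporting
#'   order (default `c("A", "B")`; group A is the shorter-list group).
#' @param list_length per-group `c(mean, sd)` of cleaned list length.
#' @param group_effect per-group `c(edge_deletion_frac, rewire_frac)`
#'   applied to that group's latent graph (defaults 0: null world).
#' @param jump_prob random-restart probability of the retrieval walk.
#' @param noise `c(intrusion_rate, perseveration_rate, misspelling_rate)`.
#' @param ses,nvi per-group `c(mean, sd)` of the covariates (0-100
#'   scales).
#' @param nvi_length_cor correlation between non-verbal intelligence and
#'   list length within group (default 0.3).
#' @param master_seed integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return a validated config list of class `fluenet_world_config`.
#' @export
world_config <- function(v = 100, k = 5, p_in = 0.35, p_out = 0.03,
                         n_per_group = 38, groups = c("A", "B"),
                         list_length = list(c(mean = 13.05, sd = 3.48),
                                            c(mean = 17.92, sd = 5.16)),
                         group_effect = list(
                           c(edge_deletion_frac = 0, rewire_frac = 0),
                           c(edge_deletion_frac = 0, rewire_frac = 0)),
                         jump_prob = 0.15,
                         noise = c(intrusion_rate = 0.03,
                                   perseveration_rate = 0.05,
                                   misspelling_rate = 0.05),
                         ses = list(c(mean = 58.6, sd = 25.1),
                                    c(mean = 59, sd = 18.1)),
                         nvi = list(c(mean = 51.8, sd = 11.1),
                                    c(mean = 88.7, sd = 9.82)),
                         nvi_length_cor = 0.3, master_seed = 1) {
  stopifnot(
    v %% k == 0, v >= 4 * k,
    p_in > p_out, p_in <= 1, p_out >= 0,
    length(groups) == 2, !anyDuplicated(groups),
    n_per_group >= 2, jump_prob >= 0, jump_prob <= 1,
    all(noise >= 0), all(noise <= 1),
    abs(nvi_length_cor) <= 1
  )
  for (ge in group_effect) stopifnot(all(ge >= 0), all(ge <= 1))
  cfg <- list(v = v, k = k, p_in = p_in, p_out = p_out,
              n_per_group = n_per_group, groups = groups,
              list_length = setNames(list_length, groups),
              group_effect = setNames(group_effect, groups),
              jump_prob = jump_prob, noise = noise,
              ses = setNames(ses, groups), nvi = setNames(nvi, groups),
              nvi_length_cor = nvi_length_cor,
              master_seed = as.integer(master_seed))
  class(cfg) <- "fluenet_world_config"
  cfg
}

#' Latent semantic world: connected stochastic block model
#'
#' `k` equal categories over `v` exemplars with edge probabilities
#' (`p_in`, `p_out`); resampled (up to 100 attempts, logged) until
#' connected, since retrieval walks must be able to reach every
#' exemplar.
#'
#' @param cfg a [world_config()].
#' @param seed integer seed.
#' @return igraph graph, vertex names `w001...`, vertex attribute
#'   `block`.
#' @export
generate_world <- function(cfg, seed) {
  block <- rep(seq_len(cfg$k), each = cfg$v / cfg$k)
  pm <- matrix(cfg$p_out, cfg$k, cfg$k)
  diag(pm) <- cfg$p_in
  withr::with_seed(as.integer(seed), {
    for (attempt in 1:100) {
      g <- igraph::sample_sbm(cfg$v, pref.matrix = pm,
                              block.sizes = rep(cfg$v / cfg$k, cfg$k))
      if (igraph::is_connected(g)) {
        if (attempt > 1) message("world connected after ", attempt, " attempts")
        igraph::V(g)$name <- sprintf("w%03d", seq_len(cfg$v))
        igraph::V(g)$block <- block
        return(g)
      }
    }
    stop("could not sample a connected world in 100 attempts")
  })
}

#' Degrade a latent world into a group-specific graph
#'
#' Deletes a fraction of within-category edges and rewires a fraction of
#' all edges uniformly at random, refusing any move that would
#' disconnect the graph (skipped moves are counted in the attribute
#' `"rejected_moves"`). This implements the hypothesis of a less
#' interconnected semantic network for one group; zero fractions return
#' the world unchanged.
#'
#' @param world graph from [generate_world()].
#' @param edge_deletion_frac fraction of within-block edges to delete.
#' @param rewire_frac fraction of edges to rewire to a random non-edge.
#' @param seed integer seed.
#' @return igraph graph.
#' @export
make_group_network <- function(world, edge_deletion_frac = 0,
                               rewire_frac = 0, seed = 1) {
  stopifnot(edge_deletion_frac >= 0, edge_deletion_frac <= 1,
            rewire_frac >= 0, rewire_frac <= 1)
  if (edge_deletion_frac == 0 && rewire_frac == 0) return(world)
  g <- world
  rejected <- 0L
  withr::with_seed(as.integer(seed), {
    blk <- igraph::V(g)$block
    el <- igraph::as_edgelist(g, names = FALSE)
    within <- which(blk[el[, 1]] == blk[el[, 2]])
    n_del <- round(edge_deletion_frac * length(within))
    for (e in sample(within)) {
      if (n_del <= 0) break
      cand <- igraph::get_edge_ids(g, el[e, ])
      if (cand == 0) next  # already gone via a previous rewire
      g2 <- igraph::delete_edges(g, cand)
      if (igraph::is_connected(g2)) {
        g <- g2
        n_del <- n_del - 1L
      } else {
        rejected <- rejected + 1L
      }
    }
    n_rw <- round(rewire_frac * igraph::ecount(g))
    for (i in seq_len(n_rw)) {
      el2 <- igraph::as_edgelist(g, names = FALSE)
      e <- sample(nrow(el2), 1)
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, el2[e, ]))
      # draw a random currently-absent pair
      for (try in 1:20) {
        uv <- sample(igraph::vcount(g), 2)
        if (igraph::get_edge_ids(g2, uv) == 0) break
      }
      g2 <- igraph::add_edges(g2, uv)
      if (igraph::is_connected(g2)) g <- g2 else rejected <- rejected + 1L
    }
  })
  g <- igraph::set_graph_attr(g, "rejected_moves", rejected)
  g
}

#' Censored random walk over a latent semantic graph
#'
#' Starts at a uniform node; at each step restarts at a uniform node
#' with probability `jump_prob`, otherwise moves to a uniform neighbour.
#' Only first visits are emitted (already-produced exemplars are
#' censored), matching how fluency lists revisit but do not re-report
#' concepts. Stops after `length` distinct exemplars or `50 * length`
#' steps (whichever first; a truncated list carries attribute
#' `"truncated"`).
#'
#' @param graph igraph graph with named vertices.
#' @param length target number of distinct exemplars.
#' @param jump_prob restart probability.
#' @param seed optional integer seed.
#' @return character vector of exemplar names in emission order.
#' @export
simulate_participant <- function(graph, length, jump_prob = 0.15,
                                 seed = NULL) {
  stopifnot(length >= 1)
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, as.integer)
  run <- function() walk_emit(adj, igraph::vcount(graph), length, jump_prob)
  ids <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  out <- igraph::V(graph)$name[ids$visited]
  if (ids$truncated) attr(out, "truncated") <- TRUE
  out
}

walk_emit <- function(adj, n, len, jump_prob) {
  len <- min(len, n)
  visited <- integer(0)
  seen <- logical(n)
  cur <- sample.int(n, 1)
  steps <- 0L
  cap <- 50L * len
  repeat {
    if (!seen[cur]) {
      seen[cur] <- TRUE
      visited <- c(visited, cur)
      if (length(visited) >= len) break
    }
    steps <- steps + 1L
    if (steps >= cap) break
    nb <- adj[[cur]]
    cur <- if (runif(1) < jump_prob || length(nb) == 0) {
      sample.int(n, 1)
    } else {
      nb[sample.int(length(nb), 1)]
    }
  }
  list(visited = visited, truncated = length(visited) < len)
}

#' Generate a synthetic two-group fluency cohort
#'
#' Draws the latent world, per-group degraded graphs, per-participant
#' list lengths (normal, truncated at 1) and retrieval walks, then
#' injects noise: perseverations (re-emission of an earlier response),
#' intrusions (out-of-category or fictional tokens) and misspellings
#' (surface variants of emitted exemplars — a plural form recoverable by
#' rule, or a typo form covered by the emitted lexicon). SES is drawn
#' per group; non-verbal intelligence is drawn with the configured
#' correlation to list length. The returned lexicon covers every token
#' the generator can emit, so cleaning is exact.
#'
#' With `mirrored = TRUE` only the first group is generated and its
#' participants are copied (new ids, other label) into the second group:
#' the calibration null in which any bootstrap group difference is pure
#' resampling noise.
#'
#' @param cfg a [world_config()].
#' @param mirrored logical, see above.
#' @return object of class `fluenet_cohort`: list with `fluency` (long
#'   tibble), `covariates`, `lexicon`, and `truth` (config, seeds, the
#'   latent world and group graphs, and per-participant generated
#'   lists — everything needed to regenerate or audit the cohort).
#' @export
generate_cohort <- function(cfg, mirrored = FALSE) {
  stopifnot(inherits(cfg, "fluenet_world_config"))
  seeds <- withr::with_seed(cfg$master_seed,
                            sample.int(.Machine$integer.max - 1L, 4))
  world <- generate_world(cfg, seeds[1])
  gen_groups <- if (mirrored) cfg$groups[1] else cfg$groups
  graphs <- list()
  for (i in seq_along(gen_groups)) {
    ge <- cfg$group_effect[[gen_groups[i]]]
    graphs[[gen_groups[i]]] <- make_group_network(
      world, ge[["edge_deletion_frac"]], ge[["rewire_frac"]],
      seed = seeds[2] + i
    )
  }

  exemplars <- igraph::V(world)$name
  intr_pool <- c(sprintf("object%02d", 1:8), sprintf("beast%02d", 1:4))
  intr_status <- rep(c("non_category", "fictional"), c(8, 4))

  rows <- list()
  cov_rows <- list()
  withr::with_seed(seeds[3], {
    for (grp in gen_groups) {
      ll <- cfg$list_length[[grp]]
      lens <- pmax(1, round(rnorm(cfg$n_per_group, ll[["mean"]], ll[["sd"]])))
      lens <- pmin(lens, cfg$v)
      z_len <- if (sd(lens) > 0) (lens - mean(lens)) / sd(lens) else rep(0, length(lens))
      ses_p <- cfg$ses[[grp]]
      nvi_p <- cfg$nvi[[grp]]
      rho <- cfg$nvi_length_cor
      ses_v <- pmin(100, pmax(0, rnorm(cfg$n_per_group, ses_p[["mean"]],
                                       ses_p[["sd"]])))
      nvi_v <- pmin(100, pmax(0, nvi_p[["mean"]] + nvi_p[["sd"]] *
                                   (rho * z_len +
                                      sqrt(1 - rho^2) * rnorm(cfg$n_per_group))))
      adjg <- graphs[[grp]]
      for (i in seq_len(cfg$n_per_group)) {
        id <- sprintf("%s%02d", tolower(grp), i)
        tokens <- simulate_participant(adjg, lens[i], cfg$jump_prob)
        raw <- inject_noise(tokens, cfg$noise, intr_pool)
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = id, group = grp,
          position = seq_along(raw), response = raw
        )
        cov_rows[[length(cov_rows) + 1]] <- tibble::tibble(
          participant_id = id, group = grp, ses = ses_v[i], nvi = nvi_v[i],
          true_length = lens[i]
        )
      }
    }
  })
  fluency <- dplyr::bind_rows(rows)
  covariates <- dplyr::bind_rows(cov_rows)

  if (mirrored) {
    twin <- function(x) {
      x$participant_id <- sub(paste0("^", tolower(cfg$groups[1])), "m",
                              x$participant_id)
      x$group <- cfg$groups[2]
      x
    }
    fluency <- dplyr::bind_rows(fluency, twin(fluency))
    covariates <- dplyr::bind_rows(covariates, twin(covariates))
  }

  lex <- lexicon(
    raw = c(exemplars, paste0(exemplars, "q"), intr_pool),
    canonical = c(exemplars, exemplars, intr_pool),
    status = c(rep("ok", 2 * length(exemplars)), intr_status)
  )
  out <- list(
    fluency = fluency,
    covariates = covariates,
    lexicon = lex,
    truth = list(
      config = cfg, seeds = seeds, mirrored = mirrored,
      world = igraph::as_edgelist(world),
      group_graphs = lapply(graphs, igraph::as_edgelist)
    )
  )
  class(out) <- "fluenet_cohort"
  out
}

# surface-noise injection: perseverations re-emit an earlier token,
# intrusions come from the out-of-category pool, misspellings swap an
# exemplar for a plural ("<w>s", recovered by rule) or typo ("<w>q",
# covered by the lexicon) variant
inject_noise <- function(tokens, noise, intr_pool) {
  raw <- tokens
  mis <- runif(length(raw)) < noise[["misspelling_rate"]]
  plural <- runif(length(raw)) < 0.5
  raw[mis & plural] <- paste0(raw[mis & plural], "s")
  raw[mis & !plural] <- paste0(raw[mis & !plural], "q")
  out <- character(0)
  for (i in seq_along(raw)) {
    out <- c(out, raw[i])
    if (i >= 2 && runif(1) < noise[["perseveration_rate"]]) {
      out <- c(out, out[sample.int(length(out) - 1, 1)])
    }
    if (runif(1) < noise[["intrusion_rate"]]) {
      out <- c(out, intr_pool[sample.int(length(intr_pool), 1)])
    }
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits `fluency.csv` (long format), `covariates.csv`, `lexicon.csv`
#' and `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$fluency, file.path(dir, "fluency.csv"))
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  write_lexicon(cohort$lexicon, file.path(dir, "lexicon.csv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
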