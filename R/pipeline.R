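#' Format a significance count the way consistency reports read
#'
#' @param k significant runs.
#' @param n total runs.
#' @return e.g. `"70% (14/20)"`.
#' @examples
#' format_significance(14, 20)
#' @export
format_significance <- function(k, n) {
  stopifnot(k >= 0, k <= n, n >= 1)
  sprintf("%d%% (%d/%d)", round(100 * k / n), k, n)
}

#' Human-readable table of a harness report
#'
#' One row per coefficient x model with pooled per-group means (mean of
#' the per-repetition replicate means) and the `"x% (k/n)"` consistency
#' string.
#'
#' @param harness a [repeat_harness()] result.
#' @return tibble.
#' @export
summarize_harness <- function(harness) {
  stopifnot(inherits(harness, "fluenet_harness"))
  s <- harness$summary
  dplyr::transmute(
    s,
    coefficient = toupper(.data$coefficient),
    model = .data$model,
    mean_a = .data$mean_a,
    mean_b = .data$mean_b,
    significant = purrr::map2_chr(.data$n_significant, .data$n_runs,
                                  format_significance),
    direction = purrr::map_chr(.data$direction, function(d) {
      if (length(d) == 0) return("")
      paste(ifelse(d > 0, "b>a", "a>b"), collapse = ",")
    })
  )
}

#' Run the full analysis end to end
#'
#' Cleans the fluency lists, reports the descriptive group comparison,
#' runs the repeated case-wise bootstrap harness for the requested
#' models, and (optionally) serializes every product plus a reproducible
#' run manifest. The configuration is a named list, or a YAML/JSON file
#' holding one, with entries:
#'
#' * `fluency`, `covariates`, `lexicon`: input CSV paths — or
#'   `synthetic: true` plus an optional `world` list of
#'   [world_config()] arguments to generate a cohort instead;
#' * `n_boot`, `n_repeats`, `alpha`, `min_producers`, `models`:
#'   bootstrap settings (defaults 1000 / 20 / 0.05 / 2 / all three
#'   models);
#' * `master_seed`: the run's single seed.
#'
#' @param config list or path to a YAML/JSON config file.
#' @param out optional output directory.
#' @return (invisibly) list with `manifest`, `cleaned`, `counts`,
#'   `harness` and `summary`. The summary written to
#'   `summary.json` is byte-stable across reruns of the same config.
#' @export
run_full <- function(config, out = NULL) {
  t_start <- Sys.time()
  cfg <- load_run_config(config)
  timings <- list()
  tick <- function(stage, t0) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  t0 <- Sys.time()
  if (isTRUE(cfg$synthetic)) {
    wc <- do.call(world_config, c(cfg$world %||% list(),
                                  list(master_seed = cfg$master_seed)))
    cohort <- generate_cohort(wc, mirrored = isTRUE(cfg$mirrored))
    fluency <- cohort$fluency
    covariates <- cohort$covariates
    lex <- cohort$lexicon
    digests <- list(synthetic = TRUE)
  } else {
    fluency <- read_fluency(cfg$fluency, format = cfg$format %||% "long")
    covariates <- if (!is.null(cfg$covariates)) read_covariates(cfg$covariates)
    lex <- read_lexicon(cfg$lexicon)
    digests <- lapply(c(fluency = cfg$fluency, covariates = cfg$covariates,
                        lexicon = cfg$lexicon),
                      function(p) unname(tools::md5sum(p)))
  }
  tick("inputs", t0)

  t0 <- Sys.time()
  cleaned <- clean_fluency(fluency, lex)
  groups <- sort_lex(unique(cleaned$group))
  mats <- lapply(groups, function(g) {
    response_matrix(cleaned[cleaned$group == g, ])
  })
  counts <- fluency_count_summary(mats[[1]], mats[[2]])
  counts$group <- groups
  tick("preprocess", t0)

  t0 <- Sys.time()
  models <- cfg$models %||% c("unadjusted", "adjusted1", "adjusted2")
  if (is.null(covariates)) models <- "unadjusted"
  harness <- repeat_harness(
    cleaned, covariates,
    n_boot = cfg$n_boot %||% 1000,
    n_repeats = cfg$n_repeats %||% 20,
    alpha = cfg$alpha %||% 0.05,
    min_producers = cfg$min_producers %||% 2,
    master_seed = cfg$master_seed,
    models = models
  )
  tick("bootstrap", t0)

  summary_tbl <- summarize_harness(harness)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fluenet")),
    master_seed = cfg$master_seed,
    config = cfg[setdiff(names(cfg), "world")],
    input_digests = digests,
    groups = groups,
    timings_sec = timings,
    total_sec = as.numeric(Sys.time() - t_start, units = "secs")
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_cleaning_report(cleaned, file.path(out, "cleaning_report.json"))
    readr::write_csv(counts, file.path(out, "group_counts.csv"))
    readr::write_csv(harness$tests, file.path(out, "bootstrap_tests.csv"))
    jsonlite::write_json(
      list(groups = groups,
           summary = summary_tbl,
           config = list(n_boot = harness$config$n_boot,
                         n_repeats = harness$config$n_repeats,
                         alpha = harness$config$alpha,
                         master_seed = cfg$master_seed)),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(manifest = manifest, cleaned = cleaned, counts = counts,
                 harness = harness, summary = summary_tbl))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$master_seed)) config$master_seed <- 1L
  config$master_seed <- as.integer(config$master_seed)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
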