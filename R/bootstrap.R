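#' Case-wise bootstrap of two groups' semantic networks
#'
#' Each replicate resamples participants with replacement within each
#' group (same size as the original group, carrying their covariate
#' values), rebuilds the binary response matrix, finalizes it (exemplars
#' produced by at least `min_producers` resampled participants), equates
#' the two groups onto their shared exemplars, estimates each group's
#' TMFG network from the cosine association matrix, and computes ASPL,
#' CC and Q. Because the networks are equated and TMFG fixes the edge
#' count at `3n - 6`, both groups have identical node and edge counts in
#' every replicate, so coefficient differences reflect connectivity, not
#' size.
#'
#' Replicates whose equated node set falls below four are discarded and
#' redrawn with the next seed in the stream; more than 5% such failures
#' aborts with a diagnostic.
#'
#' @param cleaned output of [clean_fluency()] with exactly two group
#'   levels.
#' @param covariates optional tibble `participant_id, ses, nvi` (either
#'   covariate may be absent); required for adjusted models downstream.
#' @param n_boot number of replicates (study default 1000).
#' @param min_producers finalizing threshold (study default 2).
#' @param master_seed integer; the single source of randomness.
#' @return A tibble of class `fluenet_boot`, two rows (one per group)
#'   per replicate: `replicate, group, aspl, cc, q, n_nodes, n_edges,
#'   mean_n_cleaned, mean_ses, mean_nvi, seed`. Attributes record the
#'   group levels, failure count and configuration.
#' @export
run_bootstrap <- function(cleaned, covariates = NULL, n_boot = 1000,
                          min_producers = 2, master_seed = 1) {
  stopifnot(n_boot >= 1, min_producers >= 1)
  groups <- sort_lex(unique(cleaned$group))
  if (length(groups) != 2) stop("exactly two group levels required")
  pools <- lapply(groups, function(g) {
    rec <- cleaned[cleaned$group == g, ]
    inc <- response_matrix(rec)
    cov <- list(ses = NULL, nvi = NULL)
    if (!is.null(covariates)) {
      i <- match(rec$participant_id, covariates$participant_id)
      if ("ses" %in% names(covariates)) cov$ses <- covariates$ses[i]
      if ("nvi" %in% names(covariates)) cov$nvi <- covariates$nvi[i]
    }
    list(inc = inc, n = nrow(rec), n_cleaned = rec$n_cleaned,
         ses = cov$ses, nvi = cov$nvi)
  })
  names(pools) <- groups

  max_fail <- ceiling(0.05 * n_boot)
  seed_pool <- withr::with_seed(
    as.integer(master_seed),
    sample.int(.Machine$integer.max - 1L, 2L * (n_boot + max_fail + 2L))
  )
  rows <- vector("list", 2L * n_boot)
  attempt <- 0L
  failed <- 0L
  done <- 0L
  while (done < n_boot) {
    attempt <- attempt + 1L
    seeds <- seed_pool[c(2L * attempt - 1L, 2L * attempt)]
    rep_rows <- boot_replicate(pools, groups, min_producers, seeds,
                               replicate_id = done + 1L)
    if (is.null(rep_rows)) {
      failed <- failed + 1L
      if (failed > max_fail) {
        stop("bootstrap aborted: more than 5% of replicates had fewer ",
             "than 4 shared nodes after finalizing/equating")
      }
      next
    }
    rows[[2L * done + 1L]] <- rep_rows[[1]]
    rows[[2L * done + 2L]] <- rep_rows[[2]]
    done <- done + 1L
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "groups") <- groups
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- failed
  attr(out, "master_seed") <- master_seed
  attr(out, "min_producers") <- min_producers
  attr(out, "has_ses") <- !is.null(pools[[1]]$ses)
  attr(out, "has_nvi") <- !is.null(pools[[1]]$nvi)
  class(out) <- c("fluenet_boot", class(out))
  out
}

# one equated replicate; NULL when the shared node set is too small
boot_replicate <- function(pools, groups, min_producers, seeds, replicate_id) {
  idx <- list(
    withr::with_seed(seeds[1], sample.int(pools[[1]]$n, replace = TRUE)),
    withr::with_seed(seeds[2], sample.int(pools[[2]]$n, replace = TRUE))
  )
  sub <- lapply(1:2, function(k) pools[[k]]$inc[idx[[k]], , drop = FALSE])
  keep <- lapply(sub, function(m) colnames(m)[colSums(m) >= min_producers])
  shared <- sort_lex(intersect(keep[[1]], keep[[2]]))
  if (length(shared) < 4) return(NULL)
  lapply(1:2, function(k) {
    m <- sub[[k]][, shared, drop = FALSE]
    g <- tmfg(cosine_matrix(m), strict = TRUE)
    met <- network_metrics(g, seed = 0L)
    p <- pools[[k]]
    tibble::tibble(
      replicate = replicate_id,
      group = groups[k],
      aspl = met$aspl, cc = met$cc, q = met$q,
      n_nodes = met$n_nodes, n_edges = met$n_edges,
      mean_n_cleaned = mean(p$n_cleaned[idx[[k]]]),
      mean_ses = if (is.null(p$ses)) NA_real_ else mean(p$ses[idx[[k]]]),
      mean_nvi = if (is.null(p$nvi)) NA_real_ else mean(p$nvi[idx[[k]]]),
      seed = seeds[k]
    )
  })
}

model_covariates <- function(model) {
  switch(model,
    unadjusted = c("mean_n_cleaned", "n_edges"),
    adjusted1 = c("mean_n_cleaned", "n_edges", "mean_ses"),
    adjusted2 = c("mean_n_cleaned", "n_edges", "mean_ses", "mean_nvi"),
    stop("unknown model: ", model)
  )
}

#' Compare groups on one bootstrapped coefficient
#'
#' Fits a linear model across the `2 * n_boot` replicate observations:
#' `coefficient ~ group + covariates`, reporting the group effect
#' (second group level minus first), its t statistic and two-sided p.
#' The unadjusted model uses the replicate mean cleaned-response count
#' and the equated network's edge count as covariates; `adjusted1` adds
#' the replicate mean SES, `adjusted2` additionally the mean non-verbal
#' intelligence. Covariates that are constant (or collinear) across
#' replicates are dropped with a note; when none remain the comparison
#' reduces to Welch's two-sample t-test.
#'
#' Treating replicates as observations mirrors the referenced
#' semantic-network bootstrap pipeline; it is anticonservative when the
#' two groups are genuinely distinct samples (see the package vignette).
#'
#' @param res a `fluenet_boot` from [run_bootstrap()].
#' @param coefficient `"aspl"`, `"cc"` or `"q"`.
#' @param model `"unadjusted"`, `"adjusted1"` or `"adjusted2"`.
#' @return one-row tibble: `coefficient, model, group_a, group_b,
#'   mean_a, mean_b, estimate, statistic, df, p_value, dropped`.
#' @export
compare_boot <- function(res, coefficient = c("aspl", "cc", "q"),
                         model = c("unadjusted", "adjusted1", "adjusted2")) {
  coefficient <- match.arg(coefficient)
  model <- match.arg(model)
  covs <- model_covariates(model)
  if (model != "unadjusted") {
    need <- setdiff(covs, c("mean_n_cleaned", "n_edges"))
    if (any(vapply(need, function(v) all(is.na(res[[v]])), logical(1)))) {
      stop("adjusted model requires participant covariates (ses/nvi)")
    }
  }
  groups <- attr(res, "groups")
  d <- tibble::tibble(
    value = res[[coefficient]],
    group = factor(res$group, levels = groups)
  )
  for (v in covs) d[[v]] <- res[[v]]
  if (var(d$value) == 0) stop("zero variance in ", coefficient)

  dropped <- character(0)
  for (v in covs) {
    if (var(d[[v]]) < 1e-12) {
      dropped <- c(dropped, v)
      d[[v]] <- NULL
    }
  }
  kept <- setdiff(covs, dropped)
  m_a <- mean(d$value[d$group == groups[1]])
  m_b <- mean(d$value[d$group == groups[2]])

  if (length(kept) == 0) {
    tt <- t.test(value ~ group, data = d)  # Welch
    est <- m_b - m_a
    stat <- -unname(tt$statistic)  # t.test is level1 - level2
    dfree <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    fit <- lm(value ~ ., data = d)
    cf <- coef(fit)
    if (anyNA(cf)) {
      bad <- intersect(names(cf)[is.na(cf)], kept)
      warning("dropping collinear covariate(s): ",
              paste(bad, collapse = ", "),
              " (condition number ", format(kappa(fit), digits = 3), ")")
      dropped <- c(dropped, bad)
      d[bad] <- NULL
      fit <- lm(value ~ ., data = d)
    }
    sm <- summary(fit)$coefficients
    grow <- paste0("group", groups[2])
    est <- sm[grow, "Estimate"]
    stat <- sm[grow, "t value"]
    dfree <- fit$df.residual
    p <- sm[grow, "Pr(>|t|)"]
  }
  tibble::tibble(
    coefficient = coefficient, model = model,
    group_a = groups[1], group_b = groups[2],
    mean_a = m_a, mean_b = m_b,
    estimate = unname(est), statistic = unname(stat),
    df = dfree, p_value = unname(p),
    dropped = paste(dropped, collapse = ";")
  )
}

#' All coefficient-by-model comparisons of one bootstrap run
#'
#' @inheritParams compare_boot
#' @param models character vector of models to fit.
#' @return tibble with one row per coefficient x model.
#' @export
compare_all <- function(res, models = c("unadjusted", "adjusted1", "adjusted2")) {
  grid <- tidyr::expand_grid(coefficient = c("aspl", "cc", "q"),
                             model = models)
  purrr::pmap(grid, function(coefficient, model) {
    compare_boot(res, coefficient, model)
  }) |> dplyr::bind_rows()
}

#' Repeated-bootstrap consistency harness
#'
#' Bootstrapping small samples can over-represent outliers, so the full
#' bootstrap comparison is repeated `n_repeats` times (study default 20)
#' with independent replicate streams, and the proportion of repetitions
#' in which each coefficient differs significantly between groups is
#' reported, per model, together with the direction of each significant
#' difference.
#'
#' @inheritParams run_bootstrap
#' @param n_repeats number of independent bootstrap analyses.
#' @param alpha two-sided significance threshold.
#' @param models which comparison models to run (adjusted models need
#'   `covariates`).
#' @param keep_replicates keep every replicate row of every repeat
#'   (memory; default `FALSE` keeps the test records only).
#' @return object of class `fluenet_harness`: list with `tests` (one row
#'   per repeat x coefficient x model), `summary` (per coefficient x
#'   model: significant count/proportion, directions, pooled group
#'   means), `replicates` (when kept) and `config`.
#' @export
repeat_harness <- function(cleaned, covariates = NULL, n_boot = 1000,
                           n_repeats = 20, alpha = 0.05, min_producers = 2,
                           master_seed = 1,
                           models = c("unadjusted", "adjusted1", "adjusted2"),
                           keep_replicates = FALSE) {
  stopifnot(n_repeats >= 1, alpha > 0, alpha < 1)
  run_seeds <- withr::with_seed(
    as.integer(master_seed),
    sample.int(.Machine$integer.max - 1L, n_repeats)
  )
  tests <- vector("list", n_repeats)
  reps <- if (keep_replicates) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    res <- run_bootstrap(cleaned, covariates, n_boot = n_boot,
                         min_producers = min_producers,
                         master_seed = run_seeds[r])
    tests[[r]] <- dplyr::mutate(compare_all(res, models), run = r,
                                .before = 1)
    if (keep_replicates) {
      reps[[r]] <- dplyr::mutate(tibble::as_tibble(res), run = r, .before = 1)
    }
  }
  tests <- dplyr::bind_rows(tests)
  summary <- tests |>
    dplyr::group_by(.data$coefficient, .data$model) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      n_significant = sum(.data$p_value < alpha),
      prop_significant = mean(.data$p_value < alpha),
      # direction recorded for significant runs only: +1 means the
      # second group level has the larger coefficient
      direction = list(sign(.data$estimate[.data$p_value < alpha])),
      mean_a = mean(.data$mean_a),
      mean_b = mean(.data$mean_b),
      .groups = "drop"
    )
  out <- list(
    tests = tests,
    summary = summary,
    replicates = if (keep_replicates) dplyr::bind_rows(reps) else NULL,
    config = list(n_boot = n_boot, n_repeats = n_repeats, alpha = alpha,
                  min_producers = min_producers, master_seed = master_seed,
                  models = models,
                  groups = sort_lex(unique(cleaned$group)))
  )
  class(out) <- "fluenet_harness"
  out
}

#' @export
print.fluenet_harness <- function(x, ...) {
  cfg <- x$config
  cat("Case-wise bootstrap harness: ", cfg$n_repeats, " x ", cfg$n_boot,
      " replicates, groups ", paste(cfg$groups, collapse = " vs "),
      "\n\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-4s %-10s  M_%s = %.3f vs M_%s = %.3f  significant %s\n",
                toupper(s$coefficient[i]), s$model[i],
                cfg$groups[1], s$mean_a[i], cfg$groups[2], s$mean_b[i],
                format_significance(s$n_significant[i], s$n_runs[i])))
  }
  invisible(x)
}
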