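# small, fast cohort for bootstrap unit tests
boot_fixture <- function(seed = 13, mirrored = FALSE) {
  coh <- generate_cohort(world_config(n_per_group = 15, master_seed = seed),
                         mirrored = mirrored)
  list(cleaned = clean_fluency(coh$fluency, coh$lexicon),
       covariates = coh$covariates)
}

test_that("bootstrap results are bit-identical given the master seed", {
  fx <- boot_fixture()
  r1 <- run_bootstrap(fx$cleaned, fx$covariates, n_boot = 8, master_seed = 4)
  r2 <- run_bootstrap(fx$cleaned, fx$covariates, n_boot = 8, master_seed = 4)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  r3 <- run_bootstrap(fx$cleaned, fx$covariates, n_boot = 8, master_seed = 5)
  expect_false(identical(r1$aspl, r3$aspl))
})

test_that("within every replicate the equated groups share nodes and edges", {
  fx <- boot_fixture()
  res <- run_bootstrap(fx$cleaned, fx$covariates, n_boot = 12, master_seed = 6)
  wide <- tidyr::pivot_wider(tibble::as_tibble(res)[c("replicate", "group",
                                                      "n_nodes", "n_edges")],
                             names_from = "group",
                             values_from = c("n_nodes", "n_edges"))
  expect_equal(wide$n_nodes_A, wide$n_nodes_B)
  expect_equal(wide$n_edges_A, wide$n_edges_B)
  expect_equal(wide$n_edges_A, 3 * wide$n_nodes_A - 6)
  # coefficient distributions are non-degenerate
  expect_gt(var(res$aspl), 0)
  expect_gt(var(res$cc), 0)
})

test_that("identical groups resampled with the same seed give identical coefficients", {
  fx <- boot_fixture(mirrored = TRUE)
  pools <- lapply(c("A", "B"), function(g) {
    rec <- fx$cleaned[fx$cleaned$group == g, ]
    list(inc = response_matrix(rec), n = nrow(rec),
         n_cleaned = rec$n_cleaned, ses = NULL, nvi = NULL)
  })
  rows <- fluenet:::boot_replicate(pools, c("A", "B"), 2,
                                   seeds = c(99L, 99L), replicate_id = 1L)
  expect_equal(rows[[1]]$aspl, rows[[2]]$aspl)
  expect_equal(rows[[1]]$cc, rows[[2]]$cc)
  expect_equal(rows[[1]]$q, rows[[2]]$q)
})

# build a synthetic fluenet_boot object with known structure
fake_boot <- function(n_boot, delta = 0, seed = 1, ses_b_shift = 0) {
  withr::with_seed(seed, {
    base <- rnorm(n_boot, 3.2, 0.1)
    tibble::tibble(
      replicate = rep(seq_len(n_boot), each = 2),
      group = rep(c("A", "B"), n_boot),
      aspl = as.vector(rbind(base, base + delta + rnorm(n_boot, 0, 0.05))),
      cc = rnorm(2 * n_boot, 0.7, 0.01),
      q = rnorm(2 * n_boot, 0.6, 0.01),
      n_nodes = rep(60L, 2 * n_boot),
      n_edges = rep(174L, 2 * n_boot),
      mean_n_cleaned = rnorm(2 * n_boot, 15, 0.5),
      mean_ses = rnorm(2 * n_boot, 58, 2) +
        rep(c(0, ses_b_shift), n_boot),
      mean_nvi = rnorm(2 * n_boot, 70, 2),
      seed = seq_len(2 * n_boot)
    )
  }) -> d
  attr(d, "groups") <- c("A", "B")
  attr(d, "n_boot") <- n_boot
  attr(d, "n_failed") <- 0L
  class(d) <- c("fluenet_boot", class(d))
  d
}

test_that("a known group shift is recovered by the unadjusted model", {
  d <- fake_boot(200, delta = 0.3)
  # n_edges is constant, dropped with a note; mean_n_cleaned is noise
  r <- compare_boot(d, "aspl", "unadjusted")
  expect_equal(r$estimate, 0.3, tolerance = 0.05)
  expect_lt(r$p_value, 1e-10)
  expect_match(r$dropped, "n_edges")
})

test_that("group label swap flips the estimate and keeps the magnitude", {
  d <- fake_boot(100, delta = 0.25)
  swapped <- d
  swapped$group <- ifelse(d$group == "A", "B", "A")
  r1 <- compare_boot(d, "aspl", "unadjusted")
  r2 <- compare_boot(swapped, "aspl", "unadjusted")
  expect_equal(r1$estimate, -r2$estimate)
  expect_equal(abs(r1$statistic), abs(r2$statistic))
  expect_equal(r1$p_value, r2$p_value)
})

test_that("constant covariates drop to Welch's t-test; adding one changes nothing", {
  d <- fake_boot(100, delta = 0.2)
  d$mean_n_cleaned <- 15          # now every covariate is constant
  r <- compare_boot(d, "aspl", "unadjusted")
  expect_setequal(strsplit(r$dropped, ";")[[1]],
                  c("mean_n_cleaned", "n_edges"))
  tt <- t.test(aspl ~ group, data = d)
  expect_equal(r$statistic, -unname(tt$statistic))
  expect_equal(r$p_value, tt$p.value)

  # a constant extra covariate leaves the adjusted estimate at the
  # unadjusted value
  d2 <- fake_boot(100, delta = 0.2)
  d2$mean_ses <- 58
  r_u <- compare_boot(d2, "aspl", "unadjusted")
  r_a <- compare_boot(d2, "aspl", "adjusted1")
  expect_equal(r_a$estimate, r_u$estimate)
})

test_that("a covariate uncorrelated with group leaves the estimate unchanged", {
  d <- fake_boot(300, delta = 0.2)
  r_u <- compare_boot(d, "aspl", "unadjusted")
  r_a <- compare_boot(d, "aspl", "adjusted2")
  expect_equal(r_a$estimate, r_u$estimate, tolerance = 0.05)
})

test_that("collinear covariates are dropped with a warning", {
  d <- fake_boot(100, delta = 0.2)
  d$mean_nvi <- d$mean_ses        # exactly collinear
  expect_warning(r <- compare_boot(d, "aspl", "adjusted2"), "collinear")
  expect_match(r$dropped, "mean_nvi")
  expect_true(is.finite(r$statistic))
})

test_that("adjusted models demand covariates and degenerate outcomes error", {
  fx <- boot_fixture()
  res <- run_bootstrap(fx$cleaned, covariates = NULL, n_boot = 5,
                       master_seed = 7)
  expect_error(compare_boot(res, "aspl", "adjusted1"), "covariates")
  d <- fake_boot(50)
  d$q <- 0.6
  expect_error(compare_boot(d, "q"), "zero variance")
})

test_that("the harness reports proportions and directions per model", {
  fx <- boot_fixture()
  h <- repeat_harness(fx$cleaned, fx$covariates, n_boot = 6, n_repeats = 3,
                      master_seed = 8)
  expect_s3_class(h, "fluenet_harness")
  expect_equal(nrow(h$tests), 3 * 3 * 3)  # runs x coefficients x models
  expect_equal(nrow(h$summary), 9)
  expect_true(all(h$summary$prop_significant >= 0 &
                    h$summary$prop_significant <= 1))
  expect_true(all(h$summary$n_runs == 3))
  # n_repeats = 1 gives proportions in {0, 1}
  h1 <- repeat_harness(fx$cleaned, fx$covariates, n_boot = 6, n_repeats = 1,
                       master_seed = 9, models = "unadjusted")
  expect_true(all(h1$summary$prop_significant %in% c(0, 1)))
  # determinism of the full report
  h2 <- repeat_harness(fx$cleaned, fx$covariates, n_boot = 6, n_repeats = 3,
                       master_seed = 8)
  expect_identical(h$tests, h2$tests)
})

test_that("type-I error on identically-generated groups is near alpha", {
  # mirrored null: both groups are the same records, so replicate
  # distributions coincide and the replicate-level test is calibrated
  fx <- boot_fixture(seed = 41, mirrored = TRUE)
  h <- repeat_harness(fx$cleaned, fx$covariates, n_boot = 30, n_repeats = 200,
                      master_seed = 10, models = "unadjusted")
  prop <- h$summary$prop_significant[h$summary$coefficient == "aspl"]
  expect_gte(prop, 0.01)
  expect_lte(prop, 0.12)
})

test_that("tidy, glance and autoplot methods work on bootstrap objects", {
  fx <- boot_fixture()
  res <- run_bootstrap(fx$cleaned, fx$covariates, n_boot = 6, master_seed = 11)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
  gl <- glance(res)
  expect_equal(gl$n_boot, 6)
  expect_s3_class(autoplot(res), "ggplot")

  h <- repeat_harness(fx$cleaned, fx$covariates, n_boot = 6, n_repeats = 2,
                      master_seed = 12, models = "unadjusted")
  expect_equal(nrow(tidy(h)), 6)
  expect_equal(glance(h)$n_repeats, 2)
  expect_s3_class(autoplot(h), "ggplot")
  expect_output(print(h), "Case-wise bootstrap harness")
})
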