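#' Welch's t-test from group summary statistics
#'
#' `t = |m2 - m1| / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p value. Works from published
#' summary statistics, so reported group tables can be checked without
#' raw data. The statistic is reported as a magnitude, matching the
#' convention of demographic comparison tables.
#'
#' @param stats two-row tibble/data.frame with columns `mean`, `sd`,
#'   `n` (one row per group; an optional `group` column labels them).
#' @return one-row tibble `statistic, df, p_value`.
#' @examples
#' welch_t(tibble::tibble(mean = c(13.05, 17.92),
#'                        sd = c(3.48, 5.16), n = c(38, 38)))
#' @export
welch_t <- function(stats) {
  stats <- check_summary(stats)
  v1 <- stats$sd[1]^2 / stats$n[1]
  v2 <- stats$sd[2]^2 / stats$n[2]
  if (v1 + v2 == 0) stop("zero variance in both groups")
  t <- abs(stats$mean[2] - stats$mean[1]) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (stats$n[1] - 1) + v2^2 / (stats$n[2] - 1))
  tibble::tibble(statistic = t, df = df, p_value = 2 * pt(-t, df))
}

#' Pearson chi-squared and phi on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction), 1 degree of freedom;
#' `phi = sqrt(chi2 / N)`.
#'
#' @param tab 2x2 matrix or data.frame of non-negative counts
#'   (group x trait).
#' @return one-row tibble `chi2, df, p_value, phi`.
#' @examples
#' pearson_chi2(rbind(c(18, 20), c(11, 26)))  # chi2 ~ 2.46, phi ~ 0.18
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty contingency table")
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  tibble::tibble(chi2 = chi2, df = 1,
                 p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 phi = sqrt(chi2 / n))
}

#' Cohen's d from group summary statistics
#'
#' Pooled-SD standardized mean difference, reported as a magnitude.
#' With equal group sizes the pooled SD is `sqrt((s1^2 + s2^2) / 2)`;
#' otherwise the (n-1)-weighted pooled SD is used.
#'
#' @inheritParams welch_t
#' @return numeric d (unsigned).
#' @examples
#' cohens_d(tibble::tibble(mean = c(58.6, 59), sd = c(25.1, 18.1),
#'                         n = c(38, 38)))  # ~ 0.02
#' @export
cohens_d <- function(stats) {
  stats <- check_summary(stats)
  s <- if (stats$n[1] == stats$n[2]) {
    sqrt((stats$sd[1]^2 + stats$sd[2]^2) / 2)
  } else {
    sqrt(((stats$n[1] - 1) * stats$sd[1]^2 + (stats$n[2] - 1) * stats$sd[2]^2) /
           (stats$n[1] + stats$n[2] - 2))
  }
  if (s == 0) stop("zero pooled SD")
  abs(stats$mean[2] - stats$mean[1]) / s
}

check_summary <- function(stats) {
  stats <- tibble::as_tibble(stats)
  stopifnot(nrow(stats) == 2, all(c("mean", "sd", "n") %in% names(stats)),
            all(stats$sd >= 0), all(stats$n >= 2))
  stats
}

#' Descriptive fluency-count comparison of two groups
#'
#' The vocabulary-size and diversity quantities reported alongside a
#' group network comparison: per group, the mean and SD of cleaned
#' responses per participant, the number of distinct exemplars, the
#' number produced by only one child, and the number absent from the
#' other group; plus the pooled distinct-exemplar count.
#'
#' @param m_a,m_b response matrices of the two groups (built with the
#'   same lexicon, before finalizing).
#' @return one-row-per-group tibble plus attribute `"pooled_unique"`.
#' @export
fluency_count_summary <- function(m_a, m_b) {
  per_group <- function(m, other) {
    rs <- rowSums(m)
    cs <- colSums(m)
    tibble::tibble(
      n_participants = nrow(m),
      mean_responses = mean(rs),
      sd_responses = sd(rs),
      unique_responses = ncol(m),
      singleton_responses = sum(cs == 1),
      exclusive_responses = length(setdiff(colnames(m), colnames(other)))
    )
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(per_group(m_a, m_b), group = "a", .before = 1),
    dplyr::mutate(per_group(m_b, m_a), group = "b", .before = 1)
  )
  attr(out, "pooled_unique") <- length(union(colnames(m_a), colnames(m_b)))
  out
}
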