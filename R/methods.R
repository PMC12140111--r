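#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bootstrap result
#'
#' @param x a `fluenet_boot`.
#' @param ... unused.
#' @return the replicate-level tibble (two rows per replicate).
#' @export
tidy.fluenet_boot <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-line summary of a bootstrap result
#'
#' @param x a `fluenet_boot`.
#' @param ... unused.
#' @return one-row tibble: replicate count, failures, per-group
#'   coefficient means and the (replicate-wise constant-by-design)
#'   node/edge agreement.
#' @export
glance.fluenet_boot <- function(x, ...) {
  groups <- attr(x, "groups")
  d <- tibble::as_tibble(x)
  means <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(c("aspl", "cc", "q"), mean),
                     .groups = "drop")
  tibble::tibble(
    n_boot = attr(x, "n_boot"),
    n_failed = attr(x, "n_failed"),
    group_a = groups[1], group_b = groups[2],
    aspl_a = means$aspl[means$group == groups[1]],
    aspl_b = means$aspl[means$group == groups[2]],
    cc_a = means$cc[means$group == groups[1]],
    cc_b = means$cc[means$group == groups[2]],
    q_a = means$q[means$group == groups[1]],
    q_b = means$q[means$group == groups[2]],
    mean_n_nodes = mean(d$n_nodes)
  )
}

#' Tidy a harness report
#'
#' @param x a `fluenet_harness`.
#' @param ... unused.
#' @return the per-run test records (run x coefficient x model).
#' @export
tidy.fluenet_harness <- function(x, ...) x$tests

#' One-line summary of a harness report
#'
#' @param x a `fluenet_harness`.
#' @param ... unused.
#' @export
glance.fluenet_harness <- function(x, ...) {
  tibble::tibble(
    n_repeats = x$config$n_repeats,
    n_boot = x$config$n_boot,
    alpha = x$config$alpha,
    n_models = length(x$config$models)
  )
}

#' Replicate-distribution plot of a bootstrap result
#'
#' Violin + median point of each coefficient's replicate distribution,
#' by group.
#'
#' @param object a `fluenet_boot`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fluenet_boot <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("aspl", "cc", "q"),
                        names_to = "coefficient", values_to = "value") |>
    dplyr::mutate(coefficient = toupper(.data$coefficient))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          show.legend = FALSE) +
    ggplot2::facet_wrap(~coefficient, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "bootstrap replicate value")
}

#' Consistency plot of a harness report
#'
#' Proportion of repetitions significant at alpha, per coefficient and
#' model.
#'
#' @param object a `fluenet_harness`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fluenet_harness <- function(object, ...) {
  s <- object$summary |>
    dplyr::mutate(coefficient = toupper(.data$coefficient))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$coefficient,
                                  y = .data$prop_significant,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$config$alpha, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion of significant repetitions",
                  fill = NULL)
}
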