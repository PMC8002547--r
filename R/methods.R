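#' Tidy posterior summaries of a Gibbs fit
#'
#' @param x A `twin_gibbs` object.
#' @param ... Unused.
#' @return One row per variance component: posterior mean, SD, 90% credible
#'   interval, effective sample size.
#' @export
tidy.twin_gibbs <- function(x, ...) {
  comps <- c("sigma2_a", "sigma2_pe", "sigma2_hys")
  purrr::map(comps, function(k) {
    draws <- x$chains[[k]]
    tibble(term = k,
           estimate = mean(draws),
           std.error = sd(draws),
           conf.low = unname(quantile(draws, 0.05)),
           conf.high = unname(quantile(draws, 0.95)),
           ess = unname(x$ess[[k]]))
  }) |> bind_rows()
}

#' One-row summary of a Gibbs fit
#'
#' @inheritParams tidy.twin_gibbs
#' @return Tibble with `h2`, `r2` (posterior means of the ratios), their
#'   credible bounds, chain settings, and the minimum effective sample size.
#' @export
glance.twin_gibbs <- function(x, ...) {
  tibble(h2 = mean(x$h2_draws),
         h2.conf.low = unname(quantile(x$h2_draws, 0.05)),
         h2.conf.high = unname(quantile(x$h2_draws, 0.95)),
         r2 = mean(x$r2_draws),
         n_iter = x$config$n_iter,
         burn_in = x$config$burn_in,
         min_ess = min(x$ess))
}

#' Trace plots of the variance-component chains
#'
#' @param object A `twin_gibbs` object.
#' @param ... Unused.
#' @return A ggplot of the post-burn-in variance draws by iteration.
#' @export
autoplot.twin_gibbs <- function(object, ...) {
  long <- tidyr::pivot_longer(object$chains, -"iteration",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = "variance draw") +
    ggplot2::theme_minimal()
}

#' @rdname animal_solutions
#' @param x A `twin_solutions` object.
#' @param ... Unused.
#' @export
tidy.twin_solutions <- function(x, ...) x$solutions

#' @rdname animal_solutions
#' @export
glance.twin_solutions <- function(x, ...) {
  tibble(mode = x$mode, n_equations = nrow(x$solutions),
         pcg_rounds = x$pcg_rounds, outer_iterations = x$outer_iterations,
         rel_residual = x$rel_residual)
}

#' Tidy the per-group marginal means of an incidence fit
#'
#' @param x A `twin_incidence_fit` object.
#' @param ... Unused.
#' @export
tidy.twin_incidence_fit <- function(x, ...) as_tibble(x)

#' @rdname tidy.twin_incidence_fit
#' @export
glance.twin_incidence_fit <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$herd_id) |>
    summarise(p_value = first(.data$p_value),
              any_separation = any(.data$separation), .groups = "drop")
}

#' Incidence by genetic group, per herd
#'
#' @param object A `twin_incidence_fit` object.
#' @param ... Unused.
#' @return A ggplot of marginal-mean twinning incidence (with +/-1 SEM
#'   bars) for each tertile group within each herd.
#' @export
autoplot.twin_incidence_fit <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$incidence)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$incidence - .data$sem,
                                        ymax = .data$incidence + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~herd_id) +
    ggplot2::labs(x = "STA genetic group", y = "twinning incidence") +
    ggplot2::theme_minimal()
}

#' STA distribution of a scored evaluation
#'
#' @param object A `twin_scores` tibble from [score_animals()].
#' @param ... Unused.
#' @return A ggplot histogram of unrounded STAs with the scaling-cohort
#'   mean marked.
#' @export
autoplot.twin_scores <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$sta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 100, linetype = 2) +
    ggplot2::labs(x = "standardized transmitting ability",
                  y = "animals") +
    ggplot2::theme_minimal()
}
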