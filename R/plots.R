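# ggplot2 visualisations for the main result types

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_ribbon
#'   geom_errorbar geom_function labs scale_y_log10 theme_minimal
NULL

#' Plot an extinction-time distribution
#'
#' @param object A `moran_extinction`.
#' @param generations Plot the x axis in generations (events / N) rather
#'   than event steps.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moran_extinction <- function(object, generations = TRUE, ...) {
  d <- tidy(object)
  if (generations) {
    ggplot(d, aes(x = .data$generations, y = .data$probability * object$spec$N)) +
      geom_line() +
      labs(x = "extinction time (generations)", y = "probability density",
           title = sprintf("Moran extinction times (N = %d, fc = %.2g, fe = %.2g)",
                           object$spec$N, object$spec$fc, object$spec$fe)) +
      theme_minimal()
  } else {
    ggplot(d, aes(x = .data$step, y = .data$probability)) +
      geom_line() +
      labs(x = "event step", y = "probability") +
      theme_minimal()
  }
}

#' Plot a Wright-Fisher trajectory
#'
#' Per-generation ancestor and total mutant counts.
#'
#' @param object A `wf_result` run with `totals_every > 0`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wf_result <- function(object, ...) {
  if (!nrow(object$totals)) {
    abort("No totals recorded; rerun with `totals_every > 0`.")
  }
  d <- tidyr::pivot_longer(object$totals, c("ancestor", "mutants"),
                           names_to = "type", values_to = "count")
  ggplot(d, aes(x = .data$generation, y = .data$count, colour = .data$type)) +
    geom_line() +
    labs(x = "generation", y = "individuals", colour = NULL) +
    theme_minimal()
}

#' Plot a binned extinction-time curve against the closed-form approximation
#'
#' @param curve Output of [wf_extinction_curve()].
#' @param overlay_approx Overlay `tau_approx(fe)`?
#' @param ... Unused.
#' @return A ggplot (log-scaled y).
#' @export
plot_extinction_curve <- function(curve, overlay_approx = TRUE, ...) {
  p <- ggplot(curve, aes(x = .data$fe_mid, y = .data$mean_tau)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_tau - .data$se_tau,
                      ymax = .data$mean_tau + .data$se_tau), width = 0) +
    scale_y_log10() +
    labs(x = "ecological fitness fe", y = "mean extinction time (generations)") +
    theme_minimal()
  if (overlay_approx) {
    p <- p + geom_function(fun = tau_approx, colour = "red",
                           xlim = c(min(curve$fe_mid), min(0.995, max(curve$fe_mid))))
  }
  p
}

#' Plot a stationary mutant-fitness histogram against theory
#'
#' @param hist Output of [wf_stationary_fe()].
#' @param mu Mutation probability of the run (for the theoretical overlay).
#' @param dee The DEE used (for the theoretical overlay); `NULL` to skip.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_stationary_fe <- function(hist, mu = NULL, dee = NULL, ...) {
  p <- ggplot(hist, aes(x = .data$mid, y = .data$density)) +
    geom_col(width = diff(hist$bin_lo[1:2]) * 0.9, fill = "grey70") +
    labs(x = "ecological fitness fe", y = "stationary density") +
    theme_minimal()
  if (!is.null(mu) && !is.null(dee)) {
    xs <- hist$mid[hist$mid < 1]
    th <- stationary_density(xs, mu, dee)
    th <- th / sum(th * diff(hist$bin_lo[1:2]))
    p <- p + geom_line(data = tibble(mid = xs, density = th), colour = "red")
  }
  p
}

#' Plot a game-assay fit
#'
#' Relative mutant growth rate against initial ancestor fraction with the
#' fitted frequency-dependence line; the ancestor reference (fitness 1) is
#' shown dashed.
#'
#' @param object A `game_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.game_fit <- function(object, ...) {
  d <- mutate(object$wells, rel = .data$mutant / object$ref_rate)
  ggplot(d, aes(x = .data$initial_ancestor_fraction, y = .data$rel)) +
    geom_point() +
    ggplot2::geom_abline(intercept = object$fi_hat,
                         slope = object$fe_hat - object$fi_hat) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "initial ancestor fraction", y = "relative mutant growth rate") +
    theme_minimal()
}
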