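#' Plot a Lorenz curve of trophallactic activity
#'
#' @param counts Per-ant event counts (see [lorenz_gini()]).
#' @return A ggplot: the Lorenz curve with the perfect-equality diagonal
#'   and the Gini coefficient in the subtitle.
#' @export
plot_lorenz <- function(counts) {
  lg <- lorenz_gini(counts)
  ggplot2::ggplot(lg$lorenz, ggplot2::aes(x = .data$p, y = .data$L)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "cumulative share of workers (least to most active)",
      y = "cumulative share of trophallactic events",
      subtitle = sprintf("Gini = %.3f", lg$gini)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cumulative number of trophallactic events over time
#'
#' @param sim A `troph_sim`.
#' @return A ggplot of the cumulative event count against time, with the
#'   T50 marked.
#' @export
plot_cumulative_events <- function(sim) {
  stopifnot(inherits(sim, "troph_sim"))
  if (nrow(sim$events) == 0) stop("no events to plot", call. = FALSE)
  df <- tibble::tibble(t = sort(sim$events$t_start),
                       cumulative = seq_len(nrow(sim$events)))
  half <- t50(sim$events)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = half, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "cumulative trophallactic events",
                  subtitle = sprintf("T50 = %d s", as.integer(half))) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of per-ant activity
#'
#' @param sim A `troph_sim`.
#' @return A ggplot of histograms of per-ant event counts for the five
#'   activity categories (see [activity_distributions()]).
#' @export
plot_activity_distributions <- function(sim) {
  stopifnot(inherits(sim, "troph_sim"))
  df <- activity_distributions(sim$events, sim$ants[, c("id", "caste")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5,
                            fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~distribution, scales = "free_y") +
    ggplot2::labs(x = "trophallactic events per ant", y = "workers") +
    ggplot2::theme_minimal()
}

#' @describeIn run_simulation `autoplot()` draws the cumulative event
#'   curve.
#' @param object A `troph_sim`.
#' @export
autoplot.troph_sim <- function(object, ...) plot_cumulative_events(object)

#' @describeIn run_ensemble `autoplot()` shows the distribution of event
#'   counts across replicates.
#' @param object A `troph_ensemble`.
#' @export
autoplot.troph_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$summaries, ggplot2::aes(x = .data$n_events)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::labs(x = "trophallactic events per replicate", y = "replicates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
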