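#' Plot benefit, cost and total-benefit curves
#'
#' @param object An `rrsat_curves` tibble from [benefit_curves()].
#' @param ... Unused.
#' @return A ggplot: the three curves against adjustment step, with the peak
#'   step marked.
#' @export
autoplot.rrsat_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t", "think_benefit",
                  "think_cost", "total_benefit"),
    -"t", names_to = "curve", values_to = "value"
  )
  pk <- peak_time(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = pk, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "adjustment step", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of peak times across individuals
#'
#' @param object An `rrsat_peaks` tibble from [simulate_population()].
#' @param ... Unused.
#' @return A ggplot histogram of peak times, faceted by cost regime.
#' @export
autoplot.rrsat_peaks <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     regime = factor(paste0("max cost = ", .data$max_cost)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$peak_time)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0) +
    ggplot2::facet_wrap(~regime, ncol = 1) +
    ggplot2::labs(x = "peak time (adjustment steps)", y = "individuals") +
    ggplot2::theme_minimal()
}

#' Plot cumulative response-time distributions
#'
#' @param cdf The `rt_cdf` table of an [analyze_dataset()] result.
#' @return A ggplot of cumulative probability against time, coloured by
#'   group and faceted by difficulty and correctness.
#' @export
plot_rt_cdf <- function(cdf) {
  ggplot2::ggplot(cdf, ggplot2::aes(x = .data$edge, y = .data$cum_prob,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(correct ~ difficulty,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "response time (s)", y = "cumulative probability") +
    ggplot2::theme_minimal()
}

#' Plot mean conflict area by response-time category
#'
#' @param auc_by_category The `auc_by_category` table of an
#'   [analyze_dataset()] result.
#' @return A ggplot of mean trajectory area against response-time category,
#'   per group, faceted by difficulty.
#' @export
plot_auc_by_category <- function(auc_by_category) {
  ggplot2::ggplot(auc_by_category,
                  ggplot2::aes(x = .data$rt_category, y = .data$mean_auc,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~difficulty) +
    ggplot2::labs(x = "response-time category", y = "mean AUC (px^2)") +
    ggplot2::theme_minimal()
}

#' Plot per-participant accuracy by group
#'
#' @param accuracy_by_group The `accuracy_by_group` table of an
#'   [analyze_dataset()] result.
#' @return A ggplot of individual accuracies by group, faceted by
#'   difficulty.
#' @export
plot_accuracy <- function(accuracy_by_group) {
  ggplot2::ggplot(accuracy_by_group,
                  ggplot2::aes(x = .data$group, y = .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3) +
    ggplot2::facet_wrap(~difficulty) +
    ggplot2::labs(x = "waiting-time group", y = "individual accuracy") +
    ggplot2::theme_minimal()
}
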