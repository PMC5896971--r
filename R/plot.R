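#' Trajectory plots
#'
#' `autoplot()` on a single run shows the population mean false-positive
#' probability and mean effort over the research cycles.
#' `plot_trajectories()` draws a multi-replicate records table (as written
#' by [write_records()]): one grey line per replicate with the
#' across-replicate mean in colour, the layout used throughout this
#' literature.
#'
#' @param object An `auditsim_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cfg <- scenario_config(total_cycles = 4000L, record_every = 500L)
#' autoplot(run_simulation(cfg, seed = 1))
#' @export
autoplot.auditsim_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$records[, c("cycle", "mean_alpha", "mean_effort")],
    c("mean_alpha", "mean_effort"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line(colour = "darkred") +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::labeller(quantity = c(
                          mean_alpha = "Mean false positive probability",
                          mean_effort = "Mean effort"))) +
    ggplot2::labs(x = "Research cycle", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.auditsim_run
#' @param records A records tibble with `replicate`, `cycle` and the
#'   plotted variable.
#' @param var Column to plot (default `"mean_alpha"`).
#' @export
plot_trajectories <- function(records, var = "mean_alpha") {
  stopifnot(is.data.frame(records), var %in% names(records))
  mean_line <- records |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(value = mean(.data[[var]]), .groups = "drop")
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$cycle, y = .data[[var]],
                               group = .data$replicate)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = mean_line,
                       ggplot2::aes(y = .data$value, group = NULL),
                       colour = "darkred", linewidth = 0.8) +
    ggplot2::labs(x = "Research cycle", y = var) +
    ggplot2::theme_minimal()
}
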