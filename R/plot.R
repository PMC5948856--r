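#' Plot the evolution of the tracked metrics
#'
#' Line plots of the four observer metrics over simulated hours, faceted by
#' metric. Requires ggplot2.
#'
#' @param sim A `pest_sim` from [run_simulation()].
#' @param metrics Character vector of trace columns to show.
#' @return A ggplot object.
#' @export
plot_evolution <- function(sim,
                           metrics = c("avg_power", "crop_health_pct",
                                       "alive_bugs_pct",
                                       "pesticide_per_station")) {
  stopifnot(inherits(sim, "pest_sim"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_evolution requires the ggplot2 package", call. = FALSE)
  }
  metrics <- match.arg(metrics, trace_columns()[-1L], several.ok = TRUE)
  tr <- sim$trace
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(iteration = tr$iteration, metric = m, value = tr[[m]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "simulated hour", y = NULL,
                  title = sprintf("strategy '%s'", sim$config$strategy))
}
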