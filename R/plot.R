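# Histogram panels of the pooled error distributions.

#' Histograms of the pooled error metrics of an experiment
#'
#' One panel per metric, Freedman-Diaconis binning.
#'
#' @param x an `experiment_result` from [run_experiment()].
#' @param metrics which pooled metrics to plot (default: all).
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @importFrom graphics hist par
#' @export
plot.experiment_result <- function(x, metrics = names(x$pooled), ...) {
  metrics <- intersect(metrics, names(x$pooled))
  metrics <- metrics[vapply(metrics, function(m)
    length(x$pooled[[m]]) > 1L && stats::sd(x$pooled[[m]]) > 0, logical(1))]
  if (!length(metrics)) stop("no dispersed metrics to plot")
  nr <- ceiling(length(metrics) / 2)
  op <- par(mfrow = c(nr, min(2L, length(metrics))), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (m in metrics)
    hist(x$pooled[[m]], breaks = "FD", main = m,
         xlab = paste0(m, " (", METRIC_UNITS[[m]], ")"), ...)
  invisible(x)
}
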