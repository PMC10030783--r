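#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: activity traces and electrode potentials for simulations,
#' coverage maps in gradations of grey (never covered = black, most
#' covered = white), spike trains over their traces, and overlaid ISI
#' histograms per load condition.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @name mycosim-autoplot
NULL

matrix_to_xy <- function(m, value = "value") {
  tibble(
    i = rep(seq_len(nrow(m)), times = ncol(m)),
    j = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value := as.vector(m))
}

#' @rdname mycosim-autoplot
#' @export
autoplot.conductive_template <- function(object, ...) {
  d <- matrix_to_xy(unclass_template(object), "conductive")
  ggplot2::ggplot(d, ggplot2::aes(.data$j, .data$i,
                                  fill = factor(.data$conductive))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  title = "Conductive template") +
    ggplot2::theme_minimal()
}

#' @rdname mycosim-autoplot
#' @export
autoplot.coverage_map <- function(object, ...) {
  m <- if (isTRUE(attr(object, "normalized"))) object else normalize_coverage(object)
  d <- matrix_to_xy(unclass(m), "coverage")
  ggplot2::ggplot(d, ggplot2::aes(.data$j, .data$i, fill = .data$coverage)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "coverage") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  title = "Coverage frequency (normalised)") +
    ggplot2::theme_minimal()
}

#' @rdname mycosim-autoplot
#' @param what `"activity"` (excited-node count over iterations) or
#'   `"potentials"` (one panel per electrode).
#' @export
autoplot.fhn_sim <- function(object, what = c("activity", "potentials"), ...) {
  what <- match.arg(what)
  if (what == "activity") {
    ggplot2::ggplot(activity_trace(object),
                    ggplot2::aes(.data$iteration, .data$active)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration",
                    y = sprintf("nodes with u > %g", object$activity_threshold),
                    title = "Network activity") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(potential_traces(object),
                    ggplot2::aes(.data$iteration, .data$potential)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~electrode, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = "electrode potential (model units)",
                    title = "Virtual electrode potentials") +
      ggplot2::theme_minimal()
  }
}

#' @rdname mycosim-autoplot
#' @export
autoplot.spike_train <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$prominence)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$time, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time", y = "prominence", title = "Detected spikes") +
    ggplot2::theme_minimal()
  if ("electrode" %in% names(object)) p <- p + ggplot2::facet_wrap(~electrode)
  p
}

#' @rdname mycosim-autoplot
#' @export
autoplot.isi_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$bin_mid, .data$n,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5,
                      width = attr(object, "bin_width")) +
    ggplot2::labs(x = "inter-spike interval (s)", y = "count",
                  title = "Inter-spike intervals by load condition") +
    ggplot2::theme_minimal()
}

#' @rdname mycosim-autoplot
#' @export
autoplot.amplitude_by_condition <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$condition, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = NULL, y = "spike amplitude (mV, prominence)",
                  title = "Spike amplitude by load condition") +
    ggplot2::theme_minimal()
}

#' @rdname mycosim-autoplot
#' @export
autoplot.gate_census <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(stats::reorder(.data$gate, .data$n), .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "events", title = "Boolean gate census") +
    ggplot2::theme_minimal()
}
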