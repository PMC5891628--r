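#' Plot span scores from a grid run
#'
#' Marginalises span over one grid factor (optionally split by a second) and
#' draws the resulting means as points and lines, the standard presentation
#' of complex span simulation results. With `x = "cl"` the span is plotted
#' against the nominal cognitive load and the human meta-analytic reference
#' line can be overlaid.
#'
#' @param object A `wm_grid`.
#' @param x Factor on the x axis: one of `"cl"`, `"nd"`, `"dac"`, `"ft"`,
#'   `"mdo"`, `"mdd"`.
#' @param colour Optional second factor mapped to colour (e.g. `"hod"`).
#' @param overlay Overlay the [cl_reference_line()] (only with `x = "cl"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @examples
#' g <- run_grid(grid_spec(nd = c(0, 4), dac = c(0.3, 0.7), ft = c(0.1, 1.2),
#'                         mdo = 0, mdd = 0, hod = "distinct",
#'                         list_length = c(2, 4, 6), runs_per_case = 5))
#' autoplot(g, x = "cl")
autoplot.wm_grid <- function(object, x = "cl", colour = NULL,
                             overlay = FALSE, ...) {
  by <- c(x, colour)
  agg <- aggregate_spans(object, by = by)
  if (!is.null(colour)) agg[[colour]] <- factor(agg[[colour]])
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data[[x]], y = .data$mean_span))
  if (overlay && x == "cl") {
    p <- p + ggplot2::geom_line(
      data = cl_reference_line(),
      ggplot2::aes(x = .data$cl, y = .data$span),
      linetype = "dashed", colour = "grey40"
    )
  }
  if (is.null(colour)) {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  } else {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]])) +
      ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  }
  p + ggplot2::labs(x = switch(x, cl = "cognitive load (DAC / (DAC + FT))",
                               nd = "distractors per burst",
                               mdo = "memoranda-distractor overlap",
                               mdd = "memoranda-distractor distance (sd)",
                               ft = "free time (s)", x),
                    y = "span") +
    ggplot2::ylim(0, 9) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wm_grid
#' @param grid A `wm_grid`.
#' @export
plot_span_cl <- function(grid, colour = NULL, overlay = TRUE) {
  autoplot.wm_grid(grid, x = "cl", colour = colour, overlay = overlay)
}

#' @rdname autoplot.wm_grid
#' @export
plot_span_nd <- function(grid, colour = "hod") {
  autoplot.wm_grid(grid, x = "nd", colour = colour)
}

#' @rdname autoplot.wm_grid
#' @export
plot_span_mdo <- function(grid, colour = NULL) {
  autoplot.wm_grid(grid, x = "mdo", colour = colour)
}

#' Plot the activation time course of one trial
#'
#' Reconstructs the trial timeline as shaded encoding / distractor / free
#' time bands, a compact view of the task structure a configuration
#' generates.
#'
#' @param trial A `wm_trial`.
#' @return A ggplot object.
#' @export
plot_timeline <- function(trial) {
  stopifnot(inherits(trial, "wm_trial"))
  tl <- dplyr::filter(trial$timeline, .data$kind != "recall")
  ggplot2::ggplot(tl) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$onset,
                                    xmax = .data$onset + .data$duration,
                                    ymin = 0, ymax = 1, fill = .data$kind)) +
    ggplot2::scale_fill_manual(values = c(encode = "grey70",
                                          distractor = "grey30",
                                          free_time = "white")) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
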