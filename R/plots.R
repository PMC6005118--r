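#' Scanpath plot of a cancellation trial
#'
#' Draws the target array (black = never cancelled, red = cancelled by the
#' end of the trial) with the saccade path overlaid in blue, in display
#' coordinates (row 0 at the top).
#'
#' @param object A `neglect_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neglect_trial <- function(object, ...) {
  cells <- tidy(object$display_end)
  targets <- dplyr::filter(cells, .data$state != "empty")
  path <- dplyr::bind_rows(
    loc_rc(object$start),
    object$epochs[, c("index", "row", "col")]
  )
  path$step <- seq_len(nrow(path)) - 1L
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = targets,
      ggplot2::aes(x = .data$col, y = .data$row, colour = .data$state),
      shape = 15, size = 5
    ) +
    ggplot2::scale_colour_manual(
      values = c(target = "black", cancelled = "red"), name = NULL
    ) +
    ggplot2::geom_path(
      data = path, ggplot2::aes(x = .data$col, y = .data$row),
      colour = "blue", alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = path, ggplot2::aes(x = .data$col, y = .data$row),
      colour = "blue", size = 1.2
    ) +
    ggplot2::scale_y_reverse(breaks = 0:7, limits = c(7.5, -0.5)) +
    ggplot2::scale_x_continuous(breaks = 0:7, limits = c(-0.5, 7.5)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0("Cancellation trial (", object$model_label, " lesion, ",
                     object$n_saccades, " saccades)"),
      x = "column", y = "row"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a lesion-decoding confusion matrix
#'
#' @param object A `neglect_confusion`.
#' @param which `"posterior"` (default) or `"log_evidence"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neglect_confusion <- function(object,
                                       which = c("posterior", "log_evidence"),
                                       ...) {
  which <- match.arg(which)
  df <- tidy(object)
  df$value <- df[[which]]
  lev <- rownames(object$posterior)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$candidate, levels = lev),
    y = factor(.data$generator, levels = rev(lev)),
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$value, 2)),
                       colour = "white") +
    ggplot2::labs(x = "candidate model", y = "generating model",
                  fill = which) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
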