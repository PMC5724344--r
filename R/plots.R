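#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one slice of a study
#'
#' Renders a slice in the standard brain display window.
#'
#' @param study A `ct_study`.
#' @param slice Slice number.
#' @param window_center,window_width Display window in HU.
#' @return A ggplot object.
#' @export
plot_slice <- function(study, slice = 1L, window_center = 40,
                       window_width = 80) {
  img <- study$slices[[slice]]
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- apply_window(img[cbind(df$row, df$col)], window_center, window_width)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "windowed") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s slice %d (%s)", study$study_id, slice,
                                  study$truth_class),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_slice
#' @param object A `ct_study`.
#' @param ... Passed to [plot_slice()].
#' @method autoplot ct_study
#' @export
autoplot.ct_study <- function(object, ...) plot_slice(object, ...)

#' Plot a result page as ranked score bars
#'
#' @param object A `ct_results` page.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ct_results
#' @export
autoplot.ct_results <- function(object, ...) {
  df <- tidy(object)
  score_col <- if ("combined_score" %in% names(df)) {
    "combined_score"
  } else if (attr(object, "query")$mode == "image") "image_score" else "text_score"
  df$score <- df[[score_col]]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$study_id, -.data$rank),
    y = .data$score, fill = .data$match_class
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "study (rank order)", y = score_col,
                  title = sprintf("%s search: %d studies",
                                  attr(object, "query")$mode, nrow(df))) +
    ggplot2::theme_minimal()
}
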