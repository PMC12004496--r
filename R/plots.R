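#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trade-off table against the 1:1 line
#'
#' Draws each grassland-by-litter cell as a point in standardized-benefit
#' space with the 1:1 trade-off line. Points above the line (plant benefit
#' larger, under the default orientation) favor TPCP; points below favor
#' MBCP; the perpendicular distance of a point to the line is its
#' trade-off index.
#'
#' @param object A `tradeoff_tbl` from [tradeoff_table()].
#' @param axis_orientation `"mbcp_x"` (default) puts the microbial benefit
#'   on the x axis; `"tpcp_x"` flips the axes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tradeoff_tbl
#' @export
autoplot.tradeoff_tbl <- function(object, axis_orientation = c("mbcp_x", "tpcp_x"),
                                  ...) {
  axis_orientation <- match.arg(axis_orientation)
  df <- as_tibble(object)
  if (axis_orientation == "mbcp_x") {
    df$x <- df$mbcp_std; df$y <- df$tpcp_std
    labs <- c("Standardized MBCP benefit", "Standardized TPCP benefit")
  } else {
    df$x <- df$tpcp_std; df$y <- df$mbcp_std
    labs <- c("Standardized TPCP benefit", "Standardized MBCP benefit")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$litter,
                                     shape = .data$grassland), size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = "Litter level",
                  shape = "Grassland") +
    ggplot2::theme_minimal()
}

#' Plot treatment means with significance letters
#'
#' Bar chart of per-cell means of a pool response with standard-deviation
#' error bars and Tukey compact-letter annotations, faceted by grassland
#' (the convention of grazing-experiment figures).
#'
#' @inheritParams group_statistics
#' @return A ggplot object.
#' @export
plot_treatment_summary <- function(pools, response, alpha = 0.05) {
  sm <- treatment_summary(pools, response, alpha = alpha)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$litter, y = .data$mean)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$litter), show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25
    ) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean + .data$sd, label = .data$letter),
      vjust = -0.5, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~grassland) +
    ggplot2::labs(x = "Litter treatment", y = response) +
    ggplot2::theme_minimal()
}
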