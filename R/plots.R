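# ggplot2 graphics for the result objects.

grid_to_df <- function(m, value = "value") {
  df <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m))
  )
  df[[value]] <- as.vector(m)
  df
}

#' Plot the three layers of a channel stack
#'
#' @param stack A [channel_stack()].
#' @param islet Optional [islet_mask()] drawn as a contour.
#' @return A ggplot with one facet per channel.
#' @export
plot_channels <- function(stack, islet = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  df <- dplyr::bind_rows(
    dplyr::mutate(grid_to_df(stack$dapi), channel = "dapi"),
    dplyr::mutate(grid_to_df(stack$target488), channel = "target488"),
    dplyr::mutate(grid_to_df(stack$counter555), channel = "counter555")
  )
  df$channel <- factor(df$channel, levels = c("dapi", "target488", "counter555"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
  if (!is.null(islet)) {
    mdf <- grid_to_df(islet$mask * 1, "islet")
    p <- p + ggplot2::geom_contour(
      data = mdf,
      mapping = ggplot2::aes(x = .data$col, y = .data$row, z = .data$islet),
      breaks = 0.5, colour = "yellow", inherit.aes = FALSE
    )
  }
  p
}

#' Plot a scored islet
#'
#' Shows the scored marker channel with the stained mask and the detected
#' nuclei coloured by their alpha/beta vote.
#'
#' @param object An `islet_score` from [score_islet()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.islet_score <- function(object, ...) {
  ch <- object$config$target_channel
  df <- grid_to_df(object$stack[[ch]])
  target_map <- if (ch == "target488") object$map488 else object$map555
  df$stained <- as.vector(target_map$stained & object$islet$mask)
  cells <- tibble::as_tibble(object$cells)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$stained),
      colour = "#2ca02c", size = 0.1, alpha = 0.25
    ) +
    ggplot2::geom_point(
      data = cells,
      ggplot2::aes(colour = .data$label), size = 1.6
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_colour_manual(
      values = c(beta = "#00b4d8", alpha = "#ff6b6b", unclassified = "grey70")
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("area score %.2f (stained fraction %.2f)",
                      object$features$area_score, object$features$stained_fraction),
      x = NULL, y = NULL, fill = "intensity", colour = "cell"
    )
}

#' Plot a Pearson correlation with its least-squares fit
#'
#' @param object A `pearson_cor` from [pearson()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pearson_cor <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#00b4d8") +
    ggplot2::labs(
      title = sprintf("r^2 = %.3f, two-tailed p = %.3g (n = %d)",
                      object$r2, object$p_value, object$n),
      x = "x", y = "y"
    )
}

#' Plot an ANCOVA slope comparison
#'
#' @param object An `ancova_slopes` from [ancova_slopes()].
#' @param ... Unused.
#' @return A ggplot with per-group points and fitted lines.
#' @export
autoplot.ancova_slopes <- function(object, ...) {
  lines <- tibble(
    group = names(object$slopes),
    slope = unname(object$slopes),
    intercept = unname(object$intercepts)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group)
    ) +
    ggplot2::labs(
      title = sprintf("slope difference %.3g, interaction p = %.3g",
                      object$slope_diff, object$interaction_p),
      x = "covariate", y = "response"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
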