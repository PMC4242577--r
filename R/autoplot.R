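# ggplot2 autoplot methods for the spatial and analytical result types.

raster_to_tibble <- function(grid) {
  rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  cc <- cell_center(grid, rows, cols)
  tibble(lon = cc$lon, lat = cc$lat, value = as.vector(grid$values))
}

#' Plot a raster grid
#'
#' @param object A [raster_grid].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- raster_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value")
}

#' Plot an ensemble vote map
#'
#' @param object A [vote_map].
#' @param ... Unused.
#' @return A ggplot of the per-pixel suitable-vote percentage.
#' @export
autoplot.vote_map <- function(object, ...) {
  autoplot.raster_grid(object$percent) +
    ggplot2::labs(fill = "% votes",
                  title = sprintf("Ensemble votes (n = %d)", object$n_votes))
}

#' Plot a refugium stability map
#'
#' @param object A [refugia_map].
#' @param ... Unused.
#' @return A ggplot with the none/stable50/stable75 categories.
#' @export
autoplot.refugia_map <- function(object, ...) {
  df <- raster_to_tibble(object$category)
  df$category <- factor(df$value, levels = c(0, 1, 2),
                        labels = c("none",
                                   sprintf("stable%g", object$levels[1]),
                                   sprintf("stable%g", object$levels[2])))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(
      values = c(none = "grey95", stable50 = "grey60", stable75 = "grey20"),
      na.value = "white", drop = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "stability")
}

#' Plot a niche occupancy density
#'
#' @param object A [niche_density].
#' @param ... Unused.
#' @return A ggplot of the occupancy surface in PC space.
#' @export
autoplot.niche_density <- function(object, ...) {
  df <- tibble(PC1 = rep(object$x, times = length(object$y)),
               PC2 = rep(object$y, each = length(object$x)),
               z = as.vector(object$z))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "occupancy")
}

#' Plot a DEC root-range profile
#'
#' @param object A `dec_fit`.
#' @param ... Unused.
#' @return A ggplot of `-ln L` per candidate root range.
#' @export
autoplot.dec_fit <- function(object, ...) {
  df <- mutate(object$root_profile,
               range = factor(.data$range, levels = rev(.data$range)))
  ggplot2::ggplot(df, ggplot2::aes(.data$neg_log_lik, .data$range)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-ln L (root restricted)", y = "root range",
                  title = object$hypothesis)
}
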