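# ggplot2 displays for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_line
#'   labs facet_wrap scale_size_area theme_minimal
#' @export
ggplot2::autoplot

#' Model-fit scatter for a radius sweep
#'
#' Mean R^2 against the kernel radius, one point per candidate model,
#' coloured by cluster count — the standard display for choosing among
#' candidate seasonal models.
#'
#' @param object An `fw_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fw_sweep <- function(object, ...) {
  df <- filter(object$stats, !is.na(.data$mean_r2))
  ggplot(df, aes(x = .data$r, y = .data$mean_r2,
                 colour = factor(.data$k))) +
    geom_point(size = 2) +
    labs(x = "kernel radius R (standardized units)",
         y = expression(mean ~ R^2), colour = "clusters") +
    theme_minimal()
}

#' Day-of-year histograms of a seasonal profile
#'
#' 15-day-bin histograms of each cluster's days across the year.
#'
#' @param object An `fw_season_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fw_season_profile <- function(object, ...) {
  ggplot(object$histogram,
         aes(x = .data$bin_start_doy, y = .data$count,
             fill = factor(.data$cluster))) +
    geom_col(width = 14) +
    facet_wrap(~cluster, ncol = 1) +
    labs(x = "day of year", y = "days", fill = "cluster") +
    theme_minimal()
}

#' The fire-weather plane
#'
#' Days plotted on the first two canonical discriminant functions,
#' coloured by cluster.
#'
#' @param object An `fw_discriminant`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fw_discriminant <- function(object, ...) {
  df <- filter(object$scores, .data$cluster > 0)
  ggplot(df, aes(x = .data$f1, y = .data$f2,
                 colour = factor(.data$cluster))) +
    geom_point(alpha = 0.4, size = 0.8) +
    labs(x = sprintf("function I (%.0f%%)", object$pct_variance[1]),
         y = sprintf("function II (%.0f%%)",
                     if (length(object$pct_variance) >= 2)
                       object$pct_variance[2] else 0),
         colour = "cluster") +
    theme_minimal()
}

#' Bubble plot of fires on the fire-weather plane
#'
#' Each fire is a disc at its ignition day's plane coordinates with disc
#' area proportional to burned area, faceted by ignition source.
#'
#' @param fires Joined fire tibble with `f1`, `f2`, `area_ha`, `source`.
#' @return A ggplot.
#' @export
plot_fire_bubbles <- function(fires) {
  df <- bubble_plot_export(fires)
  ggplot(df, aes(x = .data$f1, y = .data$f2, size = .data$area_ha,
                 colour = .data$source)) +
    geom_point(alpha = 0.5) +
    scale_size_area(max_size = 12) +
    facet_wrap(~source) +
    labs(x = "function I", y = "function II", size = "area (ha)") +
    theme_minimal()
}
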