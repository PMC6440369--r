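#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot an ECAP histogram
#'
#' Bar chart of the percentage of region-of-interest surface (or node
#' count) per ECAP interval; the high-risk tail (lower bound >= 3 Pa^-1)
#' is highlighted.
#'
#' @param object An [ecap_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecap_histogram
#' @export
autoplot.ecap_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$interval <- factor(
    ifelse(is.finite(df$bin_hi),
           sprintf("%g-%g", df$bin_lo, df$bin_hi),
           sprintf(">%g", df$bin_lo)),
    levels = ifelse(is.finite(df$bin_hi),
                    sprintf("%g-%g", df$bin_lo, df$bin_hi),
                    sprintf(">%g", df$bin_lo)))
  df$high_risk <- df$bin_lo >= 3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$pct,
                                   fill = .data$high_risk)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(ECAP ~ (Pa^-1)),
                  y = sprintf("%% of %s",
                              if (identical(attr(object, "weighting"),
                                            "node_count")) "nodes"
                              else "surface area")) +
    ggplot2::theme_minimal()
}

#' Plot a velocity probe trace
#'
#' @param object A [probe_velocity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot velocity_probe
#' @export
autoplot.velocity_probe <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$speed_m_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "speed (m/s)") +
    ggplot2::theme_minimal()
}

#' Plot a diameter profile along the appendage
#'
#' D1 and D2 against geodesic station, with the landing depths of both
#' device families marked.
#'
#' @param profile Tibble from [diameter_profile()].
#' @return A ggplot.
#' @export
plot_diameter_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile[, c("station_mm", "d1_mm", "d2_mm")],
                              cols = c("d1_mm", "d2_mm"),
                              names_to = "which", values_to = "diameter_mm")
  long$which <- ifelse(long$which == "d1_mm", "D1 (max)", "D2 (min)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$station_mm,
                                     y = .data$diameter_mm,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(10, 13), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "geodesic distance from ostium (mm)",
                  y = "diameter (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}
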