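#' Plot sliding-window diversity profiles
#'
#' Line plot of per-window statistics along the region for one or more
#' populations, the usual way a candidate region's diversity valley is shown.
#'
#' @param table an `sv_site_table` from [classify_sites()].
#' @param populations population tags to draw (default: all ingroup tags).
#' @param statistic one of `"theta_w"`, `"pi"`, `"tajima_d"`, `"divergence"`.
#' @param window,step window settings passed to [sliding_windows()].
#' @return a ggplot object.
#' @export
plot_windows <- function(table, populations = NULL, statistic = "theta_w",
                         window = 1000L, step = 500L) {
  statistic <- match.arg(statistic,
                         c("theta_w", "pi", "tajima_d", "divergence"))
  if (is.null(populations)) populations <- sv_pops(table)
  dat <- purrr::map_dfr(populations, function(p) {
    w <- sliding_windows(table, p, window, step)
    w$population <- p
    w
  })
  dat$midpoint <- (dat$start + dat$end) / 2
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$midpoint,
                                    y = .data[[statistic]],
                                    colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "alignment position (bp)", y = statistic,
                  colour = "population") +
    ggplot2::theme_minimal()
}
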