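new_scan_result <- function(tbl, statistic, threshold = NA_real_) {
  attr(tbl, "statistic") <- statistic
  mx <- suppressWarnings(max(tbl$value, na.rm = TRUE))
  if (!is.finite(mx) && !any(is.infinite(tbl$value) & tbl$value > 0, na.rm = TRUE)) {
    mx <- NA_real_
  }
  am <- if (is.na(mx)) NA_real_ else tbl$position[which(tbl$value == mx)[1]]
  attr(tbl, "max_value") <- mx
  attr(tbl, "argmax_position") <- am
  attr(tbl, "threshold") <- threshold
  class(tbl) <- c("sv_scan_result", class(tbl))
  tbl
}

#' @export
print.sv_scan_result <- function(x, ...) {
  cat("<sv_scan_result> statistic:", attr(x, "statistic"),
      "| max =", format(attr(x, "max_value"), digits = 4),
      "at", format(attr(x, "argmax_position"), digits = 6), "\n")
  if (!is.na(attr(x, "threshold"))) {
    cat("  threshold:", format(attr(x, "threshold"), digits = 4),
        if (isTRUE(attr(x, "max_value") > attr(x, "threshold")))
          "(significant)" else "(not significant)", "\n")
  }
  NextMethod()
}

#' Attach a calibrated significance threshold to a scan result
#' @param scan an `sv_scan_result`.
#' @param threshold calibrated null quantile for the scan maximum.
#' @return the scan result with `threshold` and `significant` set.
#' @export
set_threshold <- function(scan, threshold) {
  attr(scan, "threshold") <- threshold
  scan
}

#' @exportS3Method generics::glance
glance.sv_scan_result <- function(x, ...) {
  thr <- attr(x, "threshold")
  tibble(statistic = attr(x, "statistic"),
         argmax_position = attr(x, "argmax_position"),
         max_value = attr(x, "max_value"),
         threshold = thr,
         significant = if (is.na(thr)) NA else attr(x, "max_value") > thr)
}

#' @exportS3Method generics::tidy
tidy.sv_scan_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sv_scan_result")
  attr(out, "statistic") <- NULL
  attr(out, "max_value") <- NULL
  attr(out, "argmax_position") <- NULL
  attr(out, "threshold") <- NULL
  as_tibble(out)
}

#' @exportS3Method ggplot2::autoplot
autoplot.sv_scan_result <- function(object, ...) {
  dat <- tidy(object)
  dat$value[is.infinite(dat$value)] <- max(dat$value[is.finite(dat$value)], 1)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = attr(object, "statistic"),
                  title = paste("Sweep scan:", attr(object, "statistic"))) +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold")
  if (!is.na(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  p
}
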