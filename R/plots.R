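#' Plot yearly report counts
#'
#' Line-and-point trend of report counts over receipt years, one line per
#' drug when a `drug` column is present.
#'
#' @param yearly a tibble from [yearly_counts()], optionally with a `drug`
#'   column for several drugs.
#' @return a ggplot object.
#' @export
plot_yearly_trend <- function(yearly) {
  p <- ggplot2::ggplot(yearly, ggplot2::aes(x = .data$year, y = .data$n))
  if ("drug" %in% names(yearly)) {
    p <- p + ggplot2::aes(colour = .data$drug)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Report year", y = "Reports",
                  title = "Adverse event reports per year")
}

#' Plot a time-to-onset histogram
#'
#' Onset-day histogram in fixed-width bins (30 days by default, the
#' conventional binning for onset distributions).
#'
#' @param records a tibble from [compute_tto()].
#' @param binwidth bin width in days.
#' @return a ggplot object.
#' @export
plot_tto_histogram <- function(records, binwidth = 30) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$days)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Time to onset (days)", y = "Reports",
                  title = "Time-to-onset distribution")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted Weibull over the onset histogram
#'
#' @param object a `weibull_fit` from [fit_weibull()].
#' @param binwidth histogram bin width in days.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.weibull_fit <- function(object, binwidth = 30, ...) {
  df <- tibble::tibble(days = object$data)
  grid <- tibble::tibble(
    x = seq(0.01, max(df$days), length.out = 400)
  )
  grid$density <- stats::dweibull(grid$x, shape = object$shape,
                                  scale = object$scale)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$days)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, boundary = 0,
                            fill = "grey80", colour = "white") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "Time to onset (days)", y = "Density",
      title = sprintf(
        "Weibull fit: shape %.2f (%.2f-%.2f), scale %.1f d; %s failure",
        object$shape, object$shape_lo, object$shape_hi, object$scale,
        object$failure_type)
    )
}
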