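#' Plot an angle signal
#'
#' Angle versus time; samples below the visibility threshold are marked. When
#' the signal carries `raw` (Kalman input) or `truth` columns they are drawn
#' as reference lines.
#'
#' @param object An [angle_signal()].
#' @param visibility_threshold Gating threshold to highlight, default 0.4.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angle_signal
#' @export
autoplot.angle_signal <- function(object, visibility_threshold = 0.4, ...) {
  fps <- signal_fps(object)
  df <- tibble::as_tibble(object)
  df$time <- df$frame / fps
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$theta))
  if ("truth" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$truth),
                                colour = "grey60", linetype = "dashed")
  }
  if ("raw" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$raw),
                                colour = "grey75", linewidth = 0.3)
  }
  p +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = df[df$visibility < visibility_threshold, ],
                        colour = "firebrick", size = 0.8) +
    ggplot2::labs(
      x = "time (s)", y = "angle (deg)",
      title = sprintf("%s (%s side)", signal_joint(object), signal_side(object))
    )
}

#' Scree plot of a feature model
#'
#' Explained-variance fraction per retained principal component.
#'
#' @param object A `feature_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_model
#' @export
autoplot.feature_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$pc), y = .data$explained_variance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_variance, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_variance)) +
    ggplot2::labs(x = "principal component", y = "variance fraction",
                  title = sprintf("feature model (%s, n = %d)",
                                  object$stratum, object$n_samples))
}

#' Bland-Altman plot
#'
#' Differences against pair means, with the mean-difference line and the 95%
#' limits of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  pts <- attr(object, "differences")
  ylab <- if (isTRUE(attr(object, "relative"))) "difference (% of gold)" else "difference"
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean_pair, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "mean of pair", y = ylab, title = "Bland-Altman agreement")
}

#' Plot the four filtered signals of a gait report
#'
#' @param report A `gait_report`.
#' @return A ggplot object, facetted by joint and side.
#' @export
plot_gait_signals <- function(report) {
  stopifnot(inherits(report, "gait_report"))
  df <- purrr::imap(report$signals, function(s, nm) {
    tibble::tibble(signal = nm, time = s$frame / signal_fps(s), theta = s$theta)
  })
  df <- dplyr::bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$theta)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
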