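# ggplot2 views of the main result types. Plots are conveniences; every
# quantity they show is available from the corresponding tidy tables.

#' @export
autoplot.hypnogram <- function(object, ...) {
  lev <- if (hypnogram_arity(object) == 4L) {
    c("WKL", "WKB", "REM", "NREM")
  } else {
    c("WK", "REM", "NREM")
  }
  df <- as_tibble(object)
  df$state <- factor(df$state, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$onset_s / 3600,
    y = .data$state, group = 1
  )) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_rug(
      data = df[df$phase == "dark", ],
      sides = "b", colour = "grey30", alpha = 0.05
    ) +
    ggplot2::labs(x = "Time (h)", y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_curve <- function(object, log_time = FALSE, ...) {
  df <- tibble(
    time_s = c(0, object$time_s),
    survival = c(1, object$survival)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Bout duration (s)", y = "Fraction surviving",
      title = "Kaplan-Meier bout survival"
    ) +
    ggplot2::theme_minimal()
  if (log_time) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' @export
autoplot.state_spectra <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$frequency, .data$z_power, colour = .data$state)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Power (z-score)",
      colour = "State", title = "State-conditioned spectral profiles"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.matrix_estimate <- function(object, ...) {
  df <- tidy(object)
  df$from <- factor(df$from, levels = rev(rownames(object$probs)))
  df$to <- factor(df$to, levels = colnames(object$probs))
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from, fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.4f", .data$estimate)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue",
      limits = c(0, 1)
    ) +
    ggplot2::labs(
      x = "To", y = "From", fill = "P",
      title = paste0(
        "Transition probabilities",
        if (!is.null(object$phase)) paste0(" (", object$phase, ")") else ""
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bout-duration histogram plot
#'
#' Column plot of a [duration_histogram()], optionally on a log duration
#' axis where the brief/long wake bimodality is visible.
#'
#' @param histogram Output of [duration_histogram()].
#' @param log_x Log-scale the duration axis?
#' @return A ggplot object.
#' @export
plot_duration_histogram <- function(histogram, log_x = FALSE) {
  p <- ggplot2::ggplot(histogram, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(
      width = histogram$bin_hi - histogram$bin_lo,
      fill = "grey60", colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::labs(
      x = "Bout duration (s)", y = "Density",
      title = "Bout-duration distribution"
    ) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}
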