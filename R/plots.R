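#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a quantized level series
#'
#' Step plot of the energy levels over time; OSA-candidate sections (level 4)
#' are highlighted.
#'
#' @param object A [level_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.level_series <- function(object, ...) {
  df <- tibble::tibble(
    time_s = (seq_along(object$levels) - 1) * object$hop_s,
    level = object$levels
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$level)) +
    ggplot2::geom_step(color = "grey30") +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$level == 4L),
      color = "firebrick", size = 0.6
    ) +
    ggplot2::scale_y_continuous(
      breaks = 1:4,
      labels = c("silence", "breathing", "loud snore", "OSA candidate")
    ) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Quantized energy levels") +
    ggplot2::theme_minimal()
}

#' Plot a cyclic spectral density grid
#'
#' Raster of log10 magnitude over (alpha, f). The lower alpha half carries
#' the information; the mirrored upper half is omitted for readability.
#'
#' @param object A `csd_grid` or `running_csd_mean`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csd_grid <- function(object, ...) {
  m <- object$magnitudes
  half <- seq_len(ncol(m) %/% 2L + 1L)
  df <- tidyr::expand_grid(
    f = object$f_grid, alpha = object$alpha_grid[half]
  )
  df$mag <- as.numeric(m[, half])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$f,
                                   fill = log10(.data$mag + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 |S|") +
    ggplot2::labs(x = expression(alpha ~ "(Hz)"), y = "f (Hz)",
                  title = "Cyclic spectral density magnitude") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.running_csd_mean <- function(object, ...) {
  fake <- structure(
    list(
      magnitudes = object$rms,
      f_grid = seq_len(nrow(object$rms)) - 1,
      alpha_grid = seq_len(ncol(object$rms)) - 1
    ),
    class = "csd_grid"
  )
  autoplot.csd_grid(fake, ...) +
    ggplot2::labs(x = "alpha bin", y = "f bin",
                  title = "Running-mean CSD magnitude")
}

#' Plot a transition probability matrix
#'
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(from = 1:4, to = 1:4)
  df$prob <- as.numeric(t(object$probs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$prob)),
                       color = "white", size = 3) +
    ggplot2::scale_y_reverse(breaks = 1:4) +
    ggplot2::scale_x_continuous(breaks = 1:4, position = "top") +
    ggplot2::scale_fill_viridis_c(name = "P") +
    ggplot2::labs(x = "to level", y = "from level",
                  title = "Energy-level transition probabilities") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `osa_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osa_confusion <- function(object, ...) {
  df <- tidy(object)
  lv <- rownames(unclass(object))
  df$truth <- factor(df$truth, levels = rev(lv))
  df$predicted <- factor(df$predicted, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_fill_viridis_c(name = "n") +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = "LOOCV confusion matrix") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.osa_eval <- function(object, ...) autoplot(object$confusion, ...)
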