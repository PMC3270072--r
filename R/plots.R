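#' Plot a rate table
#'
#' Viability rate against network size with the binomial confidence band, one
#' curve per regime/mode/operator present in the table.
#'
#' @param object A `grn_rate_table` from one of the experiment runners.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_rate_table <- function(object, ...) {
  grp <- intersect(c("mode", "op", "arm", "regime"), names(object))
  grp <- if (length(grp)) grp[1] else NULL
  aes_line <- if (is.null(grp))
    ggplot2::aes(x = .data$n, y = .data$rate)
  else
    ggplot2::aes(x = .data$n, y = .data$rate, colour = .data[[grp]],
                 fill = .data[[grp]], group = .data[[grp]])
  p <- ggplot2::ggplot(object, aes_line)
  if (all(c("ci_low", "ci_high") %in% names(object)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2, colour = NA)
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, NA)) +
    ggplot2::labs(x = "genes in network", y = "viable fraction",
                  title = attr(object, "experiment")) +
    ggplot2::theme_minimal()
}

#' Plot a developmental trajectory's convergence statistic
#'
#' @param object A `grn_development` from [develop()] run with
#'   `keep_phi = TRUE`.
#' @param ... Unused.
#' @return A ggplot object showing the convergence statistic per step on a log
#'   scale, with the stability threshold as a horizontal line.
#' @export
autoplot.grn_development <- function(object, ...) {
  if (is.null(object$phi_history))
    abort("Run `develop(..., keep_phi = TRUE)` to record the statistic.")
  tau <- object$params$tau
  df <- tibble(step = seq_along(object$phi_history) + tau - 1,
               phi = object$phi_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$sigma, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "developmental step", y = "convergence statistic",
                  subtitle = if (object$viable)
                    sprintf("viable, path length %d", object$path_length)
                  else "not viable") +
    ggplot2::theme_minimal()
}
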