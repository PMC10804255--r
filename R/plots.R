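#' Plot interval-floor PPV curves
#'
#' One line per stratum of PPV against the interval floor, with the
#' benchmark drawn as a dashed line and the first floor reaching it marked
#' and labeled per stratum.
#'
#' @param object An `sa_floor_curve` from [interval_floor_curve()] or
#'   [interval_floor_curves()].
#' @param benchmark Optional PPV benchmark to annotate.
#' @param min_n Hide floors supported by fewer than this many pairs.
#' @param max_floor Optional upper limit for the x axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sa_floor_curve <- function(object, benchmark = NULL, min_n = 1,
                                    max_floor = NULL, ...) {
  df <- as_tibble(object)
  df <- df[df$n_pairs >= min_n, , drop = FALSE]
  if (!is.null(max_floor)) df <- df[df$floor <= max_floor, , drop = FALSE]
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$floor, y = .data$ppv, colour = .data$stratum)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Interval floor (days)",
      y = "PPV for a distinct attempt (pairs with interval ≥ floor)",
      colour = "Code-pair stratum"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(benchmark)) {
    marks <- df |>
      group_by(.data$stratum) |>
      filter(.data$ppv >= benchmark) |>
      dplyr::slice_min(.data$floor, n = 1, with_ties = FALSE) |>
      ungroup()
    p <- p +
      ggplot2::geom_hline(
        yintercept = benchmark, linetype = "dashed", colour = "grey40"
      )
    if (nrow(marks) > 0) {
      p <- p +
        ggplot2::geom_point(data = marks, size = 2) +
        ggplot2::geom_text(
          data = marks,
          ggplot2::aes(label = paste0(.data$floor, " d")),
          vjust = -0.8, show.legend = FALSE, size = 3
        )
    }
  }
  p
}

#' @rdname autoplot.sa_floor_curve
#' @export
autoplot.sa_rule <- function(object, ...) {
  if (is.null(object$curves)) {
    abort("This rule was built by hand; no derivation curves to plot.")
  }
  autoplot(object$curves, benchmark = object$benchmark, ...)
}
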