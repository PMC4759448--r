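#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a meristogram into long format
#'
#' @param x A [meristogram()].
#' @param ... Unused.
#' @return A tibble with columns `label`, `variable` (`L`/`B`/`A`/`R`),
#'   `position` and `value`, one row per curve point per variable.
#' @export
tidy.meristogram <- function(x, ...) {
  lbl <- attr(x, "label")
  long <- tidyr::pivot_longer(curve_points(x), cols = c("L", "B", "A", "R"),
                              names_to = "variable", values_to = "value")
  long <- mutate(long, label = lbl,
                 variable = factor(.data$variable,
                                   levels = c("L", "B", "A", "R")))
  select(arrange(long, .data$variable, .data$x),
         "label", "variable", position = "x", "value")
}

#' One-row summary of a meristogram
#'
#' @param x A [meristogram()].
#' @param ... Unused.
#' @return A tibble with the label, moving-average interval, interpolation
#'   flag, numbers of curve points, rows and hooks, and per-variable peak
#'   positions (`peak_L` ... `peak_R`).
#' @export
glance.meristogram <- function(x, ...) {
  pk <- peak_positions(x)
  out <- tibble(label = attr(x, "label"), mai = attr(x, "mai"),
                interpolated = attr(x, "interpolated"),
                n_points = nrow(x), n_rows = attr(x, "n_rows"),
                n_hooks = attr(x, "n_hooks"))
  for (v in pk$variable) {
    out[[paste0("peak_", v)]] <- pk$position[pk$variable == v]
  }
  out
}

#' Plot a meristogram
#'
#' Draws the four standardized curves (blade length L, base width B, area
#' A, robustness ratio R) against percent-position, both axes on the 0-100
#' percent scale.
#'
#' @param object A [meristogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meristogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$value,
                               colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "Percent-position (distal → proximal)",
                  y = "Percent-max-collection-value",
                  colour = NULL,
                  title = attr(object, "label"),
                  subtitle = sprintf("MAI %d%%%s", attr(object, "mai"),
                                     if (isTRUE(attr(object, "interpolated")))
                                       ", interpolated" else "")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
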