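#' Render the fluid/gas interface chart as SVG
#'
#' Draws the chart a patient lines the interface out on: a circle
#' representing the vitreous cavity with a horizontal chord at the stated
#' fractional height from the top and the superior gas region shaded.
#' The SVG markup is composed directly, so output is byte-identical for
#' identical input.
#'
#' @param h_pct Interface height, percent of the vertical extent occupied
#'   by gas, in \[0, 100\].
#' @param path Optional output path; when given the SVG is written there.
#' @param size Image side length in pixels.
#' @return The SVG document as a single character string (invisibly when
#'   `path` is given).
#' @examples
#' svg <- render_interface_chart(50)
#' @export
render_interface_chart <- function(h_pct, path = NULL, size = 240) {
  check_number(h_pct, "h_pct", lower = 0, upper = 100)
  cx <- size / 2
  cy <- size / 2
  r <- size * 0.4
  y0 <- cy - r + 2 * r * h_pct / 100
  shade <- if (h_pct <= 0) {
    ""
  } else if (h_pct >= 100) {
    sprintf('  <circle cx="%.2f" cy="%.2f" r="%.2f" fill="#b8d4e8"/>\n',
            cx, cy, r)
  } else {
    # superior segment: arc through the top pole between the chord ends
    w <- sqrt(r^2 - (y0 - cy)^2)
    large <- if (h_pct > 50) 1L else 0L
    sprintf(paste0('  <path d="M %.2f %.2f A %.2f %.2f 0 %d 1 %.2f %.2f Z"',
                   ' fill="#b8d4e8"/>\n'),
            cx - w, y0, r, r, large, cx + w, y0)
  }
  chord <- if (h_pct > 0 && h_pct < 100) {
    w <- sqrt(r^2 - (y0 - cy)^2)
    sprintf(paste0('  <line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f"',
                   ' stroke="#2c5f8a" stroke-width="2"/>\n'),
            cx - w, y0, cx + w, y0)
  } else ""
  svg <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">\n',
            size, size, size, size),
    shade,
    sprintf('  <circle cx="%.2f" cy="%.2f" r="%.2f" fill="none" stroke="#333" stroke-width="2"/>\n',
            cx, cy, r),
    chord,
    sprintf('  <text x="%.2f" y="%d" text-anchor="middle" font-family="sans-serif" font-size="14">%s%% gas</text>\n',
            cx, size - 6, format(h_pct)),
    '</svg>\n')
  if (!is.null(path)) {
    writeLines(svg, path, sep = "")
    return(invisible(svg))
  }
  svg
}

#' ggplot2 view of the interface chart
#'
#' Companion to [render_interface_chart()] for interactive use: the same
#' circle-and-chord chart as a ggplot object.
#'
#' @inheritParams render_interface_chart
#' @return A ggplot object.
#' @export
plot_interface_chart <- function(h_pct) {
  check_number(h_pct, "h_pct", lower = 0, upper = 100)
  theta <- seq(0, 2 * pi, length.out = 361)
  circle <- tibble(x = cos(theta), y = sin(theta))
  y0 <- 1 - 2 * h_pct / 100  # chord height, circle coords (top = +1)
  gas <- if (h_pct > 0) {
    keep <- circle$y >= y0
    seg <- circle[keep, , drop = FALSE]
    w <- sqrt(max(0, 1 - y0^2))
    dplyr::bind_rows(tibble(x = c(-w, w), y = c(y0, y0))[order(c(-w, w)), ],
                     seg[order(atan2(seg$y, seg$x)), ])
  } else NULL
  p <- ggplot2::ggplot() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(gas) && nrow(gas) > 2) {
    hull <- gas[grDevices::chull(gas$x, gas$y), ]
    p <- p + ggplot2::geom_polygon(data = hull,
                                   ggplot2::aes(.data$x, .data$y),
                                   fill = "#b8d4e8")
  }
  p +
    ggplot2::geom_path(data = circle, ggplot2::aes(.data$x, .data$y),
                       linewidth = 0.8, colour = "#333333") +
    ggplot2::geom_hline(yintercept = y0, colour = "#2c5f8a") +
    ggplot2::labs(title = sprintf("%s%% gas fill", format(h_pct)))
}
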