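#' Plot a dependency matrix as a colour-coded grid
#'
#' One tile per (marker, deletion); fill encodes the relative difference
#' of the deletion arm against its co-imaged controls (green = significant
#' increase, red = decrease), with called entries outlined.
#'
#' @param object A `poldep_matrix`.
#' @param compartment Which compartment to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poldep_matrix <- function(object, compartment = "end1", ...) {
  e <- filter(object$entries, .data$compartment == !!compartment)
  lim <- max(abs(e$rel_diff), 0.2)
  ggplot2::ggplot(e, ggplot2::aes(x = .data$deletion, y = .data$marker)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$rel_diff), colour = "grey80") +
    ggplot2::geom_tile(data = filter(e, .data$call != "ns"),
                       fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "red3", mid = "white",
                                  high = "green4", limits = c(-lim, lim),
                                  oob = scales_squish) +
    ggplot2::labs(x = "deleted gene", y = "GFP marker",
                  fill = "relative\ndifference",
                  title = paste0("dependency matrix (", compartment, ")")) +
    ggplot2::theme_minimal()
}

# minimal squish so we do not depend on scales directly
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force(range)
  x[x < range[1]] <- range[1]
  x[x > range[2]] <- range[2]
  x
}

#' Plot the signed dependency network
#'
#' Circular layout; green arrows are positive regulations (upstream
#' protein required for polar localisation), red arrows negative
#' (upstream protein limits polar signal), blue arrows mark NETO-shift
#' dependencies.
#'
#' @param object A `poldep_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poldep_network <- function(object, ...) {
  nodes <- object$nodes
  n <- length(nodes)
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  pos <- tibble(name = nodes, x = cos(ang), y = sin(ang))
  e <- object$edges
  e <- left_join(e, rename(pos, x0 = "x", y0 = "y"),
                 by = c(source = "name"))
  e <- left_join(e, rename(pos, x1 = "x", y1 = "y"),
                 by = c(target = "name"))
  e <- mutate(e, colour = ifelse(.data$neto, "NETO",
                                 ifelse(.data$sign == "+", "positive",
                                        "negative")),
              # stop arrows short of the node label
              xs = .data$x0 + 0.12 * (.data$x1 - .data$x0),
              ys = .data$y0 + 0.12 * (.data$y1 - .data$y0),
              xe = .data$x1 - 0.12 * (.data$x1 - .data$x0),
              ye = .data$y1 - 0.12 * (.data$y1 - .data$y0))
  ggplot2::ggplot() +
    ggplot2::geom_curve(data = e,
                        ggplot2::aes(x = .data$xs, y = .data$ys,
                                     xend = .data$xe, yend = .data$ye,
                                     colour = .data$colour),
                        curvature = 0.15,
                        arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"),
                                               type = "closed")) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       fontface = "bold") +
    ggplot2::scale_colour_manual(values = c(positive = "green4",
                                            negative = "red3",
                                            NETO = "blue")) +
    ggplot2::coord_equal(xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "regulation")
}

#' Display a field projection with its ground-truth cell outlines
#'
#' @param fs A finalized [field_stack()].
#' @param channel `"gfp"` or `"red"`.
#' @return A ggplot raster of the maximum projection with annotated pole
#'   positions overlaid when available.
#' @export
plot_field <- function(fs, channel = c("gfp", "red")) {
  channel <- match.arg(channel)
  proj <- max_project(fs, channel)
  ps <- fs$pixel_size_xy
  df <- tibble(
    x = rep((seq_len(ncol(proj)) - 0.5) * ps, each = nrow(proj)),
    y = rep((seq_len(nrow(proj)) - 0.5) * ps, times = ncol(proj)),
    value = as.vector(proj)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black",
                                 high = if (channel == "gfp") "green"
                                        else "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "intensity",
                  title = fs$field_id) +
    ggplot2::theme_minimal()
  if (nrow(fs$cells)) {
    pts <- tidyr::pivot_longer(
      select(fs$cells, "cell_id", "pole1_x", "pole1_y", "pole2_x",
             "pole2_y"),
      cols = -"cell_id",
      names_to = c("pole", ".value"), names_pattern = "(pole[12])_(.)"
    )
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(.data$x, .data$y),
                                 colour = "white", shape = 3, size = 1)
  }
  p
}
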