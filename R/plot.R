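#' Discrete identity bins
#'
#' Maps identity values in `[t, 100]` onto `bins` equal-width bins; the
#' value `t` falls in the lowest bin and 100 in the highest. Values of 0
#' (below threshold) return `NA` (uncolored).
#'
#' @param values Numeric vector of percent identities.
#' @param t Identity threshold.
#' @param bins Number of bins (>= 2).
#' @return Integer bin indices in `1..bins`, `NA` for uncolored cells.
#' @export
bin_identity <- function(values, t, bins = 11) {
  stopifnot(bins >= 2, t < 100)
  breaks <- seq(t, 100, length.out = bins + 1)
  out <- findInterval(values, breaks, rightmost.closed = TRUE)
  out[values <= 0 | values < t] <- NA_integer_
  pmin(out, bins)
}

#' Named identity-heatmap palettes
#'
#' Sequential perceptually uniform defaults plus two high-contrast presets
#' for colorblind or visually impaired users. Any palette name understood by
#' [grDevices::hcl.colors()] is also accepted, as is an explicit vector of
#' colors (hex or named) of length `bins`.
#'
#' @param palette Palette name or explicit color vector.
#' @param bins Number of colors wanted.
#' @return Character vector of `bins` colors, low identity first.
#' @export
identity_palette <- function(palette = "viridis", bins = 11) {
  if (length(palette) > 1) {
    if (length(palette) != bins) {
      stop("explicit palette must supply exactly ", bins, " colors",
           call. = FALSE)
    }
    return(palette)
  }
  preset <- switch(tolower(palette),
    "viridis" = "Viridis",
    "inferno" = "Inferno",
    "mako" = "Mako",
    "high_contrast" = "Blue-Red",
    "high_contrast2" = "Tropic",
    palette)
  rev(grDevices::hcl.colors(bins, preset))
}

# axis labels in bases with SI prefixes (1.5 Mbp, 20 kbp, ...)
label_bases <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (abs(v) >= 1e9) paste0(format(v / 1e9, digits = 3), " Gbp")
    else if (abs(v) >= 1e6) paste0(format(v / 1e6, digits = 3), " Mbp")
    else if (abs(v) >= 1e3) paste0(format(v / 1e3, digits = 3), " kbp")
    else paste0(v, " bp")
  }, character(1))
}

bin_labels <- function(t, bins) {
  breaks <- seq(t, 100, length.out = bins + 1)
  sprintf("%s-%s", formatC(breaks[-(bins + 1)], format = "g", digits = 4),
          formatC(breaks[-1], format = "g", digits = 4))
}

#' Plot an identity matrix as a heatmap
#'
#' Renders the identity heatmap with discrete bins from the threshold `t` to
#' 100; sub-threshold cells are left uncolored (background). `style =
#' "triangular"` rotates the upper triangle of a self plot 45 degrees so the
#' diagonal becomes the baseline; it is invalid for comparative matrices.
#' Plotting never alters the matrix values.
#'
#' @param object An `identity_matrix`.
#' @param bins Number of identity bins (default 11).
#' @param palette Palette name or color vector (see [identity_palette()]).
#' @param style `"square"` (default) or `"triangular"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot identity_matrix
#' @export
autoplot.identity_matrix <- function(object, bins = 11, palette = "viridis",
                                     style = c("square", "triangular"), ...) {
  style <- match.arg(style)
  if (style == "triangular" && !object$self_plot) {
    stop("triangular style is only valid for self-identity plots",
         call. = FALSE)
  }
  cells <- tidy(object)
  cells$bin <- factor(bin_identity(cells$identity, object$t, bins),
                      levels = seq_len(bins))
  cols <- identity_palette(palette, bins)
  fill_scale <- ggplot2::scale_fill_manual(
    values = setNames(cols, seq_len(bins)),
    labels = setNames(bin_labels(object$t, bins), seq_len(bins)),
    name = "% identity", drop = FALSE, na.translate = FALSE)

  if (style == "square") {
    p <- ggplot2::ggplot(cells) +
      ggplot2::geom_tile(ggplot2::aes(
        x = (.data$x_start + .data$x_end) / 2,
        y = (.data$y_start + .data$y_end) / 2,
        width = .data$x_end - .data$x_start,
        height = .data$y_end - .data$y_start,
        fill = .data$bin)) +
      ggplot2::scale_y_continuous(labels = label_bases) +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::labs(x = object$x_name, y = object$y_name)
  } else {
    upper <- dplyr::filter(cells, .data$y_start >= .data$x_start)
    upper$id <- seq_len(nrow(upper))
    corners <- tidyr::expand_grid(id = upper$id, corner = 1:4)
    corners <- dplyr::left_join(corners, upper, by = "id")
    cx <- ifelse(corners$corner %in% c(1, 4), corners$x_start, corners$x_end)
    cy <- ifelse(corners$corner %in% c(1, 2), corners$y_start, corners$y_end)
    corners$px <- (cx + cy) / 2
    corners$py <- (cy - cx) / 2
    p <- ggplot2::ggplot(corners) +
      ggplot2::geom_polygon(ggplot2::aes(x = .data$px, y = .data$py,
                                         group = .data$id, fill = .data$bin)) +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::labs(x = object$x_name, y = NULL) +
      ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                     axis.ticks.y = ggplot2::element_blank())
  }
  p + fill_scale +
    ggplot2::scale_x_continuous(labels = label_bases) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @rdname autoplot.identity_matrix
#' @param m An `identity_matrix`.
#' @export
plot_identity <- function(m, bins = 11, palette = "viridis",
                          style = "square", ...) {
  autoplot.identity_matrix(m, bins = bins, palette = palette, style = style,
                           ...)
}

#' Render an identity heatmap to an image file
#'
#' @param m An `identity_matrix`.
#' @param path Output path ending in `.png` or `.pdf`.
#' @inheritParams autoplot.identity_matrix
#' @param width,height,dpi Device size (inches) and resolution.
#' @return `path`, invisibly.
#' @export
render_static <- function(m, path, bins = 11, palette = "viridis",
                          style = "square", width = 7, height = 6, dpi = 150) {
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "pdf")) {
    stop("output format must be png or pdf, got '", fmt, "'", call. = FALSE)
  }
  p <- autoplot.identity_matrix(m, bins = bins, palette = palette,
                                style = style)
  suppressMessages(ggplot2::ggsave(path, plot = p, width = width,
                                   height = height, dpi = dpi))
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
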