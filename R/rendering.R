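#' Rendering style for trajectory maps
#'
#' Collects the tunable figure parameters. Anything left \code{NULL} is
#' resolved automatically from the map by \code{\link{resolve_style}}:
#' shift and average maps get a sequential colour scale from 0 to the
#' maximum shift; difference maps get a divergent blue-white-red scale
#' symmetric about zero, so zero always sits on the colormap midpoint.
#'
#' @param z_min,z_max colour-scale bounds (angstrom); values outside are
#'   clipped to the scale ends
#' @param colormap palette name passed to \code{grDevices::hcl.colors}
#'   (e.g. \code{"Viridis"}, \code{"Blue-Red 3"})
#' @param divergent force a divergent scale symmetric about zero
#' @param x_tick_step,y_tick_step tick spacing in frames / residue serials
#' @param y_annotations optional list of \code{list(range, label)} entries
#'   (range in region syntax, e.g. \code{"30-40"}) drawn as labels on the
#'   right of the map — e.g. secondary-structure assignments
#' @param overlay optional \code{\link{rmsd_series}} drawn as a white line
#'   against a secondary right-hand axis (it never rescales the colour
#'   mapping)
#' @param title,xlab,ylab figure strings
#' @param dpi raster resolution (default 300)
#' @return object of class \code{map_style}
#' @export
map_style <- function(z_min = NULL, z_max = NULL, colormap = NULL,
                      divergent = NULL, x_tick_step = NULL,
                      y_tick_step = NULL, y_annotations = NULL,
                      overlay = NULL, title = "",
                      xlab = "frame", ylab = "residue", dpi = 300) {
  structure(list(z_min = z_min, z_max = z_max, colormap = colormap,
                 divergent = divergent, x_tick_step = x_tick_step,
                 y_tick_step = y_tick_step, y_annotations = y_annotations,
                 overlay = overlay, title = title, xlab = xlab, ylab = ylab,
                 dpi = dpi),
            class = "map_style")
}

# anchored tick sequence: serial axis anchors at 1, frame axis at 0
.tick_seq <- function(anchor, upper, step) {
  if (step >= upper - anchor + 1) return(anchor)
  first <- if (anchor == 1L) step else anchor + step
  unique(c(anchor, seq(first, upper, by = step)))
}

.auto_step <- function(n) {
  target <- n / 6
  steps <- c(1, 2, 5, 10, 20, 25, 50, 100, 200, 250, 500, 1000, 2000, 5000)
  steps[which.min(abs(steps - target))]
}

#' Resolve all automatic style decisions for a map
#'
#' Pure, deterministic helper behind \code{\link{render_map}}: computes
#' the concrete colour-scale bounds, colormap, divergence flag, tick
#' positions and annotation placements that rendering will use, without
#' touching a graphics device.
#'
#' @param map a \code{\link{shift_matrix}}
#' @param style a \code{\link{map_style}}
#' @return list with \code{z_min}, \code{z_max}, \code{divergent},
#'   \code{colormap}, \code{colors}, \code{x_ticks} (0-based frames),
#'   \code{y_ticks} (serials), \code{annotations}
#' @export
resolve_style <- function(map, style = map_style()) {
  validate_shift_matrix(map)
  divergent <- if (!is.null(style$divergent)) isTRUE(style$divergent)
               else map$kind == "difference"
  zr <- range(map$values)
  z_min <- style$z_min; z_max <- style$z_max
  if (!is.null(z_min) && !is.null(z_max)) {
    if (z_min >= z_max)
      stop(sprintf("style error: z_min (%g) must be below z_max (%g)",
                   z_min, z_max), call. = FALSE)
  } else if (divergent) {
    # symmetric about zero unless both bounds are set explicitly
    m <- max(abs(zr), abs(z_min %||% 0), abs(z_max %||% 0))
    if (m == 0) m <- 1  # all-zero difference map: degenerate [-1, 1] scale
    z_min <- -m; z_max <- m
  } else {
    if (is.null(z_min)) z_min <- min(0, zr[1])
    if (is.null(z_max)) z_max <- max(zr[2], 0)
    if (z_max <= z_min) z_max <- z_min + 1  # all-zero map: [0, 1] fallback
  }
  colormap <- style$colormap %||% if (divergent) "Blue-Red 3" else "Viridis"
  colors <- grDevices::hcl.colors(256L, colormap,
                                  rev = identical(colormap, "Blue-Red 3"))
  n_frames <- length(map$frame_axis)
  n_res <- length(map$residue_serials)
  x_step <- style$x_tick_step %||% .auto_step(n_frames)
  y_step <- style$y_tick_step %||% .auto_step(n_res)
  ann <- NULL
  if (!is.null(style$y_annotations)) {
    ann <- lapply(style$y_annotations, function(a) {
      rs <- if (inherits(a[[1]], "region_spec")) a[[1]] else region_spec(a[[1]])
      list(at = mean(range(rs$ranges)), label = a[[2]])
    })
  }
  list(z_min = z_min, z_max = z_max, divergent = divergent,
       colormap = colormap, colors = colors,
       x_ticks = .tick_seq(0L, max(map$frame_axis), x_step),
       y_ticks = .tick_seq(1L, max(map$residue_serials), y_step),
       annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.open_png <- function(path, width, height, dpi) {
  tryCatch(grDevices::png(path, width = width, height = height,
                          units = "in", res = dpi),
           error = function(e)
             stop(sprintf("I/O error: cannot open '%s' for writing (%s)",
                          path, conditionMessage(e)), call. = FALSE))
}

#' Render a trajectory map as a heatmap
#'
#' Frames on the x axis (simulation time), residue serials on the y axis
#' (serial 1 at the bottom), shift magnitude colour-coded on the z axis
#' with a labelled colour bar in angstroms. Difference maps automatically
#' get a divergent scale with white at zero. An optional RMSD overlay is
#' drawn as a white line against its own right-hand axis.
#'
#' @param map a \code{\link{shift_matrix}}
#' @param style a \code{\link{map_style}}
#' @param out_path output PNG path
#' @return invisibly, the resolved style (see \code{\link{resolve_style}})
#' @export
render_map <- function(map, style = map_style(), out_path) {
  rs <- resolve_style(map, style)
  .open_png(out_path, width = 8, height = 5, dpi = style$dpi)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, nrow = 1), widths = c(6, 1))

  z <- pmin(pmax(t(map$values), rs$z_min), rs$z_max)
  has_ann <- !is.null(rs$annotations)
  graphics::par(mar = c(4, 4, 2.5, if (has_ann || !is.null(style$overlay)) 4 else 1))
  graphics::image(x = map$frame_axis, y = map$residue_serials, z = z,
                  zlim = c(rs$z_min, rs$z_max), col = rs$colors,
                  axes = FALSE, xlab = style$xlab, ylab = style$ylab,
                  main = style$title, useRaster = TRUE)
  graphics::axis(1, at = rs$x_ticks)
  graphics::axis(2, at = rs$y_ticks, las = 1)
  graphics::box()
  if (has_ann)
    for (a in rs$annotations)
      graphics::axis(4, at = a$at, labels = a$label, las = 1, tick = TRUE,
                     cex.axis = 0.7)
  if (!is.null(style$overlay)) {
    ov <- style$overlay
    graphics::par(new = TRUE)
    graphics::plot(map$frame_axis, ov$values, type = "l", col = "white",
                   lwd = 1.5, axes = FALSE, xlab = "", ylab = "",
                   ylim = c(0, max(ov$values) * 1.05 + 1e-12))
    graphics::axis(4, col.axis = "grey30", line = if (has_ann) 2 else 0)
    graphics::mtext("RMSD (Å)", side = 4, line = if (has_ann) 4 else 2,
                    cex = 0.8)
  }

  # colour bar
  graphics::par(mar = c(4, 0.8, 2.5, 2.5))
  grad <- seq(rs$z_min, rs$z_max, length.out = 256)
  graphics::image(x = 1, y = grad, z = matrix(grad, nrow = 1),
                  zlim = c(rs$z_min, rs$z_max), col = rs$colors,
                  axes = FALSE, xlab = "", ylab = "", useRaster = TRUE)
  graphics::axis(4, las = 1, cex.axis = 0.8)
  graphics::mtext("shift (Å)", side = 3, line = 0.3, cex = 0.7)
  graphics::box()
  invisible(rs)
}

#' Resolve the plot data of a shift graph
#'
#' Pure helper behind \code{\link{render_shift_graph}}: smooths each
#' series (when a window is given) and returns the labelled raw/smoothed
#' curves and the y range that will be drawn.
#'
#' @param series a \code{\link{shift_series}} or a list of them
#' @param window moving-average window in frames (\code{NULL} to keep any
#'   smoothing already on the series)
#' @return list with \code{series} (each: \code{label}, \code{frame_axis},
#'   \code{raw}, \code{smoothed}) and \code{ylim}
#' @export
resolve_shift_graph <- function(series, window = NULL) {
  if (inherits(series, "shift_series")) series <- list(series)
  out <- lapply(series, function(s) {
    if (!is.null(window)) s <- moving_average(s, window)
    list(label = s$region$label, frame_axis = s$frame_axis,
         raw = s$values, smoothed = s$smoothed %||% s$values)
  })
  rng <- range(unlist(lapply(out, function(s) range(s$raw))))
  pad <- max(diff(rng) * 0.05, 0.05)
  list(series = out, ylim = c(rng[1] - pad, rng[2] + pad))
}

#' Render a shift graph
#'
#' Line plot of one or more region shift series: the raw series drawn
#' light with the centered moving average superposed in bold, y axis in
#' angstroms (the map's colour scale promoted to an axis), legend from
#' the region labels.
#'
#' @inheritParams resolve_shift_graph
#' @param out_path output PNG path
#' @param dpi raster resolution
#' @return invisibly, the resolved plot data
#' @export
render_shift_graph <- function(series, window = NULL, out_path, dpi = 300) {
  rg <- resolve_shift_graph(series, window)
  .open_png(out_path, width = 7, height = 4, dpi = dpi)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(max(2L, length(rg$series)), "Dark 3")
  graphics::par(mar = c(4, 4, 1.5, 1))
  fa <- rg$series[[1]]$frame_axis
  graphics::plot(NA, xlim = range(fa), ylim = rg$ylim,
                 xlab = "frame", ylab = "shift (Å)")
  for (i in seq_along(rg$series)) {
    s <- rg$series[[i]]
    graphics::lines(s$frame_axis, s$raw,
                    col = grDevices::adjustcolor(pal[i], alpha.f = 0.35))
    graphics::lines(s$frame_axis, s$smoothed, col = pal[i], lwd = 2)
  }
  graphics::legend("topleft",
                   legend = vapply(rg$series, `[[`, "", "label"),
                   col = pal[seq_along(rg$series)], lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(rg)
}
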