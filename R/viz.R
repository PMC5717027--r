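#' Polygon representation of a positive vector
#'
#' Places component `j` of an `m`-dimensional vector at radius `v[j]` on the
#' half-axis at angle `2*pi*(j-1)/m` and connects consecutive vertices,
#' turning any positive vector (e.g. a four-note phrase of frequencies) into
#' a planar polygon.
#'
#' @param v Numeric vector with all components > 0.
#' @return An object of class `polygon_repr`: list with `vertices` (m x 2
#'   matrix of `(x, y)` points) and `radii`.
#' @examples
#' polygon_coords(c(392, 440, 493.88, 392))
#' @export
polygon_coords <- function(v) {
  check_finite(v, "vector v")
  if (any(v <= 0)) stop_invalid("polygon representation needs all components > 0")
  m <- length(v)
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  structure(list(vertices = cbind(x = v * cos(ang), y = v * sin(ang)),
                 radii = v),
            class = "polygon_repr")
}

#' @export
print.polygon_repr <- function(x, ...) {
  cat(sprintf("<polygon_repr> %d vertices, radii: %s\n",
              nrow(x$vertices), paste(signif(x$radii, 5), collapse = ", ")))
  invisible(x)
}

#' Plot a 1-D landscape, optionally against its asymptotic target
#'
#' @param L A 1-D landscape (grid or mesh-free).
#' @param target Optional second landscape (e.g. from
#'   [asymptotic_landscape()]) drawn dashed for comparison.
#' @param n_points Evaluation points for mesh-free landscapes.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, a data frame of the plotted curve (`x`, `value`).
#' @export
plot_landscape_1d <- function(L, target = NULL, n_points = 400L, ...) {
  box <- landscape_box(L)[[1L]]
  x <- seq(box[1L], box[2L], length.out = n_points)
  v <- landscape_values(L, x)
  graphics::plot(x, v, type = "l", xlab = "stimulus x", ylab = "V(x)", ...)
  if (!is.null(target)) {
    graphics::lines(x, landscape_values(target, x), lty = 2, col = "grey40")
  }
  invisible(data.frame(x = x, value = v))
}

#' Plot phrase minima as stacked polygons
#'
#' Draws one polygon per minimum of a vector landscape, deepest drawn last
#' (on top), each scaled to a common frame — the planar "sight" of the
#' memorised phrases.
#'
#' @param minima A `minima_set` over positive vectors.
#' @param labels Optional labels per minimum.
#' @return Invisibly, the list of [polygon_coords()] objects.
#' @export
plot_polygons <- function(minima, labels = NULL) {
  locs <- minima_locations(minima)
  polys <- lapply(seq_len(nrow(locs)), function(i) polygon_coords(locs[i, ]))
  r <- max(vapply(polys, function(p) max(p$radii), numeric(1L)))
  graphics::plot(NA, xlim = c(-r, r) * 1.1, ylim = c(-r, r) * 1.1, asp = 1,
                 xlab = "", ylab = "", axes = FALSE)
  graphics::abline(h = 0, v = 0, col = "grey85")
  cols <- grDevices::hcl.colors(nrow(locs), "Zissou 1")
  for (i in rev(seq_along(polys))) {  # deepest (row 1) drawn last, on top
    vv <- polys[[i]]$vertices
    graphics::polygon(vv[, 1L], vv[, 2L], border = cols[i], lwd = 2)
  }
  if (!is.null(labels)) {
    graphics::legend("topright", legend = labels, col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(polys)
}

#' Space-time picture of a learning 1-D landscape
#'
#' Replays the stimulus stream through the exact U-form integrator, storing
#' V snapshots at regular intervals, and draws them as an image in the
#' `(x, t)` plane with the stimulus samples overlaid as dots.
#'
#' @param stim A scalar [stimulus_series()].
#' @param kernel A [foam_kernel()].
#' @param k Elasticity factor.
#' @param n_snapshots Number of stored snapshots.
#' @param n_nodes Grid nodes.
#' @param plot Draw the image (set `FALSE` to only return the data).
#' @return Invisibly, a list with `x` (nodes), `t` (snapshot times) and `V`
#'   (nodes x snapshots matrix) — the CSV-able twin of the figure.
#' @export
landscape_movie_1d <- function(stim, kernel, k = 0, n_snapshots = 60L,
                               n_nodes = 301L, plot = TRUE) {
  if (stimulus_dim(stim) != 1L) stop_invalid("scalar stimulus required")
  bounds <- default_bounds(stim$values, kernel$sigma_z)
  L <- grid_landscape(bounds, n_nodes, kernel, k = k, form = "U")
  n <- n_samples(stim)
  snap_at <- unique(pmax(1L, round(seq_len(n_snapshots) * n / n_snapshots)))
  V <- matrix(NA_real_, n_nodes, length(snap_at))
  tt <- numeric(length(snap_at))
  si <- 1L
  for (i in seq_len(n)) {
    L <- step_u(L, stim$values[i, ], stim$dt)
    if (si <= length(snap_at) && i == snap_at[si]) {
      V[, si] <- u_to_v(L)$values
      tt[si] <- L$time
      si <- si + 1L
    }
  }
  if (plot) {
    graphics::image(L$axes[[1L]], tt, V, xlab = "stimulus x", ylab = "time (s)",
                    col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE))
    graphics::points(stim$values[, 1L], stimulus_times(stim), pch = 16,
                     cex = 0.2, col = grDevices::adjustcolor("black", 0.3))
  }
  invisible(list(x = L$axes[[1L]], t = tt, V = V))
}
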