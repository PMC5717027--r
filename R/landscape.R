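#' Grid-discretised plastic energy landscape
#'
#' The evolving scalar field on a regular grid, in either the raw `U` form
#' (which acquires a linear downward trend in time) or the de-trended
#' `V = U / t` form. The grid form is supported in one and two dimensions;
#' higher-dimensional landscapes use the exact mesh-free form
#' ([meshfree_landscape()]), since grid memory grows exponentially with
#' dimension.
#'
#' @param bounds Numeric vector `c(lo, hi)` for 1-D, or a list of such vectors
#'   (one per axis) for 2-D.
#' @param n_nodes Nodes per axis (recycled across axes).
#' @param kernel A [foam_kernel()] whose `dim` matches the number of axes.
#' @param k Elasticity (forgetting) factor, 1/s; `k = 0` never forgets.
#' @param form `"U"` or `"V"`.
#' @param values Initial field values (defaults to the flat landscape, 0).
#' @param time Current time, seconds.
#' @return An object of class `grid_landscape`.
#' @seealso [step_u()], [step_v()], [u_to_v()], [meshfree_landscape()]
#' @export
grid_landscape <- function(bounds, n_nodes, kernel, k = 0, form = c("U", "V"),
                           values = NULL, time = 0) {
  form <- match.arg(form)
  if (!is.list(bounds)) bounds <- list(bounds)
  m <- length(bounds)
  if (m > 2L) stop_invalid("grid landscapes support 1 or 2 dimensions; use the mesh-free form")
  if (kernel$dim != m) stop_invalid("kernel dim must match number of grid axes")
  n_nodes <- rep_len(as.integer(n_nodes), m)
  for (j in seq_len(m)) {
    b <- bounds[[j]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L]) {
      stop_invalid("each bounds entry must be a finite c(lo, hi) with lo < hi")
    }
    if (n_nodes[j] < 2L) stop_invalid("need at least 2 nodes per axis")
  }
  axes <- lapply(seq_len(m), function(j) {
    seq(bounds[[j]][1L], bounds[[j]][2L], length.out = n_nodes[j])
  })
  if (is.null(values)) {
    values <- if (m == 1L) numeric(n_nodes[1L]) else
      matrix(0, n_nodes[1L], n_nodes[2L])
  }
  check_finite(values, "landscape values")
  if (k < 0) stop_invalid("elasticity k must be >= 0")
  structure(list(bounds = bounds, n_nodes = n_nodes, axes = axes,
                 values = values, kernel = kernel, k = k, form = form,
                 time = time),
            class = "grid_landscape")
}

#' @export
print.grid_landscape <- function(x, ...) {
  cat(sprintf("<grid_landscape> form %s, %s nodes, t = %g s, k = %g, sigma_z = %g\n",
              x$form, paste(x$n_nodes, collapse = " x "), x$time, x$k,
              x$kernel$sigma_z))
  cat(sprintf("  range of values: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname grid_landscape
#' @param x A `grid_landscape`.
#' @export
landscape_dim <- function(x) UseMethod("landscape_dim")

#' @export
landscape_dim.grid_landscape <- function(x) length(x$bounds)

#' @export
landscape_dim.meshfree_landscape <- function(x) x$kernel$dim

# Kernel dent evaluated on the whole grid, centred at eta.
grid_dent <- function(L, eta) {
  m <- landscape_dim(L)
  check_finite(eta, "stimulus eta")
  if (length(eta) != m) stop_invalid("eta has wrong dimension")
  k1 <- foam_kernel(L$kernel$sigma_z, 1L)
  parts <- lapply(seq_len(m), function(j) kernel_eval(L$axes[[j]] - eta[j], k1))
  if (m == 1L) parts[[1L]] else outer(parts[[1L]], parts[[2L]])
}

#' Advance the U-form landscape by one stimulus-holding interval
#'
#' The stimulus is treated as piecewise constant over each sampling interval,
#' so the linear relaxation equation
#' \eqn{\partial U/\partial t = -g(x-\eta) - kU} has an exact
#' integrating-factor solution over the interval:
#' \deqn{U \leftarrow U e^{-k\,dt} - g(x-\eta)\,(1 - e^{-k\,dt})/k}
#' for `k > 0`, and \eqn{U \leftarrow U - g(x-\eta)\,dt} for `k = 0`.
#' Using the exact update (rather than an Euler step) makes the grid U-form
#' agree with the mesh-free representation to machine precision.
#'
#' @param L A `grid_landscape` in U form.
#' @param eta Stimulus value held over the interval (length `m`).
#' @param dt Interval length, seconds.
#' @return The advanced landscape (`time` increased by `dt`).
#' @export
step_u <- function(L, eta, dt) {
  if (L$form != "U") stop_invalid("step_u needs a U-form landscape")
  if (dt <= 0) stop_invalid("dt must be > 0")
  g <- grid_dent(L, eta)
  L$values <- u_update(L$values, g, L$k, dt)
  L$time <- L$time + dt
  L
}

u_update <- function(u, g, k, dt) {
  if (k > 0) u * exp(-k * dt) - g * (1 - exp(-k * dt)) / k else u - g * dt
}

#' De-trend a U-form landscape
#'
#' The raw field `U` decays linearly in time; `V = U / t` removes the trend
#' and converges (for `k = 0` and stationary stimuli) to the negative
#' kernel-smoothed stimulus density.
#'
#' @param L A `grid_landscape` in U form with `time > 0`.
#' @return The same landscape in V form.
#' @export
u_to_v <- function(L) {
  if (L$form != "U") stop_invalid("u_to_v needs a U-form landscape")
  if (L$time <= 0) stop_singular_time("V = U/t is undefined at time 0")
  L$values <- L$values / L$time
  L$form <- "V"
  L
}

#' Advance the V-form landscape by one stimulus-holding interval
#'
#' Explicit Euler integration of
#' \eqn{\partial V/\partial t = -(V + g(x-\eta))/t - kV}. The equation is
#' singular at `t = 0`; evolution must start at `t0 = dt` with
#' \eqn{V = -g(x - \eta_1)}, which is exactly `U/t` after the first holding
#' interval (see [learn_landscape()], which handles the start). The stimulus
#' is held constant over the interval; `substeps` Euler sub-steps of size
#' `dt/substeps` reduce the O(dt) truncation error.
#'
#' @param L A `grid_landscape` in V form with `time >= dt`.
#' @param eta Stimulus value (length `m`).
#' @param dt Interval length, seconds.
#' @param substeps Number of Euler sub-steps per interval.
#' @return The advanced landscape.
#' @export
step_v <- function(L, eta, dt, substeps = 1L) {
  if (L$form != "V") stop_invalid("step_v needs a V-form landscape")
  if (L$time <= 0) stop_singular_time("the V equation is singular at time 0; seed it with the first dent")
  if (dt <= 0) stop_invalid("dt must be > 0")
  g <- grid_dent(L, eta)
  h <- dt / substeps
  v <- L$values
  t <- L$time
  for (s in seq_len(substeps)) {
    v <- v + h * (-(v + g) / t - L$k * v)
    t <- t + h
  }
  L$values <- v
  L$time <- t
  L
}

#' Asymptotic landscape for a stimulus density
#'
#' The `t -> Inf`, `k = 0` limit of the learned V landscape under i.i.d.
#' (or stationary ergodic) stimuli with density `p` is the negative
#' kernel-smoothed density, \eqn{-(g * p)(x)}, computed here by quadrature.
#' It is the target against which learned landscapes are compared.
#'
#' @param p Density function: takes a numeric vector (1-D) or an n x 2 matrix
#'   (2-D) and returns non-negative densities.
#' @param kernel A [foam_kernel()].
#' @param bounds,n_nodes Grid specification as in [grid_landscape()].
#' @param q_points Quadrature points per axis.
#' @param pad Quadrature domain extends this many `sigma_z` beyond the grid.
#' @return A `grid_landscape` in V form with `time = Inf` semantics
#'   (`time` is set to `NA`).
#' @export
asymptotic_landscape <- function(p, kernel, bounds, n_nodes = 401L,
                                 q_points = 2001L, pad = 6) {
  L <- grid_landscape(bounds, n_nodes, kernel, k = 0, form = "V")
  m <- landscape_dim(L)
  s <- kernel$sigma_z
  k1 <- foam_kernel(s, 1L)
  if (m == 1L) {
    lo <- L$bounds[[1L]][1L] - pad * s
    hi <- L$bounds[[1L]][2L] + pad * s
    y <- seq(lo, hi, length.out = q_points)
    dy <- y[2L] - y[1L]
    py <- p(y)
    if (any(!is.finite(py)) || any(py < 0)) stop_invalid("density p must be finite and non-negative")
    gmat <- kernel_eval(matrix(outer(L$axes[[1L]], y, `-`), ncol = 1L), k1)
    gmat <- matrix(gmat, nrow = n_nodes[1L])
    L$values <- -as.vector(gmat %*% py) * dy
  } else {
    qp <- min(q_points, 201L)  # 2-D quadrature grid kept modest
    ys <- lapply(L$bounds, function(b) seq(b[1L] - pad * s, b[2L] + pad * s,
                                           length.out = qp))
    dy <- prod(vapply(ys, function(y) y[2L] - y[1L], numeric(1L)))
    yy <- as.matrix(expand.grid(ys[[1L]], ys[[2L]]))
    py <- p(yy)
    if (any(!is.finite(py)) || any(py < 0)) stop_invalid("density p must be finite and non-negative")
    g1 <- outer(L$axes[[1L]], ys[[1L]], function(a, b) kernel_eval(matrix(a - b), k1))
    g2 <- outer(L$axes[[2L]], ys[[2L]], function(a, b) kernel_eval(matrix(a - b), k1))
    pm <- matrix(py, nrow = length(ys[[1L]]))
    L$values <- -(g1 %*% pm %*% t(g2)) * dy
  }
  L$time <- NA_real_
  L
}

#' Learn a landscape from a stimulus stream
#'
#' Streams every sample of `stim` into the landscape: each sample dents the
#' field with the kernel and the elasticity term `k` relaxes it back toward
#' flat. Three integrators are available: the exact U-form update
#' ([step_u()]), the Euler V-form ([step_v()], seeded at `t0 = dt` with the
#' first dent), and the exact mesh-free kernel-sum form
#' ([meshfree_absorb()]), which is the only choice for stimulus dimension
#' greater than 2.
#'
#' @param stim A [stimulus_series()].
#' @param kernel A [foam_kernel()] with `dim` matching the stimulus.
#' @param k Elasticity factor, 1/s.
#' @param integrator `"U"`, `"V"` or `"meshfree"`.
#' @param bounds Grid bounds; default: observed stimulus range padded by
#'   `4 sigma_z` per side. Ignored for the mesh-free form.
#' @param n_nodes Grid nodes per axis (grid forms only).
#' @param substeps Euler sub-steps per sample (V form only).
#' @param as_v For the U form, de-trend to V before returning.
#' @param prune_tol Mesh-free weight pruning threshold, relative to the
#'   largest weight.
#' @return A `grid_landscape` or `meshfree_landscape`.
#' @examples
#' stim <- gen_iid_bimodal(2000, seed = 1)
#' L <- learn_landscape(stim, foam_kernel(sqrt(0.1)))
#' find_minima(L, n_starts = 50, seed = 2)
#' @export
learn_landscape <- function(stim, kernel, k = 0,
                            integrator = c("U", "V", "meshfree"),
                            bounds = NULL, n_nodes = 401L, substeps = 1L,
                            as_v = TRUE, prune_tol = 1e-12) {
  integrator <- match.arg(integrator)
  m <- stimulus_dim(stim)
  if (kernel$dim != m) stop_invalid("kernel dim must match stimulus dim")
  dt <- stim$dt
  vals <- stim$values
  n <- nrow(vals)
  if (integrator == "meshfree") {
    M <- meshfree_landscape(kernel, k = k, prune_tol = prune_tol)
    return(meshfree_absorb(M, vals, dt))
  }
  if (is.null(bounds)) bounds <- default_bounds(vals, kernel$sigma_z)
  if (integrator == "U") {
    L <- grid_landscape(bounds, n_nodes, kernel, k = k, form = "U")
    if (k == 0 && m == 1L) {
      # k = 0 collapses to a plain kernel sum; chunked for memory
      x <- L$axes[[1L]]
      acc <- numeric(length(x))
      idx <- split(seq_len(n), ceiling(seq_len(n) / 4096))
      k1 <- foam_kernel(kernel$sigma_z, 1L)
      for (ii in idx) {
        d <- outer(x, vals[ii, 1L], `-`)
        acc <- acc + rowSums(matrix(kernel_eval(matrix(as.vector(d), ncol = 1L), k1),
                                    nrow = length(x)))
      }
      L$values <- -acc * dt
      L$time <- n * dt
    } else {
      for (i in seq_len(n)) L <- step_u(L, vals[i, ], dt)
    }
    if (as_v) L <- u_to_v(L)
    return(L)
  }
  # V form: seed at t0 = dt with the first dent (exact U/t value), then Euler
  L <- grid_landscape(bounds, n_nodes, kernel, k = k, form = "V")
  L$values <- -grid_dent(L, vals[1L, ]) * (if (k > 0) (1 - exp(-k * dt)) / (k * dt) else 1)
  L$time <- dt
  for (i in seq_len(n)[-1L]) L <- step_v(L, vals[i, ], dt, substeps = substeps)
  L
}

default_bounds <- function(vals, sigma_z, pad = 4) {
  lapply(seq_len(ncol(vals)), function(j) {
    range(vals[, j]) + c(-1, 1) * pad * sigma_z
  })
}

#' Evaluate a landscape (value and gradient) at a point
#'
#' Grid landscapes are evaluated by (bi)linear interpolation of the node
#' values, with the gradient taken from central differences at the nodes and
#' interpolated the same way; mesh-free landscapes are evaluated exactly.
#'
#' @param L A landscape.
#' @param x Point, length `m`.
#' @return A list with elements `value` (scalar) and `grad` (length-`m`).
#' @export
landscape_eval <- function(L, x) UseMethod("landscape_eval")

#' @export
landscape_eval.grid_landscape <- function(L, x) {
  m <- landscape_dim(L)
  check_finite(x, "point x")
  if (length(x) != m) stop_invalid("point has wrong dimension")
  if (m == 1L) {
    ax <- L$axes[[1L]]
    sf <- stats::splinefun(ax, L$values, method = "natural")
    xx <- min(max(x, ax[1L]), ax[length(ax)])
    list(value = sf(xx), grad = sf(xx, deriv = 1L))
  } else {
    ax <- L$axes
    v <- L$values
    gx <- node_gradient_2d(v, ax)
    list(value = interp2(ax, v, x),
         grad = c(interp2(ax, gx[[1L]], x), interp2(ax, gx[[2L]], x)))
  }
}

node_gradient_1d <- function(v, ax) {
  h <- ax[2L] - ax[1L]
  n <- length(v)
  g <- numeric(n)
  g[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * h)
  g[1L] <- (v[2L] - v[1L]) / h
  g[n] <- (v[n] - v[n - 1L]) / h
  g
}

node_gradient_2d <- function(v, axes) {
  list(apply(v, 2L, node_gradient_1d, ax = axes[[1L]]),
       t(apply(v, 1L, node_gradient_1d, ax = axes[[2L]])))
}

interp1 <- function(ax, v, x) {
  x <- min(max(x, ax[1L]), ax[length(ax)])
  i <- max(1L, min(findInterval(x, ax), length(ax) - 1L))
  u <- (x - ax[i]) / (ax[i + 1L] - ax[i])
  (1 - u) * v[i] + u * v[i + 1L]
}

interp2 <- function(axes, v, x) {
  a1 <- axes[[1L]]; a2 <- axes[[2L]]
  x1 <- min(max(x[1L], a1[1L]), a1[length(a1)])
  x2 <- min(max(x[2L], a2[1L]), a2[length(a2)])
  i <- max(1L, min(findInterval(x1, a1), length(a1) - 1L))
  j <- max(1L, min(findInterval(x2, a2), length(a2) - 1L))
  u <- (x1 - a1[i]) / (a1[i + 1L] - a1[i])
  w <- (x2 - a2[j]) / (a2[j + 1L] - a2[j])
  (1 - u) * (1 - w) * v[i, j] + u * (1 - w) * v[i + 1L, j] +
    (1 - u) * w * v[i, j + 1L] + u * w * v[i + 1L, j + 1L]
}

#' Evaluate a landscape at many points
#'
#' @param L A landscape.
#' @param X Numeric vector (1-D) or matrix of points, one per row.
#' @return Vector of landscape values.
#' @export
landscape_values <- function(L, X) UseMethod("landscape_values")

#' @export
landscape_values.grid_landscape <- function(L, X) {
  X <- if (landscape_dim(L) == 1L && !is.matrix(X)) matrix(X, ncol = 1L) else as_row_matrix(X)
  if (landscape_dim(L) == 1L) {
    ax <- L$axes[[1L]]
    sf <- stats::splinefun(ax, L$values, method = "natural")
    sf(pmin(pmax(X[, 1L], ax[1L]), ax[length(ax)]))
  } else {
    vapply(seq_len(nrow(X)), function(i) landscape_eval(L, X[i, ])$value,
           numeric(1L))
  }
}

#' Grid node coordinates of a grid landscape
#'
#' @param L A `grid_landscape`.
#' @return For 1-D, the axis vector; for 2-D, a matrix of all node coordinates.
#' @export
landscape_nodes <- function(L) {
  if (landscape_dim(L) == 1L) L$axes[[1L]] else
    as.matrix(expand.grid(L$axes[[1L]], L$axes[[2L]]))
}

#' Read / write grid landscapes as CSV
#'
#' Plain-text serialisation: comment lines `#key,value` carry the metadata
#' (form, time, k, sigma_z, bounds, n_nodes), followed by one row per node
#' with the node coordinates and the field value.
#'
#' @param L A `grid_landscape`.
#' @param path File path.
#' @return `read_landscape_csv` returns the landscape; the writer returns
#'   `path` invisibly.
#' @export
write_landscape_csv <- function(L, path) {
  m <- landscape_dim(L)
  meta <- c(sprintf("#form,%s", L$form),
            sprintf("#time,%.17g", L$time),
            sprintf("#k,%.17g", L$k),
            sprintf("#sigma_z,%.17g", L$kernel$sigma_z),
            sprintf("#dim,%d", m),
            sprintf("#bounds,%s", paste(sprintf("%.17g", unlist(L$bounds)), collapse = ";")),
            sprintf("#n_nodes,%s", paste(L$n_nodes, collapse = ";")))
  nodes <- landscape_nodes(L)
  nodes <- if (m == 1L) matrix(nodes, ncol = 1L) else nodes
  df <- as.data.frame(nodes)
  names(df) <- paste0("x", seq_len(m))
  df$value <- as.vector(L$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), ",", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  m <- as.integer(meta$dim)
  b <- as.numeric(strsplit(meta$bounds, ";")[[1L]])
  bounds <- split(b, rep(seq_len(m), each = 2L))
  n_nodes <- as.integer(strsplit(meta$n_nodes, ";")[[1L]])
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  vals <- if (m == 1L) df$value else matrix(df$value, n_nodes[1L], n_nodes[2L])
  L <- grid_landscape(unname(bounds), n_nodes, foam_kernel(as.numeric(meta$sigma_z), m),
                      k = as.numeric(meta$k), form = meta$form, values = vals,
                      time = 0)
  L$time <- as.numeric(meta$time)
  L
}
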