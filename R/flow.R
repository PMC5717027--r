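#' Wrap analytic value/gradient functions as a landscape
#'
#' Convenience for tests and examples: any pair of functions `V(x)` and
#' `grad(x)` behaves like a landscape for [descend()] and [find_minima()].
#'
#' @param value_fn Function of a length-`m` point returning a scalar.
#' @param grad_fn Function returning the length-`m` gradient.
#' @param dim Dimension `m`.
#' @return An object of class `function_landscape`.
#' @export
function_landscape <- function(value_fn, grad_fn, dim = 1L) {
  structure(list(value_fn = value_fn, grad_fn = grad_fn, dim = as.integer(dim)),
            class = "function_landscape")
}

#' @export
landscape_eval.function_landscape <- function(L, x) {
  list(value = L$value_fn(x), grad = L$grad_fn(x))
}

#' @export
landscape_values.function_landscape <- function(L, X) {
  X <- if (L$dim == 1L && !is.matrix(X)) matrix(X, ncol = 1L) else as_row_matrix(X)
  vapply(seq_len(nrow(X)), function(i) L$value_fn(X[i, ]), numeric(1L))
}

#' @export
landscape_dim.function_landscape <- function(x) x$dim

#' Gradient descent on a frozen landscape
#'
#' Integrates the gradient system `dx/dt = -grad V` by explicit Euler with
#' an adaptive step: the step is halved whenever it would increase `V`
#' (backtracking) and grown again after successful moves, while the
#' displacement of a single step is capped at `max_move` so the state cannot
#' hop across a ridge into a neighbouring basin. The recorded `V` values are
#' therefore non-increasing by construction. Descent stops when the gradient
#' norm drops below `tol` or after `max_iter` steps (the latter is returned
#' as a flagged non-converged trajectory, not an error).
#'
#' @param landscape Any landscape with a [landscape_eval()] method.
#' @param x0 Starting point, length `m`.
#' @param step Initial Euler step size (time units of the flow).
#' @param tol Gradient-norm stopping threshold.
#' @param max_iter Iteration cap.
#' @param max_move Cap on the displacement of one step; default
#'   `sigma_z / 4` (quarter of a dent width) for kernel landscapes.
#' @param record Keep the full path (`TRUE`) or only the endpoints.
#' @return An object of class `trajectory`: list with `states` (matrix, one
#'   row per recorded point), `times`, `terminal_grad_norm`, `converged`.
#' @export
descend <- function(landscape, x0, step = NULL, tol = 1e-8, max_iter = 5000L,
                    max_move = NULL, record = TRUE) {
  check_finite(x0, "x0")
  if (is.null(step)) step <- default_step(landscape)
  if (step <= 0) stop_invalid("step must be > 0")
  if (is.null(max_move)) {
    s <- tryCatch(landscape$kernel$sigma_z, error = function(e) NULL)
    max_move <- if (is.null(s)) 10 * step else s / 4
  }
  evaluator <- make_evaluator(landscape)
  x <- as.numeric(x0)
  ev <- evaluator(x)
  states <- list(x)
  vvals <- ev$value
  times <- 0
  t_now <- 0
  converged <- FALSE
  h_cur <- step
  for (i in seq_len(max_iter)) {
    gn <- sqrt(sum(ev$grad^2))
    if (gn < tol) { converged <- TRUE; break }
    h <- min(h_cur, max_move / gn)
    v_cur <- vvals[length(vvals)]
    repeat {
      x_try <- x - h * ev$grad
      ev_try <- evaluator(x_try)
      if (ev_try$value <= v_cur) break
      h <- h / 2
      if (h < step * 2^-30) { # numerically stuck at a flat spot; stop here
        ev_try <- ev
        x_try <- x
        break
      }
    }
    if (identical(x_try, x)) break
    # zero V progress at an accepted move: the step straddles the minimum at
    # machine precision, so contract; otherwise grow the step back
    h_cur <- if (ev_try$value == v_cur) h / 2 else min(h * 2, 1e9 * step)
    t_now <- t_now + h
    x <- x_try
    ev <- ev_try
    if (record) {
      states[[length(states) + 1L]] <- x
      vvals <- c(vvals, ev$value)
      times <- c(times, t_now)
    } else {
      states[[2L]] <- x
      vvals <- c(vvals[1L], ev$value)[1:2]
      times <- c(0, t_now)
    }
  }
  if (!converged) converged <- sqrt(sum(ev$grad^2)) < tol
  structure(list(states = do.call(rbind, states), times = times,
                 values = vvals, terminal_grad_norm = sqrt(sum(ev$grad^2)),
                 converged = converged),
            class = "trajectory")
}

# One-off closure for repeated evaluation inside a descent: precomputes the
# node-gradient fields of grid landscapes so each step costs an interpolation.
make_evaluator <- function(landscape) {
  if (inherits(landscape, "grid_landscape")) {
    m <- landscape_dim(landscape)
    if (m == 1L) {
      # cubic spline: the gradient is the exact derivative of the evaluated
      # V, so backtracking line search and descent are mutually consistent
      ax <- landscape$axes[[1L]]
      sf <- stats::splinefun(ax, landscape$values, method = "natural")
      lo <- ax[1L]
      hi <- ax[length(ax)]
      function(x) {
        xx <- min(max(x, lo), hi)
        list(value = sf(xx), grad = sf(xx, deriv = 1L))
      }
    } else {
      ax <- landscape$axes
      v <- landscape$values
      gx <- node_gradient_2d(v, ax)
      function(x) list(value = interp2(ax, v, x),
                       grad = c(interp2(ax, gx[[1L]], x),
                                interp2(ax, gx[[2L]], x)))
    }
  } else if (inherits(landscape, "meshfree_landscape")) {
    if (landscape$time <= 0) stop_singular_time("V = U/t is undefined at time 0")
    m <- landscape$kernel$dim
    cols <- lapply(seq_len(m), function(j) landscape$centers[, j])
    w <- landscape$weights
    s2 <- landscape$kernel$sigma_z^2
    nrm <- (2 * pi * s2)^(-m / 2)
    tinv <- 1 / landscape$time
    function(x) {
      d2 <- 0
      zs <- vector("list", m)
      for (j in seq_len(m)) {
        zj <- x[j] - cols[[j]]
        zs[[j]] <- zj
        d2 <- d2 + zj * zj
      }
      wg <- w * (nrm * exp(-d2 / s2))
      grad <- numeric(m)
      for (j in seq_len(m)) grad[j] <- (2 / s2) * sum(wg * zs[[j]]) * tinv
      list(value = -sum(wg) * tinv, grad = grad)
    }
  } else {
    function(x) landscape_eval(landscape, x)
  }
}

default_step <- function(landscape) {
  s <- tryCatch(landscape$kernel$sigma_z, error = function(e) NULL)
  if (is.null(s)) 0.1 else {
    # scale so one step moves at most ~sigma_z/4 at the steepest kernel slope
    g0 <- kernel_peak(landscape$kernel)
    maxslope <- g0 * sqrt(2 / exp(1)) / landscape$kernel$sigma_z
    (landscape$kernel$sigma_z / 4) / maxslope
  }
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("<trajectory> %d recorded states, dim %d, |grad| at end = %.3g, %s\n",
              n, ncol(x$states), x$terminal_grad_norm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname descend
#' @param trajectory A `trajectory`.
#' @export
trajectory_endpoint <- function(trajectory) {
  trajectory$states[nrow(trajectory$states), ]
}

#' Write a trajectory as CSV
#' @param trajectory A `trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory$states)
  names(df) <- paste0("x", seq_len(ncol(trajectory$states)))
  df <- cbind(time = trajectory$times, df, value = trajectory$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Discover all memorised minima by random-restart descent
#'
#' Runs [descend()] from `n_starts` uniform random starting points inside a
#' bounding box, drops non-converged restarts, clusters the endpoints by
#' single linkage at `merge_radius`, and returns one row per cluster:
#' centroid location, landscape depth there, and the number of restarts that
#' fell into that basin (a proxy for basin size). Deterministic for a fixed
#' seed.
#'
#' @param landscape Any landscape with a [landscape_eval()] method.
#' @param n_starts Number of random restarts.
#' @param seed RNG seed (restarts are reproducible given the seed).
#' @param box Bounding box for starts: list of `c(lo, hi)` per axis; default
#'   is the landscape's own extent (grid bounds, or the mesh-free centers
#'   padded by `2 sigma_z`).
#' @param merge_radius Endpoints closer than this are one minimum; default
#'   `sigma_z / 2` (dents closer than `sigma_z` merge into a single minimum
#'   anyway).
#' @param starts Optional explicit matrix of starting points (one per row),
#'   overriding the uniform draw. Useful in high dimension, where uniform
#'   box samples almost never land inside a basin: restarting from observed
#'   stimulus vectors (e.g. the mesh-free centers) is the mean-shift-style
#'   alternative. `n_starts` points are subsampled (seeded) if more rows are
#'   supplied.
#' @param min_depth Optional depth floor: discovered minima shallower than
#'   this (i.e. `|depth| < min_depth`) are dropped. A single stimulus sample
#'   can carve a dent of depth `g(0) * dt / t`, so setting the floor to a
#'   small multiple of that keeps only memories reinforced by repetition.
#' @param ... Passed to [descend()].
#' @return An object of class `minima_set`: data frame with columns
#'   `x1..xm`, `depth`, `basin_count`, ordered deepest first, plus attributes
#'   `merge_radius` and `n_nonconverged`.
#' @export
find_minima <- function(landscape, n_starts = 200L, seed = NULL, box = NULL,
                        merge_radius = NULL, starts = NULL, min_depth = NULL,
                        ...) {
  if (n_starts < 1L) stop_invalid("n_starts must be >= 1")
  if (is.null(box)) box <- landscape_box(landscape)
  m <- length(box)
  if (is.null(merge_radius)) {
    s <- tryCatch(landscape$kernel$sigma_z, error = function(e) NULL)
    merge_radius <- if (is.null(s)) 0.05 else s / 2
  }
  if (is.null(starts)) {
    starts <- with_seed(seed, {
      vapply(box, function(b) stats::runif(n_starts, b[1L], b[2L]),
             numeric(n_starts))
    })
    starts <- matrix(starts, nrow = n_starts)
  } else {
    starts <- as_row_matrix(starts)
    if (ncol(starts) != m) stop_invalid("starts have wrong dimension")
    if (nrow(starts) > n_starts) {
      keep <- with_seed(seed, sample.int(nrow(starts), n_starts))
      starts <- starts[keep, , drop = FALSE]
    }
    n_starts <- nrow(starts)
  }
  ends <- matrix(NA_real_, n_starts, m)
  conv <- logical(n_starts)
  evaluator <- make_evaluator(landscape)
  for (i in seq_len(n_starts)) {
    tr <- descend(landscape, starts[i, ], record = FALSE, ...)
    # a vanishing gradient on a flat plateau between distant dents is not a
    # minimum: keep only endpoints that are strictly below axis probes
    conv[i] <- tr$converged &&
      is_local_min(evaluator, trajectory_endpoint(tr), merge_radius / 2)
    ends[i, ] <- trajectory_endpoint(tr)
  }
  ends_ok <- ends[conv, , drop = FALSE]
  if (nrow(ends_ok) == 0L) {
    stop(errorCondition("no restart converged to a minimum",
                        class = c("memoryfoam_empty_result", "error")))
  }
  cl <- if (nrow(ends_ok) == 1L) 1L else {
    hc <- stats::hclust(stats::dist(ends_ok), method = "single")
    stats::cutree(hc, h = merge_radius)
  }
  locs <- vapply(split(seq_len(nrow(ends_ok)), cl), function(ii) {
    colMeans(ends_ok[ii, , drop = FALSE])
  }, numeric(m))
  locs <- if (m == 1L) matrix(locs, ncol = 1L) else t(locs)
  depths <- vapply(seq_len(nrow(locs)), function(i) {
    landscape_eval(landscape, locs[i, ])$value
  }, numeric(1L))
  counts <- as.integer(table(cl))
  if (!is.null(min_depth)) {
    keep <- depths <= -abs(min_depth)
    if (!any(keep)) {
      stop(errorCondition("all discovered minima are shallower than min_depth",
                          class = c("memoryfoam_empty_result", "error")))
    }
    locs <- locs[keep, , drop = FALSE]
    depths <- depths[keep]
    counts <- counts[keep]
  }
  ord <- order(depths)
  out <- as.data.frame(locs[ord, , drop = FALSE])
  names(out) <- paste0("x", seq_len(m))
  out$depth <- depths[ord]
  out$basin_count <- counts[ord]
  rownames(out) <- NULL
  structure(out, class = c("minima_set", "data.frame"),
            merge_radius = merge_radius, n_nonconverged = sum(!conv))
}

is_local_min <- function(evaluator, x, delta) {
  v0 <- evaluator(x)$value
  m <- length(x)
  for (j in seq_len(m)) {
    for (s in c(-1, 1)) {
      xp <- x
      xp[j] <- xp[j] + s * delta
      if (evaluator(xp)$value <= v0) return(FALSE)
    }
  }
  TRUE
}

landscape_box <- function(landscape) {
  if (inherits(landscape, "grid_landscape")) return(landscape$bounds)
  if (inherits(landscape, "meshfree_landscape")) {
    s <- landscape$kernel$sigma_z
    return(lapply(seq_len(landscape$kernel$dim), function(j) {
      range(landscape$centers[, j]) + c(-1, 1) * 2 * s
    }))
  }
  stop_invalid("supply a bounding box for this landscape type")
}

#' @export
print.minima_set <- function(x, ...) {
  cat(sprintf("<minima_set> %d minima (deepest first), merge_radius = %g, %d non-converged restart(s)\n",
              nrow(x), attr(x, "merge_radius"), attr(x, "n_nonconverged")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Locations of a minima set as a matrix
#' @param minima A `minima_set`.
#' @export
minima_locations <- function(minima) {
  as.matrix(minima[grep("^x[0-9]+$", names(minima))])
}

#' Write a minima set as CSV
#' @param minima A `minima_set`.
#' @param path File path.
#' @export
write_minima_csv <- function(minima, path) {
  utils::write.csv(as.data.frame(minima), path, row.names = FALSE)
  invisible(path)
}

#' Recognise a stimulus against catalogued minima
#'
#' Models recognition by reset: the state is set to the stimulus value and
#' descends the frozen landscape; the stimulus is labelled with the
#' catalogued minimum whose location is within `merge_radius` of the descent
#' endpoint.
#'
#' @param landscape Any landscape with a [landscape_eval()] method.
#' @param eta Stimulus value, length `m`.
#' @param minima A `minima_set` from [find_minima()] (non-empty).
#' @param merge_radius Match radius; defaults to the minima set's own.
#' @param ... Passed to [descend()].
#' @return Integer index into `minima` (row number), or `NA_integer_` when
#'   the endpoint matches no catalogued minimum (an unknown category, not an
#'   error), with the trajectory attached as attribute `"trajectory"`.
#' @export
recognize <- function(landscape, eta, minima, merge_radius = NULL, ...) {
  if (!inherits(minima, "minima_set") || nrow(minima) == 0L) {
    stop_invalid("minima must be a non-empty minima_set")
  }
  if (is.null(merge_radius)) merge_radius <- attr(minima, "merge_radius")
  tr <- descend(landscape, eta, record = FALSE, ...)
  ep <- trajectory_endpoint(tr)
  locs <- minima_locations(minima)
  d <- sqrt(rowSums(sweep(locs, 2L, ep)^2))
  idx <- if (any(d <= merge_radius)) which.min(d) else NA_integer_
  structure(idx, trajectory = tr)
}

#' Online learning with interleaved recognition
#'
#' Streams the stimulus into a mesh-free landscape sample by sample
#' (unsupervised learning); every `recognition_interval` samples the state is
#' reset to the current stimulus value and descends the current landscape
#' (recognition). Recognition is read-only: the returned landscape is
#' identical to one produced by pure absorption of the same stream.
#' Categories are discovered online: each recognition endpoint is matched to
#' the catalogue of previously seen endpoints within `merge_radius`, and a
#' novel endpoint opens the next category index.
#'
#' @param stim A [stimulus_series()].
#' @param kernel A [foam_kernel()].
#' @param k Elasticity factor, 1/s.
#' @param recognition_interval Recognise every this many samples (default 1:
#'   every sample).
#' @param merge_radius Endpoint matching radius (default `sigma_z / 2`).
#' @param warmup Samples absorbed before the first recognition event.
#' @param prune_tol Mesh-free pruning threshold.
#' @param ... Passed to [descend()].
#' @return List with `landscape` (the final [meshfree_landscape()]) and
#'   `log`: a data frame with one row per recognition event — `time`, the
#'   stimulus components `eta1..etam`, the descent endpoint `end1..endm`,
#'   and `category` (integer id in order of first appearance; `NA` only if
#'   descent failed to converge).
#' @export
run_online <- function(stim, kernel, k = 0, recognition_interval = 1L,
                       merge_radius = NULL, warmup = 1L, prune_tol = 1e-12,
                       ...) {
  if (n_samples(stim) < 1L) stop_invalid("stimulus stream is empty")
  if (is.null(merge_radius)) merge_radius <- kernel$sigma_z / 2
  M <- meshfree_landscape(kernel, k = k, prune_tol = prune_tol)
  m <- stimulus_dim(stim)
  cats <- matrix(numeric(0), 0L, m)   # catalogue of category prototypes
  log_rows <- list()
  tt <- stimulus_times(stim)
  for (i in seq_len(n_samples(stim))) {
    eta <- stim$values[i, ]
    M <- meshfree_absorb(M, eta, stim$dt)
    if (i >= warmup && (i %% recognition_interval == 0L)) {
      tr <- descend(M, eta, record = FALSE, ...)
      ep <- trajectory_endpoint(tr)
      cat_id <- NA_integer_
      if (tr$converged) {
        if (nrow(cats) > 0L) {
          d <- sqrt(rowSums(sweep(cats, 2L, ep)^2))
          if (any(d <= merge_radius)) cat_id <- which.min(d)
        }
        if (is.na(cat_id)) {
          cats <- rbind(cats, ep)
          cat_id <- nrow(cats)
        }
      }
      log_rows[[length(log_rows) + 1L]] <-
        c(time = tt[i], stats::setNames(eta, paste0("eta", seq_len(m))),
          stats::setNames(ep, paste0("end", seq_len(m))), category = cat_id)
    }
  }
  log_df <- as.data.frame(do.call(rbind, log_rows))
  list(landscape = M, log = log_df)
}
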