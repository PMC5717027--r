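#' Mesh-free plastic energy landscape
#'
#' Exact integral representation of the landscape for piecewise-constant
#' stimuli: the field is a weighted sum of dents,
#' \deqn{V(x) = -\frac{1}{t} \sum_i w_i\, g(x - \eta_i),}
#' where each absorbed sample contributes a center \eqn{\eta_i} and a weight
#' \eqn{w_i} that the elasticity term shrinks geometrically as later samples
#' arrive. No grid is involved, so this form works in any dimension and is
#' the one used for the 4-D phrase landscapes.
#'
#' @param kernel A [foam_kernel()].
#' @param k Elasticity factor, 1/s.
#' @param prune_tol Centers whose weight falls below `prune_tol` times the
#'   largest weight are dropped.
#' @return An object of class `meshfree_landscape`.
#' @export
meshfree_landscape <- function(kernel, k = 0, prune_tol = 1e-12) {
  if (k < 0) stop_invalid("elasticity k must be >= 0")
  structure(list(centers = matrix(numeric(0), 0L, kernel$dim),
                 weights = numeric(0), k = k, time = 0, kernel = kernel,
                 prune_tol = prune_tol),
            class = "meshfree_landscape")
}

#' @export
print.meshfree_landscape <- function(x, ...) {
  cat(sprintf("<meshfree_landscape> dim %d, %d centers, t = %g s, k = %g, sigma_z = %g\n",
              x$kernel$dim, nrow(x$centers), x$time, x$k, x$kernel$sigma_z))
  invisible(x)
}

#' Absorb stimulus samples into a mesh-free landscape
#'
#' One absorption is the exact integral of the U equation over a holding
#' interval `dt` with the stimulus held at `eta`: existing weights shrink by
#' `exp(-k dt)` and the new dent enters with weight `(1 - exp(-k dt))/k`
#' (`dt` when `k = 0`). A matrix `eta` absorbs one row per interval.
#'
#' @param M A [meshfree_landscape()].
#' @param eta Stimulus value (length `m`) or matrix of samples (rows).
#' @param dt Holding interval, seconds.
#' @return The updated landscape; `time` grows by `dt` per sample.
#' @export
meshfree_absorb <- function(M, eta, dt) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  etas <- as_row_matrix(eta)
  if (ncol(etas) != M$kernel$dim) stop_invalid("eta has wrong dimension")
  check_finite(etas, "stimulus eta")
  n <- nrow(etas)
  k <- M$k
  if (k > 0) {
    decay <- exp(-k * dt)
    w_new <- (1 - decay) / k
    # weight of sample i after all n absorptions: w_new * decay^(n - i)
    w_in <- w_new * decay^((n - 1L):0L)
    M$weights <- c(M$weights * decay^n, w_in)
  } else {
    M$weights <- c(M$weights, rep(dt, n))
  }
  M$centers <- rbind(M$centers, etas)
  M$time <- M$time + n * dt
  if (length(M$weights)) {
    keep <- M$weights >= M$prune_tol * max(M$weights)
    M$weights <- M$weights[keep]
    M$centers <- M$centers[keep, , drop = FALSE]
  }
  M
}

#' Evaluate a mesh-free landscape and its gradient at one point
#'
#' @param M A [meshfree_landscape()] with `time > 0`.
#' @param x Point, length `m`.
#' @return List with `value` \eqn{= -(1/t)\sum_i w_i g(x-\eta_i)} and the
#'   analytic `grad`.
#' @export
meshfree_eval <- function(M, x) {
  if (M$time <= 0) stop_singular_time("V = U/t is undefined at time 0")
  check_finite(x, "point x")
  if (length(x) != M$kernel$dim) stop_invalid("point has wrong dimension")
  z <- sweep(M$centers, 2L, x, function(c_, x_) x_ - c_)
  g <- kernel_eval(z, M$kernel)
  gr <- z * (-2 / M$kernel$sigma_z^2) * g
  list(value = -sum(M$weights * g) / M$time,
       grad = -as.vector(crossprod(gr, M$weights)) / M$time)
}

#' @export
landscape_eval.meshfree_landscape <- function(L, x) meshfree_eval(L, x)

#' @export
landscape_values.meshfree_landscape <- function(L, X) {
  if (L$time <= 0) stop_singular_time("V = U/t is undefined at time 0")
  X <- if (L$kernel$dim == 1L && !is.matrix(X)) matrix(X, ncol = 1L) else as_row_matrix(X)
  s2 <- L$kernel$sigma_z^2
  norm <- (2 * pi * s2)^(-L$kernel$dim / 2)
  vapply(seq_len(nrow(X)), function(i) {
    z <- sweep(L$centers, 2L, X[i, ])
    -sum(L$weights * norm * exp(-rowSums(z^2) / s2)) / L$time
  }, numeric(1L))
}

#' Read / write mesh-free landscapes as CSV
#'
#' One row per dent center (`eta1..etam, weight`), with `#key,value` comment
#' lines carrying time, k, sigma_z and the pruning threshold.
#'
#' @param M A [meshfree_landscape()].
#' @param path File path.
#' @return `read_meshfree_csv` returns the landscape; the writer returns
#'   `path` invisibly.
#' @export
write_meshfree_csv <- function(M, path) {
  m <- M$kernel$dim
  meta <- c(sprintf("#time,%.17g", M$time),
            sprintf("#k,%.17g", M$k),
            sprintf("#sigma_z,%.17g", M$kernel$sigma_z),
            sprintf("#dim,%d", m),
            sprintf("#prune_tol,%.17g", M$prune_tol))
  df <- as.data.frame(M$centers)
  names(df) <- paste0("eta", seq_len(m))
  df$weight <- M$weights
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meshfree_csv
#' @export
read_meshfree_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), ",", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- as.numeric(kv[2L])
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  m <- as.integer(meta$dim)
  M <- meshfree_landscape(foam_kernel(meta$sigma_z, m), k = meta$k,
                          prune_tol = meta$prune_tol)
  M$centers <- as.matrix(df[paste0("eta", seq_len(m))])
  dimnames(M$centers) <- NULL
  M$weights <- df$weight
  M$time <- meta$time
  M
}
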