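#' Uniformly sampled stimulus stream
#'
#' A stream of `m`-dimensional stimulus values sampled every `dt` seconds,
#' starting at `t0`. This is the common currency between the synthetic
#' generators, the audio front end and the landscape integrators.
#'
#' @param values Numeric vector (scalar stimulus) or matrix with one row per
#'   sample and `m` columns.
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `stimulus_series`: a list with elements
#'   `values` (matrix, n x m), `dt`, `t0`.
#' @examples
#' s <- stimulus_series(c(1, 2, 3), dt = 0.5)
#' stimulus_times(s)
#' @export
stimulus_series <- function(values, dt, t0 = 0) {
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(values) < 1L) stop_invalid("stimulus series must be non-empty")
  check_finite(values, "stimulus values")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_invalid("dt must be a single positive number")
  }
  check_finite(t0, "t0")
  structure(list(values = unname(values), dt = dt, t0 = t0),
            class = "stimulus_series")
}

#' @export
print.stimulus_series <- function(x, ...) {
  cat(sprintf("<stimulus_series> %d samples, dim %d, dt = %g s, t0 = %g s\n",
              nrow(x$values), ncol(x$values), x$dt, x$t0))
  invisible(x)
}

#' @rdname stimulus_series
#' @param x A `stimulus_series`.
#' @export
stimulus_dim <- function(x) ncol(x$values)

#' @rdname stimulus_series
#' @export
stimulus_times <- function(x) x$t0 + (seq_len(nrow(x$values)) - 1L) * x$dt

#' @rdname stimulus_series
#' @export
n_samples <- function(x) nrow(x$values)

#' Read / write stimulus streams as CSV
#'
#' The on-disk format is a plain CSV with columns `time, v1..vm`; the sampling
#' interval is recovered from the time column (which must be uniform).
#'
#' @param x A [stimulus_series()].
#' @param path File path.
#' @return `read_stimulus_csv` returns a [stimulus_series()];
#'   `write_stimulus_csv` returns `path` invisibly.
#' @export
write_stimulus_csv <- function(x, path) {
  m <- stimulus_dim(x)
  df <- data.frame(time = stimulus_times(x))
  df[paste0("v", seq_len(m))] <- split(x$values, col(x$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df) || ncol(df) < 2L) {
    stop_invalid("stimulus CSV needs a 'time' column and at least one value column")
  }
  tt <- df$time
  dt <- if (length(tt) > 1L) stats::median(diff(tt)) else 1
  if (length(tt) > 1L && max(abs(diff(tt) - dt)) > 1e-6 * max(dt, 1)) {
    stop_invalid("stimulus CSV time column is not uniformly sampled")
  }
  vals <- as.matrix(df[setdiff(names(df), "time")])
  stimulus_series(vals, dt = dt, t0 = tt[1L])
}
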