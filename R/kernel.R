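#' Dent kernel
#'
#' The bell-shaped deformation left on the energy landscape by a single
#' stimulus sample. In one dimension
#' \deqn{g(z) = (2\pi\sigma_z^2)^{-1/2} \exp(-z^2/\sigma_z^2),}
#' and in `m` dimensions the product of the one-dimensional kernels, one per
#' coordinate. Note the exponent is \eqn{-z^2/\sigma_z^2} (no factor 1/2), so
#' the kernel is narrower than a Gaussian density of the same
#' \eqn{\sigma_z} and its integral over each axis is \eqn{1/\sqrt{2}}, not 1.
#' All asymptotic statements in the package use the kernel-smoothed density
#' \eqn{g * p}, which absorbs this normalisation.
#'
#' @param sigma_z Kernel width, in stimulus units (> 0).
#' @param dim Dimension `m` of the stimulus space (positive integer).
#' @return An object of class `foam_kernel`.
#' @examples
#' ker <- foam_kernel(sigma_z = sqrt(0.1))
#' kernel_eval(0, ker)          # the dent depth scale g(0)
#' kernel_grad(0.2, ker)
#' @export
foam_kernel <- function(sigma_z, dim = 1L) {
  if (!is.numeric(sigma_z) || length(sigma_z) != 1L || !is.finite(sigma_z) ||
      sigma_z <= 0) {
    stop_invalid("sigma_z must be a single positive finite number")
  }
  dim <- as.integer(dim)
  if (length(dim) != 1L || is.na(dim) || dim < 1L) {
    stop_invalid("dim must be a positive integer")
  }
  structure(list(sigma_z = sigma_z, dim = dim), class = "foam_kernel")
}

#' @export
print.foam_kernel <- function(x, ...) {
  cat(sprintf("<foam_kernel> sigma_z = %g, dim = %d, g(0) = %g\n",
              x$sigma_z, x$dim, kernel_peak(x)))
  invisible(x)
}

#' Kernel peak value g(0)
#'
#' @param kernel A [foam_kernel()].
#' @return \eqn{g(0) = (2\pi\sigma_z^2)^{-m/2}}, the depth scale of a single
#'   dent; the learned landscape `V` always lies in `[-g(0), 0]`.
#' @export
kernel_peak <- function(kernel) {
  (2 * pi * kernel$sigma_z^2)^(-kernel$dim / 2)
}

#' Evaluate the dent kernel
#'
#' @param z Displacement(s): a numeric vector of length `m`, or a matrix with
#'   `m` columns (one displacement per row).
#' @param kernel A [foam_kernel()].
#' @return Kernel value(s) `g(z)`, one per row of `z`.
#' @export
kernel_eval <- function(z, kernel) {
  z <- kernel_check_z(z, kernel)
  s2 <- kernel$sigma_z^2
  (2 * pi * s2)^(-kernel$dim / 2) * exp(-rowSums(z^2) / s2)
}

#' Gradient of the dent kernel
#'
#' Analytic gradient of [kernel_eval()]: component `j` equals
#' \eqn{g(z) \cdot (-2 z_j / \sigma_z^2)}.
#'
#' @inheritParams kernel_eval
#' @return A matrix of gradients (rows match rows of `z`); a plain vector if
#'   `z` was a vector.
#' @export
kernel_grad <- function(z, kernel) {
  zm <- kernel_check_z(z, kernel)
  g <- kernel_eval(zm, kernel)
  out <- zm * (-2 / kernel$sigma_z^2) * g
  if (!is.matrix(z)) drop(out) else out
}

kernel_check_z <- function(z, kernel) {
  if (!inherits(kernel, "foam_kernel")) stop_invalid("kernel must be a foam_kernel")
  zm <- if (is.matrix(z)) z else if (kernel$dim == 1L) matrix(z, ncol = 1L) else
    matrix(z, nrow = 1L)
  if (ncol(zm) != kernel$dim) {
    stop_invalid("displacement has dimension ", ncol(zm),
                 " but kernel has dim ", kernel$dim)
  }
  check_finite(zm, "displacement z")
  zm
}
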