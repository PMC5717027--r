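# Independent oracles used across the suite. These never call the code paths
# they check: modes/minima come from dense-grid scans, gradients from central
# finite differences, phrase statistics from direct counting.

# local maxima of a density (dense-grid scan)
scan_density_modes <- function(p, lo, hi, n = 8001L) {
  x <- seq(lo, hi, length.out = n)
  px <- p(x)
  x[which(diff(sign(diff(px))) == -2) + 1L]
}

# local minima of a 1-D field given as a function (dense-grid scan)
scan_field_minima <- function(f, lo, hi, n = 8001L) {
  x <- seq(lo, hi, length.out = n)
  v <- f(x)
  x[which(diff(sign(diff(v))) == 2) + 1L]
}

# central finite-difference gradient of a scalar function of a vector
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1L))
}

# brute-force recomputation of the k = 0 grid field: U = -dt * sum_i g(x - eta_i)
brute_sum_field <- function(nodes, etas, dt, sigma_z) {
  nrm <- 1 / sqrt(2 * pi * sigma_z^2)
  vapply(nodes, function(x) {
    -dt * sum(nrm * exp(-(x - etas)^2 / sigma_z^2))
  }, numeric(1L))
}

# all distinct 4-beat phrases of the repeated song, with occurrence counts;
# phrases wrap across repetitions (offsets are cyclic in the 32-beat loop)
phrase_table <- function(spec, dim = 4L) {
  seq32 <- spec$sequence
  n <- length(seq32)
  grams <- vapply(seq_len(n), function(i) {
    paste(seq32[((i - 1L + 0:(dim - 1L)) %% n) + 1L], collapse = "")
  }, character(1L))
  tab <- sort(table(grams), decreasing = TRUE)
  freqs <- do.call(rbind, lapply(names(tab), function(g) {
    spec$tuning[strsplit(g, "")[[1L]]]
  }))
  list(names = names(tab), counts = as.integer(tab), freqs = unname(freqs))
}

# tiny deterministic two-dent mesh-free landscape for flow tests
two_dent_landscape <- function(centers = c(-1, 2), weights = c(1, 1),
                               sigma_z = sqrt(0.1)) {
  M <- meshfree_landscape(foam_kernel(sigma_z), k = 0)
  for (i in seq_along(centers)) M <- meshfree_absorb(M, centers[i], 1)
  M$weights <- weights
  M
}

# dent profile over a 1-D grid landscape's nodes (independent of step_u internals)
grid_dent_for_test <- function(L, eta) {
  kernel_eval(L$axes[[1L]] - eta, L$kernel)
}
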