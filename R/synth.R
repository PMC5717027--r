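#' Specification of the i.i.d. bimodal stimulus
#'
#' Independent stimulus values are produced by pushing standard Gaussian
#' white noise \eqn{\xi} through the strictly monotone nonlinear transform
#' \deqn{\eta = A \tanh(\beta(\xi - \mu)) + c\,(\xi - \mu).}
#' The saturating tanh piles mass near \eqn{\pm A}, giving a two-peak
#' density; the offset \eqn{\mu} makes the two modes carry unequal mass; the
#' linear leak `c > 0` keeps the transform strictly monotone so the density
#' has a closed form by change of variables ([true_density_iid()]).
#'
#' @param A Amplitude (mode scale), stimulus units.
#' @param beta Steepness of the saturation.
#' @param c Linear leak (> 0 guarantees monotonicity).
#' @param mu Asymmetry offset.
#' @return An object of class `bimodal_spec`.
#' @export
bimodal_spec <- function(A = 1.5, beta = 2, c = 0.1, mu = 0.3) {
  if (!(A > 0 && beta > 0 && c > 0)) {
    stop_invalid("bimodal_spec needs A > 0, beta > 0, c > 0")
  }
  check_finite(mu, "mu")
  structure(list(A = A, beta = beta, c = c, mu = mu), class = "bimodal_spec")
}

bimodal_transform <- function(xi, spec) {
  u <- xi - spec$mu
  spec$A * tanh(spec$beta * u) + spec$c * u
}

bimodal_transform_deriv <- function(xi, spec) {
  u <- xi - spec$mu
  spec$A * spec$beta / cosh(spec$beta * u)^2 + spec$c
}

#' Generate i.i.d. bimodal stimulus samples
#'
#' @param n Number of samples.
#' @param spec A [bimodal_spec()].
#' @param seed RNG seed for reproducibility.
#' @param dt Sampling interval attached to the output stream.
#' @return A [stimulus_series()] of scalar samples.
#' @export
gen_iid_bimodal <- function(n, spec = bimodal_spec(), seed = NULL, dt = 1) {
  if (!inherits(spec, "bimodal_spec")) stop_invalid("spec must be a bimodal_spec")
  if (n < 1L) stop_invalid("n must be >= 1")
  xi <- with_seed(seed, stats::rnorm(n))
  stimulus_series(bimodal_transform(xi, spec), dt = dt)
}

#' Closed-form density of the i.i.d. bimodal stimulus
#'
#' The transform is strictly monotone, so the stimulus density follows by
#' change of variables:
#' \eqn{p(\eta) = \phi(\xi(\eta)) / |T'(\xi(\eta))|}, with \eqn{T} the
#' transform and \eqn{\xi(\eta)} its numerical inverse. For the default
#' spec the density has exactly two local maxima of unequal mass.
#'
#' @param spec A [bimodal_spec()].
#' @return A vectorised density function `p(eta)`.
#' @export
true_density_iid <- function(spec = bimodal_spec()) {
  if (!inherits(spec, "bimodal_spec")) stop_invalid("spec must be a bimodal_spec")
  inv <- bimodal_inverse(spec)
  function(eta) {
    xi <- inv(eta)
    stats::dnorm(xi) / bimodal_transform_deriv(xi, spec)
  }
}

# numerical inverse of the monotone transform, vectorised over eta
bimodal_inverse <- function(spec) {
  function(eta) {
    vapply(eta, function(e) {
      # bracket: |eta| <= A + c|u| gives |u| >= (|e| - A)/c
      hw <- max(10, (abs(e - 0) + spec$A) / spec$c + 10)
      stats::uniroot(function(xi) bimodal_transform(xi, spec) - e,
                     lower = spec$mu - hw, upper = spec$mu + hw,
                     tol = 1e-12)$root
    }, numeric(1L))
  }
}

#' Specification of the correlated double-well stimulus
#'
#' Correlated stimulus values come from an overdamped Langevin particle in a
#' tilted quartic double well,
#' \deqn{dx = -W'(x)\,dt + \sqrt{2D}\,dW, \qquad
#'       W(x) = a_4 x^4/4 - a_2 x^2/2 + \epsilon x,}
#' integrated by Euler–Maruyama with step `h`. The tilt \eqn{\epsilon \ne 0}
#' makes the two wells (hence the two stimulus categories) unequal; the
#' stationary density is \eqn{p(x) \propto \exp(-W(x)/D)}
#' ([true_density_langevin()]). Defaults put the wells near \eqn{\pm 1.5}
#' with a modest barrier so that a stream of ten thousand samples visits
#' both wells many times.
#'
#' @param a4,a2 Quartic and quadratic coefficients (`a4 > 0`).
#' @param eps Tilt (asymmetry); nonzero gives non-symmetric wells.
#' @param D Noise intensity (> 0).
#' @param h Euler–Maruyama step, seconds.
#' @return An object of class `double_well_spec`.
#' @export
double_well_spec <- function(a4 = 1, a2 = 2.25, eps = 0.15, D = 0.4, h = 0.05) {
  if (!(a4 > 0 && D > 0 && h > 0)) {
    stop_invalid("double_well_spec needs a4 > 0, D > 0, h > 0")
  }
  check_finite(c(a2, eps), "a2/eps")
  structure(list(a4 = a4, a2 = a2, eps = eps, D = D, h = h),
            class = "double_well_spec")
}

double_well_potential <- function(x, spec) {
  spec$a4 * x^4 / 4 - spec$a2 * x^2 / 2 + spec$eps * x
}

double_well_force <- function(x, spec) {
  -(spec$a4 * x^3 - spec$a2 * x + spec$eps)
}

#' Generate correlated stimulus samples from the double-well Langevin model
#'
#' @param n Number of samples (one per Euler–Maruyama step).
#' @param spec A [double_well_spec()].
#' @param seed RNG seed.
#' @param x0 Initial particle position.
#' @return A [stimulus_series()] with `dt = spec$h`; consecutive samples are
#'   positively correlated.
#' @export
gen_langevin <- function(n, spec = double_well_spec(), seed = NULL, x0 = NULL) {
  if (!inherits(spec, "double_well_spec")) stop_invalid("spec must be a double_well_spec")
  if (n < 1L) stop_invalid("n must be >= 1")
  guard <- 10 * (1 + sqrt(spec$a2 / spec$a4))  # divergence guard
  x <- numeric(n)
  noise <- with_seed(seed, stats::rnorm(n))
  sig <- sqrt(2 * spec$D * spec$h)
  xi <- if (is.null(x0)) -sqrt(spec$a2 / spec$a4) else x0
  for (i in seq_len(n)) {
    xi <- xi + double_well_force(xi, spec) * spec$h + sig * noise[i]
    if (!is.finite(xi) || abs(xi) > guard) {
      stop(errorCondition(
        "Langevin integration diverged; reduce the step h",
        class = c("memoryfoam_stability", "error")))
    }
    x[i] <- xi
  }
  stimulus_series(x, dt = spec$h)
}

#' Stationary density of the double-well Langevin stimulus
#'
#' \eqn{p(x) = \exp(-W(x)/D) / Z}, with `Z` computed by quadrature.
#'
#' @param spec A [double_well_spec()].
#' @param lim Integration half-width for the normalising constant.
#' @return A vectorised density function.
#' @export
true_density_langevin <- function(spec = double_well_spec(), lim = 10) {
  if (!inherits(spec, "double_well_spec")) stop_invalid("spec must be a double_well_spec")
  z <- stats::integrate(function(x) exp(-double_well_potential(x, spec) / spec$D),
                        -lim, lim, rel.tol = 1e-10)$value
  function(x) exp(-double_well_potential(x, spec) / spec$D) / z
}

#' The default 32-beat three-note song
#'
#' The standard three-note nursery arrangement ("Mary had a little lamb") in
#' which held notes are expanded into repeated beats, using only the notes
#' G, A and B. One character per beat.
#'
#' @return Character vector of 32 note names.
#' @export
default_melody_sequence <- function() {
  c("B", "A", "G", "A", "B", "B", "B", "B",
    "A", "A", "A", "A", "B", "B", "B", "B",
    "B", "A", "G", "A", "B", "B", "B", "B",
    "A", "A", "B", "A", "G", "G", "G", "G")
}

#' Specification of the jittered melody stimulus
#'
#' Emulates a pitch track of a three-note, 32-beat song played several
#' times: at `rate` samples per second the stream emits the tuning frequency
#' of the current beat's note plus i.i.d. Gaussian jitter (performer and
#' measurement variability).
#'
#' @param sequence 32 note names drawn from `names(tuning)`.
#' @param tuning Named map note -> frequency in Hz (equal-temperament
#'   defaults: G4 392, A4 440, B4 493.88).
#' @param beat Beat duration \eqn{\tau} in seconds (default 0.75).
#' @param jitter_sd Pitch jitter standard deviation, Hz.
#' @param reps Number of repetitions of the song.
#' @param rate Output sampling rate, Hz (default 8).
#' @return An object of class `melody_spec`.
#' @export
melody_spec <- function(sequence = default_melody_sequence(),
                        tuning = c(G = 392, A = 440, B = 493.88),
                        beat = 0.75, jitter_sd = 2, reps = 6L, rate = 8) {
  if (length(sequence) != 32L) stop_invalid("sequence must have 32 beats")
  if (!all(sequence %in% names(tuning))) {
    stop_invalid("unknown note name(s): ",
                 paste(setdiff(sequence, names(tuning)), collapse = ", "))
  }
  if (any(tuning <= 0)) stop_invalid("tuning frequencies must be > 0")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  if (reps < 1L) stop_invalid("reps must be >= 1")
  if (beat <= 0 || rate <= 0) stop_invalid("beat and rate must be > 0")
  structure(list(sequence = sequence, tuning = tuning, beat = beat,
                 jitter_sd = jitter_sd, reps = as.integer(reps), rate = rate),
            class = "melody_spec")
}

#' Note frequency at each output sample of a melody spec (jitter-free)
#' @param spec A [melody_spec()].
#' @return Numeric vector of per-sample note frequencies, Hz.
#' @export
melody_note_track <- function(spec) {
  spb <- round(spec$beat * spec$rate)        # samples per beat
  per_rep <- rep(spec$tuning[spec$sequence], each = spb)
  unname(rep(per_rep, spec$reps))
}

#' Generate the jittered melody pitch stream
#'
#' @param spec A [melody_spec()].
#' @param seed RNG seed for the jitter.
#' @return A [stimulus_series()] of scalar pitch values in Hz, sampled at
#'   `spec$rate`; total length `reps * 32 * beat * rate`.
#' @export
gen_melody <- function(spec = melody_spec(), seed = NULL) {
  if (!inherits(spec, "melody_spec")) stop_invalid("spec must be a melody_spec")
  f <- melody_note_track(spec)
  jit <- if (spec$jitter_sd > 0) {
    with_seed(seed, stats::rnorm(length(f), sd = spec$jitter_sd))
  } else 0
  stimulus_series(f + jit, dt = 1 / spec$rate)
}
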