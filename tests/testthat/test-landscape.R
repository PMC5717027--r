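ker01 <- foam_kernel(sqrt(0.1))

test_that("one exact U step from flat carves a single dent", {
  L <- grid_landscape(c(-2, 2), 101L, ker01, k = 0, form = "U")
  L1 <- step_u(L, eta = 0.3, dt = 0.5)
  expect_equal(L1$values, -kernel_eval(L$axes[[1]] - 0.3, ker01) * 0.5)
  expect_equal(L1$time, 0.5)
  expect_error(step_u(L, eta = NaN, dt = 0.5), class = "memoryfoam_invalid_input")
})

test_that("with forgetting, a held stimulus drives U to the -g/k fixed point", {
  k <- 1
  L <- grid_landscape(c(-2, 2), 101L, ker01, k = k, form = "U")
  for (i in 1:40) L <- step_u(L, 0.2, 1)     # t = 40 >> 1/k
  target <- -kernel_eval(L$axes[[1]] - 0.2, ker01) / k
  expect_lt(max(abs(L$values - target)), 1e-6)
})

test_that("without forgetting the field is the exact dent sum (telescoping oracle)", {
  etas <- c(-0.4, 0.1, 0.1, 0.7, -1.2)
  L <- grid_landscape(c(-3, 3), 121L, ker01, k = 0, form = "U")
  for (e in etas) L <- step_u(L, e, 0.25)
  expect_equal(L$values, brute_sum_field(L$axes[[1]], etas, 0.25, sqrt(0.1)),
               tolerance = 1e-12)
})

test_that("de-trending divides by time and refuses t = 0", {
  L <- grid_landscape(c(-1, 1), 11L, ker01, form = "U",
                      values = rep(-1, 11), time = 2)
  V <- u_to_v(L)
  expect_equal(V$values, rep(-0.5, 11))
  expect_identical(V$form, "V")
  L0 <- grid_landscape(c(-1, 1), 11L, ker01, form = "U")
  expect_error(u_to_v(L0), class = "memoryfoam_singular_time")
  expect_error(step_v(u_to_v(L), 0, 0), class = "memoryfoam_invalid_input")
})

test_that("the de-trended equation holds a constant-stimulus field at -g", {
  # for eta held fixed the exact solution is V = -g(x - eta) at all t;
  # the Euler V-form must preserve it to rounding
  stim <- stimulus_series(rep(0.4, 200), dt = 0.5)
  L <- learn_landscape(stim, ker01, integrator = "V")
  expect_lt(max(abs(L$values + kernel_eval(L$axes[[1]] - 0.4, ker01))), 1e-12)
})

test_that("Euler V-form converges to the exact U-form at first order in dt", {
  stim <- gen_iid_bimodal(150, seed = 9)
  for (k in c(0, 0.05)) {
    LU <- learn_landscape(stim, ker01, k = k, integrator = "U")
    e1 <- max(abs(learn_landscape(stim, ker01, k = k, integrator = "V")$values -
                    LU$values))
    e2 <- max(abs(learn_landscape(stim, ker01, k = k, integrator = "V",
                                  substeps = 2)$values - LU$values))
    expect_lt(e2, e1 * 0.6)   # halving the step at least nearly halves the gap
  }
})

test_that("far from all stimuli the field decays as (t1/t) exp(-k(t-t1))", {
  k <- 0.3
  # exact-update route: machine precision
  L <- grid_landscape(c(-2, 2), 41L, foam_kernel(sqrt(0.1)), k = k, form = "U")
  L <- step_u(L, 0, 1)
  v1 <- u_to_v(L)$values
  t1 <- 1
  Lfar <- L
  for (i in 1:10) Lfar <- step_u(Lfar, 500, 1)   # stimulus far outside domain
  vt <- u_to_v(Lfar)$values
  pred <- v1 * (t1 / Lfar$time) * exp(-k * (Lfar$time - t1))
  expect_lt(max(abs(vt - pred)) / max(abs(pred)), 1e-12)
  # Euler V-form route at small dt reproduces the same closed form
  LV <- grid_landscape(c(-2, 2), 41L, foam_kernel(sqrt(0.1)), k = k, form = "V")
  LV$values <- -grid_dent_for_test(LV, 0) * (1 - exp(-k * 1)) / k
  LV$time <- 1
  nstep <- 5000L
  for (i in seq_len(nstep)) LV <- step_v(LV, 500, 0.5 / nstep)
  pred2 <- (-grid_dent_for_test(LV, 0) * (1 - exp(-k * 1)) / k) *
    (1 / 1.5) * exp(-k * 0.5)
  expect_lt(max(abs(LV$values - pred2)) / max(abs(pred2)), 1e-4)
})

test_that("learned fields stay within the sign bounds -g(0) <= V <= 0", {
  g0 <- kernel_peak(ker01)
  for (s in 1:3) {
    stim <- gen_iid_bimodal(400, seed = s)
    for (k in c(0, 0.2)) {
      L <- learn_landscape(stim, ker01, k = k)
      expect_true(all(L$values <= 0))
      expect_true(all(L$values >= -g0))
    }
  }
})

test_that("asymptotic landscape reduces to a single dent for a point mass", {
  # a density concentrated far below the kernel width acts as a delta
  spike <- function(x) stats::dnorm(x, mean = 0.7, sd = 1e-3)
  A <- asymptotic_landscape(spike, ker01, bounds = list(c(-2, 2)),
                            n_nodes = 201L, q_points = 40001L)
  expect_equal(A$values, -kernel_eval(A$axes[[1]] - 0.7, ker01),
               tolerance = 1e-4)
  expect_error(asymptotic_landscape(function(x) -spike(x), ker01,
                                    bounds = list(c(-2, 2)), n_nodes = 51L),
               class = "memoryfoam_invalid_input")
})

test_that("asymptotic landscape minima track the bimodal density at kernel resolution", {
  p <- true_density_iid()
  A <- asymptotic_landscape(p, ker01, bounds = list(c(-3, 3)), n_nodes = 1201L)
  sf <- function(x) landscape_values(A, x)
  mins <- scan_field_minima(sf, -3, 3)
  expect_length(mins, 2L)
  modes <- scan_density_modes(p, -3, 3)
  expect_length(modes, 2L)
  # smoothing by the kernel shifts the sharp modes inward; the minima still
  # recover them within half a kernel width
  expect_true(all(abs(sort(mins) - sort(modes)) < sqrt(0.1) / 2))
})

test_that("a long i.i.d. stream converges to -(g*p) and improves with n", {
  p <- true_density_iid()
  bounds <- list(c(-3.3, 3.3))
  A <- asymptotic_landscape(p, ker01, bounds, n_nodes = 401L)
  e_small <- max(abs(learn_landscape(gen_iid_bimodal(1000, seed = 5), ker01,
                                     bounds = bounds)$values - A$values))
  e_large <- max(abs(learn_landscape(gen_iid_bimodal(100000, seed = 5), ker01,
                                     bounds = bounds)$values - A$values))
  expect_lt(e_large, 0.05 * kernel_peak(ker01))
  expect_lt(e_large, e_small)
})

test_that("grid landscapes round-trip through CSV", {
  stim <- gen_iid_bimodal(100, seed = 2)
  L <- learn_landscape(stim, ker01, k = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landscape_csv(L, f)
  L2 <- read_landscape_csv(f)
  expect_equal(L2$values, as.vector(L$values), tolerance = 1e-12)
  expect_equal(L2$time, L$time)
  expect_equal(L2$k, L$k)
  expect_identical(L2$form, L$form)
})

test_that("stimulus streams round-trip through CSV", {
  stim <- stimulus_series(matrix(stats::rnorm(20), ncol = 2), dt = 0.25, t0 = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stimulus_csv(stim, f)
  s2 <- read_stimulus_csv(f)
  expect_equal(s2$values, stim$values, tolerance = 1e-12)
  expect_equal(s2$dt, stim$dt)
  expect_equal(s2$t0, 3)
})
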