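ker01 <- foam_kernel(sqrt(0.1))

test_that("descent on a single dent lands on the dent center", {
  M <- two_dent_landscape(centers = 0.8, weights = 1)
  for (x0 in c(0.1, 0.5, 1.4)) {         # within ~3 sigma of the center
    tr <- descend(M, x0)
    expect_true(tr$converged)
    expect_lt(abs(trajectory_endpoint(tr) - 0.8), 1e-3)
  }
})

test_that("descent stays in the basin it starts in", {
  M <- two_dent_landscape(centers = c(-1, 2))
  # basin boundary oracle: dense scan of the gradient sign changes
  sgn <- sign(vapply(seq(-1.5, 2.5, length.out = 4001),
                     function(x) meshfree_eval(M, x)$grad, numeric(1L)))
  expect_true(any(diff(sgn) != 0))       # there are two basins and a ridge
  tr <- descend(M, -0.5)
  expect_lt(abs(trajectory_endpoint(tr) - (-1)), 1e-3)
  tr2 <- descend(M, 1.3)
  expect_lt(abs(trajectory_endpoint(tr2) - 2), 1e-3)
})

test_that("the landscape value never increases along a trajectory", {
  set.seed(77)
  for (rep in 1:30) {
    M <- two_dent_landscape(centers = stats::runif(3, -2, 2),
                            weights = stats::runif(3, 0.2, 1))
    tr <- descend(M, stats::runif(1, -2.5, 2.5))
    expect_true(all(diff(tr$values) <= 0))
  }
})

test_that("hitting the iteration cap flags the trajectory instead of erroring", {
  M <- two_dent_landscape(centers = 0)
  tr <- descend(M, 0.9, max_iter = 2L)
  expect_false(tr$converged)
  expect_gt(tr$terminal_grad_norm, 1e-8)
})

test_that("a constant stimulus yields exactly one minimum at the stimulus", {
  stim <- stimulus_series(rep(0.6, 100), dt = 1)
  L <- learn_landscape(stim, ker01)
  mins <- find_minima(L, n_starts = 40, seed = 1)
  expect_identical(nrow(mins), 1L)
  expect_lt(abs(mins$x1 - 0.6), 1e-3)
})

test_that("the bimodal stream carves two minima at the smoothed density modes", {
  stim <- gen_iid_bimodal(10000, seed = 1)
  L <- learn_landscape(stim, ker01)
  mins <- find_minima(L, n_starts = 120, seed = 2)
  expect_identical(nrow(mins), 2L)
  # dense-scan oracle on the same field must agree in count and location
  sf <- function(x) landscape_values(L, x)
  scan <- scan_field_minima(sf, L$bounds[[1]][1], L$bounds[[1]][2])
  scan <- scan[abs(sf(scan)) > 1e-6]     # ignore numerically flat dust
  expect_identical(nrow(mins), length(scan))
  expect_true(all(abs(sort(minima_locations(mins)[, 1]) - sort(scan)) < 6 / 8000))
  # mode-mass ordering: the left density mode is the heavier one
  p <- true_density_iid()
  left <- mins[order(mins$x1), ]
  expect_gt(left$basin_count[1], left$basin_count[2])
  expect_lt(left$depth[1], left$depth[2])
})

test_that("minima discovery is deterministic and stable under more restarts", {
  stim <- gen_iid_bimodal(4000, seed = 8)
  L <- learn_landscape(stim, ker01)
  m1 <- find_minima(L, n_starts = 80, seed = 3)
  m2 <- find_minima(L, n_starts = 80, seed = 3)
  expect_identical(m1, m2)
  m3 <- find_minima(L, n_starts = 160, seed = 4)
  expect_identical(nrow(m1), nrow(m3))
  expect_true(all(abs(minima_locations(m1) - minima_locations(m3)) < 1e-3))
})

test_that("recognition labels stimuli by basin and flags unknowns", {
  M <- two_dent_landscape(centers = c(-1, 2))
  mins <- find_minima(M, n_starts = 60, seed = 5)
  # a stimulus exactly at a minimum is recognized instantly as that minimum
  for (i in seq_len(nrow(mins))) {
    idx <- recognize(M, minima_locations(mins)[i, ], mins)
    expect_identical(as.integer(idx), i)
  }
  # within one kernel width of a dent -> that dent's category
  idx_a <- recognize(M, -1 + sqrt(0.1) / 2, mins)
  expect_identical(as.integer(idx_a),
                   as.integer(which.min(abs(minima_locations(mins) - (-1)))))
  # far outside every basin -> unknown, not an error
  idx_u <- recognize(M, 40, mins)
  expect_true(is.na(idx_u))
})

test_that("two stimuli closer than the kernel width merge into one memory", {
  d <- sqrt(0.1) / 2                      # half a kernel width apart
  stim <- stimulus_series(rep(c(0, d), 50), dt = 1)
  L <- learn_landscape(stim, ker01)
  mins <- find_minima(L, n_starts = 60, seed = 6)
  expect_identical(nrow(mins), 1L)
  expect_identical(as.integer(recognize(L, 0, mins)),
                   as.integer(recognize(L, d, mins)))
})

test_that("online learning recognizes a constant stream as one category", {
  st <- stimulus_series(rep(1, 40), dt = 1)
  res <- run_online(st, ker01, recognition_interval = 4)
  expect_true(all(res$log$category == 1L))
  # recognition is read-only: the landscape equals pure absorption
  M <- learn_landscape(st, ker01, integrator = "meshfree")
  expect_equal(res$landscape, M)
})

test_that("late online recognitions agree with the nearer density mode", {
  stim <- gen_iid_bimodal(3000, seed = 4)
  res <- run_online(stim, ker01, recognition_interval = 25, warmup = 500)
  lg <- res$log
  late <- lg[lg$time > 1500, ]
  p <- true_density_iid()
  modes <- sort(scan_density_modes(p, -3, 3))
  near_mode <- modes[apply(abs(outer(late$eta1, modes, "-")), 1, which.min)]
  end_mode <- modes[apply(abs(outer(late$end1, modes, "-")), 1, which.min)]
  expect_gte(mean(near_mode == end_mode), 0.95)
  # every recognized endpoint lies near a catalogued category prototype
  expect_true(all(!is.na(late$category)))
})
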