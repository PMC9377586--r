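test_that("zero-intercept slope matches hand computation and is linear in force", {
  expect_equal(fit_slope_zero_intercept(indentation_curve(1:3, c(2, 4, 6))),
               2.0)
  # sum(dF)/sum(d^2) = 1/1 even though the best affine fit would differ
  expect_equal(fit_slope_zero_intercept(indentation_curve(c(0, 1), c(1, 1))),
               1.0)
  set.seed(1)
  cu <- indentation_curve(sort(runif(20, 0, 10)), runif(20, 0, 5))
  s <- fit_slope_zero_intercept(cu)
  cu2 <- indentation_curve(cu$displacement, 3.3 * cu$force)
  expect_equal(fit_slope_zero_intercept(cu2), 3.3 * s, tolerance = 1e-12)
  expect_error(fit_slope_zero_intercept(
    indentation_curve(c(0, 0), c(1, 2))), class = "tissuecal_invalid_curve")
})

test_that("crop/align applies the three rules", {
  sim <- indentation_curve(0:3, c(0.1, 0.2, 0.5, 1.0), "simulated")
  exp0 <- indentation_curve(c(0, 0.5, 1.0), c(0.4, 0.7, 1.0))
  out <- crop_align(sim, exp0)
  expect_equal(out$displacement, c(0, 1))
  expect_equal(out$force, c(0.5, 1.0))
  # no preload, equal ranges: curve unchanged
  expq <- indentation_curve(c(0, 3), c(0, 9))
  sim0 <- indentation_curve(0:3, c(0, 1, 2, 3), "simulated")
  un <- crop_align(sim0, expq)
  expect_equal(un$displacement, sim0$displacement)
  expect_equal(un$force, sim0$force)
  # preload above every simulated force: informative error
  exp_hi <- indentation_curve(c(0, 1), c(5, 6))
  expect_error(crop_align(sim, exp_hi),
               class = "tissuecal_insufficient_simulation")
  # rule 3 trims samples beyond the experimental span
  exp_short <- indentation_curve(c(0, 0.8), c(0, 1))
  tr <- crop_align(sim0, exp_short)
  expect_lte(max(tr$displacement), 0.8 + 1e-9)
})

test_that("slope-ratio update reproduces the reference iteration arithmetic", {
  # female-upper-arm worked example, experimental slope 1.5265
  expect_equal(update_c1(0.01, 3.0807, 1.5265), 0.004955, tolerance = 1e-4)
  expect_equal(update_c1(0.004955, 1.9580, 1.5265), 0.003863,
               tolerance = 1e-4)
  expect_equal(update_c1(0.5, 2, 2), 0.5)
  # scale consistency: common slope factor cancels exactly
  expect_identical(update_c1(0.01, 3.0807 * 7, 1.5265 * 7),
                   update_c1(0.01, 3.0807, 1.5265))
  expect_error(update_c1(0.01, -1, 1), class = "tissuecal_invalid_input")
})

test_that("symmetric percent difference matches the reported statistic", {
  expect_equal(percent_difference(0.00779, 0.00808), 3.65, tolerance = 2e-3)
  expect_equal(percent_difference(4, 4), 0)
  expect_equal(percent_difference(1, 3), 100)
  expect_error(percent_difference(1, -1), class = "tissuecal_invalid_input")
})

test_that("exact-linear forward with no preload converges after one update", {
  fw <- make_surrogate_forward(stiffening = 0, d_max = 8)
  target <- fw(0.0063)
  exp0 <- indentation_curve(target$displacement, target$force)
  for (c1_init in c(0.0005, 0.01, 0.15)) {
    st <- calibrate(fw, exp0, c1_init = c1_init)
    expect_true(st$converged)
    # one corrective update, one verifying evaluation
    expect_equal(st$n_forward, 2L)
    expect_equal(st$c1, 0.0063, tolerance = 1e-10)
    expect_equal(st$iterations$ratio[2], 1, tolerance = 1e-12)
  }
})

test_that("scripted slope replay reproduces the four-iteration trace", {
  slopes <- c(3.0807, 1.9580, 1.6454, 1.5265)
  i <- 0
  scripted <- function(c1) {
    i <<- i + 1
    indentation_curve(c(0, 1), c(0, slopes[i]), "simulated")
  }
  exp0 <- indentation_curve(c(0, 1), c(0, 1.5265))
  st <- calibrate(scripted, exp0, c1_init = 0.01)
  expect_true(st$converged)
  expect_equal(st$n_forward, 4L)
  expect_equal(st$iterations$c1, c(0.01, 0.004955, 0.003863, 0.003584),
               tolerance = 1e-4)
  expect_equal(st$iterations$ratio[1], 2.0181, tolerance = 1e-4)
  # recorded k follows the 1000x coupling
  expect_equal(st$iterations$k, 1000 * st$iterations$c1)
})

test_that("surrogate experiments are recovered within the slope tolerance", {
  fw <- make_surrogate_forward(stiffening = 0.05, d_max = 12)
  se <- synth_experiment(0.005,
                         forward = make_surrogate_forward(stiffening = 0.05,
                                                          d_max = 8),
                         preload_force = 0, noise_sd = 0, seed = 1)
  st <- calibrate(fw, se$curve)
  expect_true(st$converged)
  expect_equal(st$c1, 0.005, tolerance = 0.025)
})

test_that("the iteration contracts toward the fixed point for a monotone forward model", {
  fw <- make_surrogate_forward(stiffening = 0.08, d_max = 12)
  se <- synth_experiment(0.004, forward = make_surrogate_forward(
    stiffening = 0.08, d_max = 9), preload_force = 0.14, noise_sd = 0,
    seed = 2)
  st <- calibrate(fw, se$curve, c1_init = 0.02, tol = 1e-6, max_iter = 30)
  cstar <- st$iterations$c1[nrow(st$iterations)]
  errs <- abs(st$iterations$c1 - cstar)
  errs <- errs[errs > 1e-12]
  expect_true(all(diff(errs) < 0))
})

test_that("parameter recovery across preload/noise conditions stays within budget", {
  set.seed(33)
  true_c1 <- runif(20, 0.001, 0.02)
  for (i in seq_along(true_c1)) {
    gen <- make_surrogate_forward(stiffening = 0.05, d_max = 8)
    peak <- max(gen(true_c1[i])$force)
    se <- synth_experiment(true_c1[i], forward = gen,
                           preload_force = runif(1, 0, 0.3),
                           noise_sd = 0.02 * peak, seed = 100 + i)
    st <- calibrate(make_surrogate_forward(stiffening = 0.05, d_max = 12),
                    se$curve)
    expect_true(st$converged)
    expect_lte(st$n_forward, 6L)
    expect_lt(abs(st$iterations$ratio[st$n_forward] - 1), 0.025)
  }
})

test_that("Brent baseline agrees with the ratio method and counts evaluations", {
  fw <- make_surrogate_forward(stiffening = 0, d_max = 10)
  target <- fw(0.006)
  exp0 <- indentation_curve(target$displacement, target$force)
  ratio_st <- calibrate(fw, exp0)
  brent_st <- calibrate_brent(fw, exp0)
  expect_true(brent_st$converged)
  # both satisfy the same 2.5% slope stopping rule
  expect_equal(brent_st$c1, ratio_st$c1, tolerance = 0.05)
  expect_lte(ratio_st$n_forward, brent_st$n_forward)
  # invalid bracket: slope mismatch has one sign on both ends
  expect_error(calibrate_brent(fw, exp0, bracket = c(0.05, 0.2)),
               class = "tissuecal_invalid_bracket")
})

test_that("forward-model failures propagate with iteration context", {
  bad <- function(c1) stop("solver exploded")
  exp0 <- indentation_curve(c(0, 1), c(0, 1))
  expect_error(calibrate(bad, exp0), class = "tissuecal_forward_failure")
  # max_iter exhaustion yields a non-converged state, not an error
  stubborn <- function(c1) indentation_curve(c(0, 1), c(0, 99), "simulated")
  st <- calibrate(function(c1) stubborn(c1), exp0, max_iter = 3)
  expect_false(st$converged)
  expect_equal(st$n_forward, 3L)
})
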