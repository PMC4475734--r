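test_that("pulse waveform is zero at onset, peaks at tau, decays as t*exp", {
  expect_equal(pulse_shape(0, tau_ms = 1), 0)
  expect_equal(pulse_shape(1, tau_ms = 1), 1)           # analytic maximum
  expect_equal(pulse_shape(2, tau_ms = 1), 2 * exp(-1)) # direct evaluation
  expect_equal(pulse_shape(-5, tau_ms = 1), 0)          # silent before onset
  # peak location and height scale with tau and amplitude
  expect_equal(pulse_shape(3, tau_ms = 3, amplitude = 2.5), 2.5)
  expect_lt(max(pulse_shape(seq(0, 20, 0.01), tau_ms = 3)), 1 + 1e-12)
  expect_error(pulse_shape(1, tau_ms = 0), "positive")
})

test_that("state stays at the fixed point without stimulation", {
  p <- release_params(tau_rec_ms = 32, tau_dep_ms = 5, p0 = 0.35, x0 = 1,
                      h = 0.1)
  traj <- simulate_release(p, silent_train(), dt_ms = 0.05)
  expect_lt(max(abs(traj$x - 1)), 1e-10)
  expect_lt(max(abs(traj$p - 0.35)), 1e-10)
})

test_that("occupancy relaxes monotonically to its steady state, both forms", {
  for (form in c("logistic", "linear")) {
    p <- release_params(tau_rec_ms = 30, tau_dep_ms = 50, p0 = 0.3,
                        x0 = 0.2, x_inf = 1, h = 0, relaxation = form)
    traj <- simulate_release(p, silent_train(), dt_ms = 0.05)
    gap <- abs(traj$x - 1)
    expect_true(all(diff(gap) <= 1e-12))
    expect_lt(gap[length(gap)], gap[1] / 5)
  }
})

test_that("release probability never exceeds 1", {
  for (cond in c("control", "6-OHDA")) {
    for (cls in c("STD", "STF", "STB")) {
      traj <- simulate_release(stsp_model_params(cond, cls))
      expect_lte(max(traj$p), 1 + 1e-9)
      expect_gte(min(traj$x), -1e-9)
    }
  }
  # extreme facilitation gain saturates p at 1 rather than overshooting
  hot <- release_params(tau_rec_ms = 50, tau_dep_ms = 500, p0 = 0.5,
                        x0 = 1, h = 5)
  expect_lte(max(simulate_release(hot)$p), 1 + 1e-6)
})

test_that("simulated dynamics reproduce the three qualitative classes", {
  std <- simulate_release(stsp_model_params("control", "STD"))
  expect_true(all(diff(std$normalized_release) < 0))
  expect_equal(std$normalized_release[1], 1, tolerance = 1e-8)

  stf <- simulate_release(stsp_model_params("control", "STF"))
  expect_true(all(diff(stf$normalized_release) > 0))
  expect_gt(stf$normalized_release[10], stf$normalized_release[1])

  stb <- simulate_release(stsp_model_params("control", "STB"))
  peak <- which.max(stb$normalized_release)
  expect_gt(peak, 1)
  expect_lt(peak, 10)
  expect_gt(max(stb$normalized_release), 1.1)
  expect_lt(stb$normalized_release[10], max(stb$normalized_release) - 0.1)
})

test_that("integration matches an independent adaptive-solver reference", {
  # reference: lsoda at rtol 1e-10 on the control facilitating set,
  # sampled at pulse onsets and normalized by x0*p0 (frozen values)
  lsoda_ref <- c(1.00000000, 1.34958550, 1.55398933, 1.66050380, 1.71398259,
                 1.74067407, 1.75406134, 1.76081918, 1.76424735, 1.76599185)
  sim <- simulate_release(stsp_model_params("control", "STF"), dt_ms = 0.05)
  expect_lt(max(rel_err(sim$normalized_release, lsoda_ref)), 0.01)

  # live cross-check against deSolve on the biphasic control set
  p <- stsp_model_params("control", "STB")
  tr <- stimulus_train()
  rhs <- function(t, y, parms) {
    f <- stspdyn:::train_forcing(tr, t)
    list(c(y[1] * (p$x_inf - y[1]) / p$tau_rec_ms - y[2] * y[1] * f,
           y[2] * (p$p_inf - y[2]) / p$tau_dep_ms + (1 - y[2]) * q_gain(p) * f))
  }
  out <- deSolve::lsoda(c(p$x0, p$p0), seq(0, 500, by = 0.5), rhs, NULL,
                        rtol = 1e-9, atol = 1e-11)
  onset_idx <- match(seq(0, 450, by = 50), out[, 1])
  ref <- out[onset_idx, 2] * out[onset_idx, 3] / (p$x0 * p$p0)
  sim2 <- simulate_release(p, tr, dt_ms = 0.05)
  expect_lt(max(rel_err(sim2$normalized_release, ref)), 1e-4)
})

test_that("halving the step changes per-pulse release by < 0.1%", {
  for (cond in c("control", "6-OHDA")) {
    for (cls in c("STD", "STF", "STB")) {
      p <- stsp_model_params(cond, cls)
      a <- simulate_release(p, dt_ms = 0.05)$per_pulse_release
      b <- simulate_release(p, dt_ms = 0.025)$per_pulse_release
      expect_lt(max(rel_err(a, b)), 1e-3)
    }
  }
})

test_that("windowed-max readout agrees with onset readout under depression", {
  # under depression the release product peaks at (within a forcing
  # rise-time of) each pulse onset, so the two readouts nearly coincide
  p <- stsp_model_params("control", "STD")
  a <- simulate_release(p, readout = "onset")$normalized_release
  b <- simulate_release(p, readout = "window_max")$normalized_release
  expect_lt(max(abs(a - b)), 1e-3)
})

test_that("single free parameters are recovered from noiseless simulations", {
  # p0 round trip for every bundled regime
  for (cond in c("control", "6-OHDA")) {
    for (cls in c("STD", "STF", "STB")) {
      truth <- stsp_model_params(cond, cls)
      curve <- as_normalized_curve(simulate_release(truth))
      start <- update_p0(truth, min(0.9, truth$p0 * 1.6))
      fit <- fit_model_to_curve(curve, start, "p0")
      expect_true(fit$converged)
      expect_lt(rel_err(fit$estimate[["p0"]], truth$p0), 1e-3)
    }
  }
  # remaining parameters on the control facilitating set
  truth <- stsp_model_params("control", "STF")
  curve <- as_normalized_curve(simulate_release(truth))
  perturb <- list(tau_rec_ms = 30, tau_dep_ms = 120, x0 = 0.5, h = 0.1)
  for (nm in names(perturb)) {
    start <- stspdyn:::update_release_params(truth, perturb[nm])
    fit <- fit_model_to_curve(curve, start, nm)
    expect_lt(rel_err(fit$estimate[[nm]], truth[[nm]]), 1e-3)
  }
})

test_that("self-fit leaves parameters unchanged", {
  truth <- stsp_model_params("control", "STD")
  curve <- as_normalized_curve(simulate_release(truth))
  fit <- fit_model_to_curve(curve, truth, "tau_rec_ms")
  expect_lt(rel_err(fit$estimate[["tau_rec_ms"]], truth$tau_rec_ms), 1e-6)
})

test_that("simulation and fitting guard their preconditions", {
  p <- stsp_model_params("control", "STD")
  expect_error(simulate_release(p, dt_ms = 0.5), "pulse_tau_ms/10")
  expect_error(simulate_release(p, dt_ms = -1), "> 0")
  curve <- as_normalized_curve(simulate_release(p))
  expect_error(fit_model_to_curve(curve, p, character()), "non-empty")
  expect_error(fit_model_to_curve(curve, p, "banana"), "subset")
  short <- normalized_curve(c(1, 0.8), x_ms = c(0, 50))
  expect_error(fit_model_to_curve(short, p, "p0"), "at least 3")
  expect_error(release_params(tau_rec_ms = -1, tau_dep_ms = 5, p0 = 0.5,
                              x0 = 1, h = 0.1), "tau_rec_ms")
  expect_error(release_params(tau_rec_ms = 10, tau_dep_ms = 5, p0 = 1.5,
                              x0 = 1, h = 0.1), "p0")
})

test_that("facilitation-gain conventions and parameter files round-trip", {
  p <- release_params(tau_rec_ms = 15, tau_dep_ms = 60, p0 = 0.2, x0 = 1,
                      h = 0.05)
  expect_equal(q_gain(p), 0.05)  # constant form: q_bar * h
  pe <- release_params(tau_rec_ms = 15, tau_dep_ms = 60, p0 = 0.2, x0 = 1,
                       h = 0.05, q_form = "exponential")
  expect_equal(q_gain(pe), 0.05 * exp(1 - 0.05 / 60))

  path <- withr::local_tempfile(fileext = ".yaml")
  write_release_params(pe, path)
  back <- read_release_params(path)
  expect_equal(back$q_form, "exponential")
  expect_equal(q_gain(back), q_gain(pe))
  expect_true(back$p_inf_tied)

  # round trip in either q convention recovers h from its own simulation
  curve <- as_normalized_curve(simulate_release(pe))
  fit <- fit_model_to_curve(curve, stspdyn:::update_release_params(pe, list(h = 0.2)), "h")
  expect_lt(rel_err(fit$estimate[["h"]], 0.05), 1e-3)
})
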