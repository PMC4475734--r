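test_that("exponential-product curve evaluates to its analytic values", {
  # e^0 = 1 at onset
  expect_equal(eval_eq1(list(A = 2, B = 0, C = 0, tau_rec_ms = 100,
                             tau_dep_ms = 20), 0), 1)
  # asymptote: exponentials vanish, leaves A*B + C
  expect_equal(eval_eq1(list(A = 1, B = -1, C = 1, tau_rec_ms = 10,
                             tau_dep_ms = 10), 1e7), 0, tolerance = 1e-12)
  # control depressing parameters at onset, against hand arithmetic:
  # (1.15 - 1) * (1 - 0.5) + 0.92 = 0.995
  row <- stsp_eq1_params("control", "STD")
  pars <- as.list(row[, c("A", "B", "C", "tau_rec_ms", "tau_dep_ms")])
  expect_equal(eval_eq1(pars, 0), 0.995)
  expect_error(eval_eq1(list(A = 1, B = 0, C = 0, tau_rec_ms = -1,
                             tau_dep_ms = 1), 0), "> 0")
})

test_that("noiseless exponential-product curves are recovered to 1e-4", {
  tab <- stsp_eq1_params()
  for (i in seq_len(nrow(tab))) {
    truth <- as.list(tab[i, c("A", "B", "C", "tau_rec_ms", "tau_dep_ms")])
    fit <- fit_eq1(eq1_curve_from_row(tab[i, ]))
    expect_true(fit$converged)
    err <- rel_err(unlist(fit$pars[names(truth)]), unlist(truth))
    expect_lt(max(err), 1e-4,
              label = sprintf("%s %s max rel err", tab$condition[i],
                              tab$class[i]))
  }
})

test_that("a flat curve fits no worse than its starting point", {
  curve <- normalized_curve(rep(1, 10))
  init <- list(A = 2, B = 1, C = -1, tau_rec_ms = 100, tau_dep_ms = 30)
  init$C <- 1 - (init$A - 1) * (1 + init$B)
  r0 <- sqrt(sum((eval_eq1(init, curve$x_ms) - curve$value)^2))
  fit <- fit_eq1(curve, init = init)
  expect_lte(fit$residual_norm, r0 + 1e-12)
})

test_that("noisy curve fits are unbiased within two standard errors", {
  tab <- stsp_eq1_params("control", "STD")
  truth <- as.list(tab[, c("A", "B", "C", "tau_rec_ms", "tau_dep_ms")])
  x <- seq(0, 450, by = 50)
  clean <- eval_eq1(truth, x)
  set.seed(7)
  est <- replicate(20, {
    noisy <- normalized_curve(clean + stats::rnorm(length(x), 0, 0.05),
                              x_ms = x)
    unlist(fit_eq1(noisy, init = truth)$pars)
  })
  for (nm in names(truth)) {
    m <- mean(est[nm, ])
    se <- stats::sd(est[nm, ]) / sqrt(ncol(est))
    expect_lt(abs(m - truth[[nm]]), 2 * se,
              label = sprintf("bias in %s", nm))
  }
})

test_that("sigmoid intensity-amplitude fits recover noiseless parameters", {
  tab <- stsp_ia_params()
  for (i in seq_len(nrow(tab))) {
    truth <- as.list(tab[i, c("a_max_pa", "k", "i_h_tu")])
    d <- gen_ia_data(truth, 1:8, noise_sd_pa = 0)
    fit <- fit_eq2(d$intensity_tu, d$amplitude_pa)
    expect_true(fit$converged)
    expect_lt(max(rel_err(unlist(fit$pars), unlist(truth))), 1e-4)
    # midpoint identity: amplitude at I_h is half the maximum
    expect_equal(eval_eq2(fit$pars, fit$pars$i_h_tu),
                 fit$pars$a_max_pa / 2)
  }
})

test_that("sigmoid fitting flags degenerate and rejects bad input", {
  flat <- fit_eq2(1:6, rep(50, 6))
  expect_true(flat$degenerate)
  expect_false(flat$converged)
  expect_error(fit_eq2(1:3, c(1, 2, 3)), "at least 4")
  expect_error(fit_eq2(c(0.5, 1, 2, 3), c(1, 2, 3, 4)), "threshold units")
})

test_that("recruitment index separates depressing from facilitating inputs", {
  ia <- stsp_ia_params("control")
  ri <- vapply(seq_len(nrow(ia)), function(i) {
    recruitment_index(as.list(ia[i, c("k", "i_h_tu")]))
  }, numeric(1))
  names(ri) <- ia$class
  expect_equal(unname(ri["STD"]), 2.3 / 2)       # 1.15
  expect_gte(ri[["STD"]], 1)
  expect_lt(ri[["STF"]], 1)                      # 1.2 / 3.1
  expect_lt(ri[["STB"]], 1)                      # 0.73 / 4.5
  expect_equal(recruitment_index(list(k = 0, i_h_tu = 2)), 0)
  expect_error(recruitment_index(list(k = 1, i_h_tu = 0)), "i_h_tu")
})

test_that("recruitment index is invariant to amplitude scaling", {
  truth <- as.list(stsp_ia_params("control", "STF")[, c("a_max_pa", "k",
                                                        "i_h_tu")])
  d <- gen_ia_data(truth, 1:8, noise_sd_pa = 0)
  f1 <- fit_eq2(d$intensity_tu, d$amplitude_pa)
  f2 <- fit_eq2(d$intensity_tu, d$amplitude_pa * 3.7)
  expect_equal(f2$pars$k, f1$pars$k, tolerance = 1e-6)
  expect_equal(f2$pars$i_h_tu, f1$pars$i_h_tu, tolerance = 1e-6)
  expect_equal(f2$pars$a_max_pa, f1$pars$a_max_pa * 3.7, tolerance = 1e-6)
  expect_equal(f2$recruitment_index, f1$recruitment_index, tolerance = 1e-6)
})

test_that("classification follows the curve shape rules", {
  expect_equal(as.character(
    classify_stsp(normalized_curve(c(1, 0.8, 0.6, 0.5, 0.45)))$label), "STD")
  expect_equal(as.character(
    classify_stsp(normalized_curve(c(1, 1.5, 2.0, 2.4, 2.6)))$label), "STF")
  lab <- classify_stsp(normalized_curve(c(1, 1.6, 1.4, 1.1, 0.9)))
  expect_equal(as.character(lab$label), "STB")
  expect_equal(lab$peak_pulse, 2)
  expect_false(lab$low_confidence)
  expect_error(classify_stsp(normalized_curve(c(1, 0.9, 0.8))), "at least 5")
  expect_error(classify_stsp(normalized_curve(rep(1, 5) + 0:4), delta = 0),
               "delta")
  # near-flat curve falls back with a low-confidence flag
  flat <- classify_stsp(normalized_curve(c(1, 1.02, 1.03, 1.02, 1.01)))
  expect_true(flat$low_confidence)
})

test_that("curves built from the bundled descriptive fits classify correctly", {
  tab <- stsp_eq1_params("control")
  labels <- vapply(seq_len(nrow(tab)), function(i) {
    as.character(classify_stsp(eq1_curve_from_row(tab[i, ]))$label)
  }, character(1))
  expect_equal(labels, tab$class)
})

test_that("the simulated biphasic regime classifies as biphasic", {
  curve <- as_normalized_curve(simulate_release(stsp_model_params("control",
                                                                  "STB")))
  lab <- classify_stsp(curve)
  expect_equal(as.character(lab$label), "STB")
  expect_false(lab$low_confidence)
})
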