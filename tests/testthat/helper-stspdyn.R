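# shared helpers for the stspdyn test suite

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# noiseless curve from one row of the bundled exponential-product table
eq1_curve_from_row <- function(row, x = seq(0, 450, by = 50)) {
  pars <- as.list(row[, c("A", "B", "C", "tau_rec_ms", "tau_dep_ms")])
  normalized_curve(eval_eq1(pars, x), x_ms = x)
}

# a quiet train with no effective forcing (amplitude 0), spanning ~1 s
silent_train <- function(span_ms = 1000) {
  stimulus_train(n_pulses = 1, frequency_hz = 1000 / span_ms,
                 pulse_amplitude = 0)
}
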