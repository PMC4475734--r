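#' Define a presynaptic stimulus train
#'
#' Describes a regular (or explicitly timed) train of presynaptic field
#' stimuli. Each pulse drives the release model through an alpha-shaped
#' forcing waveform \eqn{\phi(t) = A (t/\tau_\phi) e^{1 - t/\tau_\phi}} that
#' peaks at \eqn{t = \tau_\phi} with amplitude \eqn{A}.
#'
#' The default train reproduces the standard recording protocol for striatal
#' inhibitory inputs: 10 pulses at 20 Hz (50 ms interstimulus interval),
#' repeated every 10 s so that consecutive trains are independent.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param frequency_hz Train frequency in Hz; the interstimulus interval is
#'   `1000 / frequency_hz` ms.
#' @param pulse_amplitude Dimensionless forcing amplitude \eqn{A}.
#' @param pulse_tau_ms Forcing time-to-peak \eqn{\tau_\phi} in ms (> 0).
#' @param pulse_times_ms Optional explicit pulse onset times in ms (strictly
#'   increasing). Overrides `n_pulses`/`frequency_hz` spacing; the
#'   interstimulus interval used for the readout window is then the median
#'   spacing (or `1000 / frequency_hz` for a single pulse).
#' @return An object of class `stimulus_train`.
#' @examples
#' stimulus_train()                      # 10 pulses at 20 Hz
#' stimulus_train(n_pulses = 5, frequency_hz = 10)
#' @export
stimulus_train <- function(n_pulses = 10, frequency_hz = 20,
                           pulse_amplitude = 1, pulse_tau_ms = 1,
                           pulse_times_ms = NULL) {
  if (pulse_tau_ms <= 0) {
    stop("'pulse_tau_ms' must be > 0", call. = FALSE)
  }
  if (is.null(pulse_times_ms)) {
    if (n_pulses < 1) stop("'n_pulses' must be >= 1", call. = FALSE)
    if (frequency_hz <= 0) stop("'frequency_hz' must be > 0", call. = FALSE)
    isi <- 1000 / frequency_hz
    pulse_times_ms <- (seq_len(n_pulses) - 1) * isi
  } else {
    if (length(pulse_times_ms) < 1 || any(diff(pulse_times_ms) <= 0)) {
      stop("'pulse_times_ms' must be non-empty and strictly increasing",
           call. = FALSE)
    }
    n_pulses <- length(pulse_times_ms)
    isi <- if (n_pulses > 1) stats::median(diff(pulse_times_ms)) else
      1000 / frequency_hz
  }
  structure(
    list(pulse_times_ms = pulse_times_ms,
         n_pulses = as.integer(n_pulses),
         frequency_hz = frequency_hz,
         isi_ms = isi,
         pulse_amplitude = pulse_amplitude,
         pulse_tau_ms = pulse_tau_ms),
    class = "stimulus_train"
  )
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d pulses, ISI %.3g ms (%.3g Hz), phi: A=%.3g tau=%.3g ms\n",
              x$n_pulses, x$isi_ms, 1000 / x$isi_ms,
              x$pulse_amplitude, x$pulse_tau_ms))
  invisible(x)
}

#' Alpha-shaped pulse waveform
#'
#' Evaluates the presynaptic forcing waveform
#' \eqn{\phi(t) = A (t/\tau_\phi) e^{1 - t/\tau_\phi}} for \eqn{t \ge 0}
#' and 0 before onset. The waveform is 0 at onset, peaks at exactly
#' \eqn{A} when \eqn{t = \tau_\phi}, and decays with tail constant
#' \eqn{\tau_\phi}.
#'
#' @param t_ms Time since pulse onset, ms (vectorised).
#' @param tau_ms Time-to-peak \eqn{\tau_\phi} in ms (> 0).
#' @param amplitude Peak amplitude \eqn{A}.
#' @return Numeric vector of forcing values.
#' @examples
#' pulse_shape(1, tau_ms = 1)  # 1, the peak
#' pulse_shape(2, tau_ms = 1)  # 2 * exp(-1)
#' @export
pulse_shape <- function(t_ms, tau_ms = 1, amplitude = 1) {
  if (!is.numeric(tau_ms) || length(tau_ms) != 1 || tau_ms <= 0) {
    stop("'tau_ms' must be a single positive number", call. = FALSE)
  }
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  out[pos] <- amplitude * (t_ms[pos] / tau_ms) * exp(1 - t_ms[pos] / tau_ms)
  out
}

# Summed forcing of a whole train on a vector of absolute times.
train_forcing <- function(train, t_ms) {
  f <- numeric(length(t_ms))
  for (tk in train$pulse_times_ms) {
    f <- f + pulse_shape(t_ms - tk, train$pulse_tau_ms, train$pulse_amplitude)
  }
  f
}
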