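#' Construct a sweep set of evoked IPSC amplitudes
#'
#' A sweep set holds the per-pulse IPSC amplitudes of repeated stimulus
#' trains: one row per sweep (train repetition), one column per pulse.
#' Amplitudes are stored as positive magnitudes (baseline-to-peak)
#' regardless of recording polarity.
#'
#' @param amplitudes Numeric matrix, sweeps x pulses, in pA. All entries
#'   must be finite.
#' @param baseline_sd_pa Standard deviation of the baseline noise, pA
#'   (>= 0); used by [failure_rate()] and subtracted (as variance) by
#'   [variance_mean()].
#' @param frequency_hz Train frequency the sweeps were recorded at.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(amplitudes, baseline_sd_pa = 0, frequency_hz = 20) {
  amplitudes <- as.matrix(amplitudes)
  if (!is.numeric(amplitudes) || any(!is.finite(amplitudes))) {
    stop("'amplitudes' must be a finite numeric matrix", call. = FALSE)
  }
  if (baseline_sd_pa < 0) stop("'baseline_sd_pa' must be >= 0", call. = FALSE)
  colnames(amplitudes) <- paste0("pulse_", seq_len(ncol(amplitudes)))
  structure(
    list(amplitudes = amplitudes,
         n_sweeps = nrow(amplitudes),
         n_pulses = ncol(amplitudes),
         baseline_sd_pa = baseline_sd_pa,
         frequency_hz = frequency_hz),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d pulses at %g Hz, baseline SD %g pA\n",
              x$n_sweeps, x$n_pulses, x$frequency_hz, x$baseline_sd_pa))
  cat("  per-pulse mean (pA):", round(colMeans(x$amplitudes), 2), "\n")
  invisible(x)
}

#' Construct a normalized IPSC train curve
#'
#' Holds the per-pulse mean amplitude of a train, normalized by the first
#' pulse (IPSC_n / IPSC_1), with the time of each pulse from train onset
#' as abscissa and an optional per-point SEM.
#'
#' @param value Numeric vector of normalized amplitudes; `value[1]` is 1
#'   for self-normalized data.
#' @param x_ms Abscissa: time of each pulse from train onset, ms
#'   (non-negative, increasing). Defaults to 50 ms spacing (20 Hz).
#' @param sem Optional per-point SEM (same length as `value`).
#' @param n_sweeps Number of sweeps averaged, if known.
#' @return An object of class `normalized_curve`.
#' @export
normalized_curve <- function(value, x_ms = (seq_along(value) - 1) * 50,
                             sem = NULL, n_sweeps = NA_integer_) {
  if (length(value) != length(x_ms)) {
    stop("'value' and 'x_ms' must have the same length", call. = FALSE)
  }
  if (any(x_ms < 0) || any(diff(x_ms) <= 0)) {
    stop("'x_ms' must be non-negative and strictly increasing", call. = FALSE)
  }
  if (!is.null(sem) && length(sem) != length(value)) {
    stop("'sem' must match 'value' in length", call. = FALSE)
  }
  structure(
    list(pulse_index = seq_along(value), x_ms = x_ms,
         value = value, sem = sem, n_sweeps = n_sweeps),
    class = "normalized_curve"
  )
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve> %d pulses%s\n", length(x$value),
              if (is.na(x$n_sweeps)) "" else
                sprintf(" (from %d sweeps)", x$n_sweeps)))
  cat("  value:", round(x$value, 4), "\n")
  invisible(x)
}

#' Coerce a simulated trajectory to a normalized curve
#'
#' @param x A [simulate_release()] trajectory.
#' @return A [normalized_curve()] of the normalized per-pulse release, with
#'   pulse times as abscissa.
#' @export
as_normalized_curve <- function(x) {
  stopifnot(inherits(x, "release_trajectory"))
  normalized_curve(x$normalized_release, x_ms = x$pulse_times_ms)
}

#' Fraction of release failures at a given pulse
#'
#' A sweep counts as a failure at a pulse when its amplitude falls below
#' `threshold_sd` baseline standard deviations - i.e. the evoked response
#' is indistinguishable from baseline noise. Facilitating and biphasic
#' striatal inputs show substantial failure rates at the first pulse,
#' consistent with a low initial release probability; depressing inputs
#' show almost none.
#'
#' @param sweeps A [sweep_set()].
#' @param pulse Pulse index (1-based).
#' @param threshold_sd Detection threshold in baseline SD units (> 0,
#'   default 3).
#' @return Fraction of sweeps in `[0, 1]`.
#' @export
failure_rate <- function(sweeps, pulse = 1, threshold_sd = 3) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (pulse < 1 || pulse > sweeps$n_pulses) {
    stop("'pulse' out of range", call. = FALSE)
  }
  if (threshold_sd <= 0) stop("'threshold_sd' must be > 0", call. = FALSE)
  if (sweeps$baseline_sd_pa == 0) {
    stop("failure detection needs a positive 'baseline_sd_pa' in the sweep set",
         call. = FALSE)
  }
  mean(sweeps$amplitudes[, pulse] < threshold_sd * sweeps$baseline_sd_pa)
}

#' Variance-mean (multiple-probability fluctuation) analysis
#'
#' Under a binomial quantal model with `N` release sites of quantal size
#' `Q` and per-pulse release probability `P_n`, the per-pulse amplitude
#' mean and variance are \eqn{\mu_n = N P_n Q} and
#' \eqn{\sigma^2_n = N P_n (1 - P_n) Q^2}, so across pulses (which sample
#' different probabilities along the train) the variance is a concave
#' parabola in the mean:
#' \deqn{\sigma^2 = Q \mu - \mu^2 / N.}
#' Fitting this parabola to the per-pulse (mean, variance) points yields
#' the quantal size `q_hat`, the number of release sites `n_hat`, and the
#' weighted (apparent) release probability of the first pulse
#' \eqn{P_w = \mu_1 / (N Q)}. Dopamine depletion widens the parabola
#' (larger `n_hat`) and increases `P_w` at facilitating and biphasic
#' inputs.
#'
#' `variance_mean()` computes the per-pulse moments from a sweep set,
#' subtracts the known baseline variance, and delegates to
#' `variance_mean_points()`, which fits the parabola through the origin by
#' unweighted least squares (exact for noiseless binomial moments).
#'
#' @param sweeps A [sweep_set()] with at least 20 sweeps and at least 3
#'   pulses with distinct means.
#' @return An object of class `variance_mean_result`: list with `points`
#'   (data frame `mean_pa`, `var_pa2`), `q_hat`, `n_hat`, `pw`,
#'   `coefficients` of the parabola, `valid` (FALSE when the fitted
#'   parabola is not concave, in which case `pw` is `NA`), and
#'   `pw_clipped` (TRUE when `pw` was clipped into `[0, 1]`).
#' @examples
#' p <- seq(0.2, 0.8, by = 0.1)
#' mu <- 10 * p * 15
#' v <- 10 * p * (1 - p) * 15^2
#' variance_mean_points(mu, v)  # recovers Q = 15, N = 10 exactly
#' @export
variance_mean <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (sweeps$n_sweeps < 20) {
    stop("variance-mean analysis needs at least 20 sweeps", call. = FALSE)
  }
  mu <- colMeans(sweeps$amplitudes)
  v <- apply(sweeps$amplitudes, 2, stats::var) - sweeps$baseline_sd_pa^2
  if (length(unique(round(mu, 10))) < 3) {
    stop("variance-mean analysis needs at least 3 pulses with distinct means",
         call. = FALSE)
  }
  variance_mean_points(mu, v, mu_1 = mu[1])
}

#' @rdname variance_mean
#' @param mean_pa Per-pulse mean amplitudes, pA (baseline-free).
#' @param var_pa2 Per-pulse amplitude variances, pA^2, with baseline
#'   variance already removed.
#' @param mu_1 First-pulse mean used for `pw`; defaults to `mean_pa[1]`.
#' @export
variance_mean_points <- function(mean_pa, var_pa2, mu_1 = mean_pa[1]) {
  if (length(mean_pa) != length(var_pa2) || length(mean_pa) < 3) {
    stop("need at least 3 (mean, variance) points", call. = FALSE)
  }
  fit <- stats::lm(var_pa2 ~ 0 + mean_pa + I(mean_pa^2))
  a <- unname(stats::coef(fit)[1])   # = Q
  b <- unname(stats::coef(fit)[2])   # = -1/N
  valid <- is.finite(a) && is.finite(b) && b < 0 && a > 0
  q_hat <- if (valid) a else NA_real_
  n_hat <- if (valid) -1 / b else NA_real_
  pw <- NA_real_
  clipped <- FALSE
  if (valid) {
    pw <- mu_1 / (n_hat * q_hat)
    if (pw < 0 || pw > 1) {
      pw <- min(max(pw, 0), 1)
      clipped <- TRUE
    }
  }
  structure(
    list(points = data.frame(mean_pa = mean_pa, var_pa2 = var_pa2),
         q_hat = q_hat, n_hat = n_hat, pw = pw,
         coefficients = c(q = a, neg_inv_n = b),
         valid = valid, pw_clipped = clipped, mu_1 = mu_1),
    class = "variance_mean_result"
  )
}

#' @export
print.variance_mean_result <- function(x, ...) {
  cat("<variance_mean_result>\n")
  if (x$valid) {
    cat(sprintf("  quantal size Q = %.3g pA, release sites N = %.3g, Pw = %.3g%s\n",
                x$q_hat, x$n_hat, x$pw,
                if (x$pw_clipped) " (clipped)" else ""))
  } else {
    cat("  parabola fit not concave: Pw undefined\n")
  }
  invisible(x)
}

#' Weighted release probability from a variance-mean result
#'
#' Returns \eqn{P_w = \mu_1 / (\hat N \hat Q)}, the apparent release
#' probability of the first pulse implied by the fitted binomial parabola,
#' clipped into `[0, 1]` (with the `pw_clipped` flag preserved on the
#' input object).
#'
#' @param result A [variance_mean()] result with a valid concave fit.
#' @return A single probability.
#' @export
weighted_release_probability <- function(result) {
  stopifnot(inherits(result, "variance_mean_result"))
  if (!result$valid) {
    stop("weighted release probability undefined: parabola fit was not concave",
         call. = FALSE)
  }
  result$pw
}

#' Normalize a sweep set into an IPSC train curve
#'
#' Computes the across-sweep mean amplitude of each pulse and divides by
#' the first-pulse mean (ratio of means, robust to first-pulse failures in
#' individual sweeps). The SEM of each ratio is propagated by the delta
#' method including the covariance between pulse n and pulse 1.
#'
#' @param sweeps A [sweep_set()] whose first-pulse mean amplitude is
#'   positive.
#' @return A [normalized_curve()] with abscissa `(n-1) * ISI` ms.
#' @export
normalize_train <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  amp <- sweeps$amplitudes
  mu <- colMeans(amp)
  if (mu[1] <= 0) {
    stop("cannot normalize: first-pulse mean amplitude is not positive",
         call. = FALSE)
  }
  s <- sweeps$n_sweeps
  value <- unname(mu / mu[1])
  sem <- if (s >= 2) {
    cv <- stats::cov(amp)
    vapply(seq_along(mu), function(n) {
      # var of ratio mu_n/mu_1 by the delta method
      vr <- (cv[n, n] / mu[1]^2 +
               mu[n]^2 * cv[1, 1] / mu[1]^4 -
               2 * mu[n] * cv[n, 1] / mu[1]^3) / s
      sqrt(max(vr, 0))
    }, numeric(1))
  } else NULL
  isi <- 1000 / sweeps$frequency_hz
  normalized_curve(value, x_ms = (seq_along(mu) - 1) * isi,
                   sem = sem, n_sweeps = s)
}
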