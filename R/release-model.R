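#' Simulate the presynaptic release model over a stimulus train
#'
#' Integrates the two-variable release model
#' \deqn{dx/dt = x (x_\infty - x)/\tau_{Rec} - p \, x \sum_k \phi(t - t_k)}
#' \deqn{dp/dt = p (p_\infty - p)/\tau_{Dep} + (1 - p) \, q(h) \sum_k \phi(t - t_k)}
#' where `x` is the readily releasable pool occupancy, `p` the release
#' probability, and \eqn{\phi} the alpha-shaped pulse forcing of
#' [pulse_shape()] (with `relaxation = "linear"`, the first terms become
#' \eqn{(x_\infty - x)/\tau_{Rec}} and \eqn{(p_\infty - p)/\tau_{Dep}}).
#' Integration uses a fixed-step fourth-order Runge-Kutta scheme with the
#' forcing evaluated analytically on the full- and half-step grid; pulses
#' enter only through the continuous forcing, with no discrete state jumps.
#'
#' The released transmitter corresponds to the product `x(t) * p(t)`. The
#' per-pulse release is, by default (`readout = "onset"`), this product
#' sampled at each pulse onset - the amplitude a spike arriving at
#' \eqn{t_k} sees, and the local maximum of the release trace associated
#' with that pulse. `readout = "window_max"` instead takes the maximum of
#' the product over `[t_k, t_k + ISI)`; the two agree for depressing
#' dynamics but the window maximum trails the rising product into the next
#' interval under facilitation. Per-pulse values are also returned
#' normalized by the initial maximal release `x0 * p0`.
#'
#' @param params A [release_params()] object.
#' @param train A [stimulus_train()]; defaults to 10 pulses at 20 Hz.
#' @param dt_ms Integration step, ms; must be positive and at most
#'   `train$pulse_tau_ms / 10` so the pulse waveform is resolved.
#' @param readout Per-pulse release readout, `"onset"` (default) or
#'   `"window_max"`.
#' @return An object of class `release_trajectory`: a list with
#'   `time_ms`, `x`, `p`, `release` (= x*p), `pulse_times_ms`,
#'   `per_pulse_release`, `normalized_release`, plus the `params`, `train`,
#'   `dt_ms` and `readout` used.
#' @examples
#' traj <- simulate_release(stsp_model_params("control", "STD"))
#' round(traj$normalized_release, 3)  # monotonically depressing
#' @export
simulate_release <- function(params, train = stimulus_train(),
                             dt_ms = 0.05,
                             readout = c("onset", "window_max")) {
  readout <- match.arg(readout)
  stopifnot(inherits(params, "release_params"),
            inherits(train, "stimulus_train"))
  if (!is.numeric(dt_ms) || dt_ms <= 0) {
    stop("'dt_ms' must be > 0", call. = FALSE)
  }
  if (dt_ms > train$pulse_tau_ms / 10) {
    stop(sprintf("'dt_ms' (%g) must be <= pulse_tau_ms/10 (%g) to resolve the pulse waveform",
                 dt_ms, train$pulse_tau_ms / 10), call. = FALSE)
  }

  t_end <- train$pulse_times_ms[train$n_pulses] + train$isi_ms
  n_step <- ceiling(t_end / dt_ms)
  times <- seq(0, by = dt_ms, length.out = n_step + 1)

  # forcing is parameter-independent: precompute on full and half grid
  f_full <- train_forcing(train, times)
  f_half <- train_forcing(train, times[-length(times)] + dt_ms / 2)

  q <- q_gain(params)
  logistic <- params$relaxation == "logistic"
  tr <- params$tau_rec_ms; td <- params$tau_dep_ms
  xi <- params$x_inf; pi_ <- params$p_inf

  x <- numeric(n_step + 1); p <- numeric(n_step + 1)
  x[1] <- params$x0; p[1] <- params$p0

  deriv <- if (logistic) {
    function(xv, pv, f) c(xv * (xi - xv) / tr - pv * xv * f,
                          pv * (pi_ - pv) / td + (1 - pv) * q * f)
  } else {
    function(xv, pv, f) c((xi - xv) / tr - pv * xv * f,
                          (pi_ - pv) / td + (1 - pv) * q * f)
  }

  h2 <- dt_ms / 2
  for (i in seq_len(n_step)) {
    f1 <- f_full[i]; f2 <- f_half[i]; f4 <- f_full[i + 1]
    xv <- x[i]; pv <- p[i]
    k1 <- deriv(xv, pv, f1)
    k2 <- deriv(xv + h2 * k1[1], pv + h2 * k1[2], f2)
    k3 <- deriv(xv + h2 * k2[1], pv + h2 * k2[2], f2)
    k4 <- deriv(xv + dt_ms * k3[1], pv + dt_ms * k3[2], f4)
    x[i + 1] <- xv + dt_ms / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    p[i + 1] <- pv + dt_ms / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    if (!is.finite(x[i + 1]) || !is.finite(p[i + 1])) {
      stop(sprintf("integration failure: non-finite state at t = %.4g ms",
                   times[i + 1]), call. = FALSE)
    }
  }

  release <- x * p
  tk <- train$pulse_times_ms
  per_pulse <- if (readout == "onset") {
    idx <- pmin(round(tk / dt_ms) + 1, n_step + 1)
    release[idx]
  } else {
    vapply(seq_len(train$n_pulses), function(k) {
      win <- times >= tk[k] & times < tk[k] + train$isi_ms
      max(release[win])
    }, numeric(1))
  }

  structure(
    list(time_ms = times, x = x, p = p, release = release,
         pulse_times_ms = tk,
         per_pulse_release = per_pulse,
         normalized_release = per_pulse / (params$x0 * params$p0),
         params = params, train = train, dt_ms = dt_ms, readout = readout),
    class = "release_trajectory"
  )
}

#' @export
print.release_trajectory <- function(x, ...) {
  cat(sprintf("<release_trajectory> %d pulses, dt = %g ms, readout = %s\n",
              x$train$n_pulses, x$dt_ms, x$readout))
  cat("  normalized per-pulse release:\n  ")
  cat(round(x$normalized_release, 4), sep = " ")
  cat("\n")
  invisible(x)
}

# bounds used for constrained refits
model_param_bounds <- function() {
  list(tau_rec_ms = c(0.1, 1e4), tau_dep_ms = c(0.1, 1e4),
       p0 = c(0, 1), x0 = c(1e-6, 10), h = c(0, 10), q_bar = c(0, 100))
}

#' Refit release-model parameters to a normalized IPSC curve
#'
#' Adjusts a chosen subset of release-model parameters so that the
#' simulated normalized per-pulse release matches a normalized IPSC curve,
#' by bounded Levenberg-Marquardt least squares on the per-pulse residuals.
#' The optimisation is deterministic given the starting parameters: no
#' random restarts are performed.
#'
#' Steady states that were left tied at construction follow their free
#' partner: refitting `p0` on a tied parameter set moves `p_inf` with it,
#' preserving the resting-state-equals-steady-state convention.
#'
#' @param curve A [normalized_curve()] (or anything with a numeric `value`
#'   field of per-pulse normalized amplitudes), with at least 3 pulses.
#' @param init A [release_params()] object: starting values and the fixed
#'   values of the non-free parameters.
#' @param free_params Character vector naming the parameters to fit, a
#'   non-empty subset of `c("tau_rec_ms", "tau_dep_ms", "p0", "x0", "h",
#'   "q_bar")`.
#' @param train The [stimulus_train()] the curve was recorded under; by
#'   default reconstructed from the curve's abscissa spacing.
#' @param dt_ms,readout Passed to [simulate_release()].
#' @param control Passed to [minpack.lm::nls.lm.control()][minpack.lm::nls.lm].
#' @return An object of class `release_model_fit`: list with `params`
#'   (refitted [release_params()]), `free_params`, `estimate`, `std_error`
#'   (per free parameter), `residual_norm`, `converged`, `message`,
#'   `n_iter`.
#' @examples
#' truth <- stsp_model_params("control", "STD")
#' curve <- as_normalized_curve(simulate_release(truth))
#' fit <- fit_model_to_curve(curve, update_p0(truth, 0.5), "p0")
#' fit$estimate  # recovers p0 = 0.35
#' @export
fit_model_to_curve <- function(curve, init, free_params,
                               train = NULL, dt_ms = 0.05,
                               readout = c("onset", "window_max"),
                               control = list(maxiter = 200)) {
  readout <- match.arg(readout)
  stopifnot(inherits(init, "release_params"))
  value <- curve$value
  if (length(value) < 3) {
    stop("curve must have at least 3 pulses", call. = FALSE)
  }
  allowed <- names(model_param_bounds())
  if (length(free_params) == 0 || !all(free_params %in% allowed)) {
    stop("'free_params' must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (is.null(train)) {
    train <- train_from_curve(curve, n_pulses = length(value))
  }
  if (train$n_pulses != length(value)) {
    stop("train pulse count does not match curve length", call. = FALSE)
  }

  bounds <- model_param_bounds()[free_params]
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  start <- unlist(unclass(init)[free_params])

  resid_fun <- function(theta) {
    cand <- update_release_params(init, as.list(theta))
    sim <- simulate_release(cand, train, dt_ms = dt_ms, readout = readout)
    sim$normalized_release - value
  }

  res <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fun,
    control = do.call(minpack.lm::nls.lm.control, control)
  )

  est <- res$par
  names(est) <- free_params
  se <- tryCatch(sqrt(diag(solve(res$hessian)) * res$deviance /
                        max(1, length(value) - length(est))),
                 error = function(e) rep(NA_real_, length(est)))
  names(se) <- free_params
  converged <- res$info %in% 1:4

  structure(
    list(params = update_release_params(init, as.list(est)),
         free_params = free_params,
         estimate = est, std_error = se,
         residual_norm = sqrt(res$deviance),
         converged = converged, message = res$message,
         n_iter = res$niter),
    class = "release_model_fit"
  )
}

#' @export
print.release_model_fit <- function(x, ...) {
  cat("<release_model_fit>",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(data.frame(parameter = x$free_params,
                   estimate = unname(x$estimate),
                   std_error = unname(x$std_error)))
  cat(sprintf("  residual norm: %.4g after %d iterations\n",
              x$residual_norm, x$n_iter))
  invisible(x)
}

#' Convenience helpers for perturbed starting parameter sets
#'
#' Return a copy of a [release_params()] object with one field replaced
#' (tied steady states follow), typically to build a perturbed start for
#' [fit_model_to_curve()].
#'
#' @param params A [release_params()] object.
#' @param value New value for the field.
#' @return A [release_params()] object.
#' @export
update_p0 <- function(params, value) {
  update_release_params(params, list(p0 = value))
}

#' @rdname update_p0
#' @export
update_tau_dep <- function(params, value) {
  update_release_params(params, list(tau_dep_ms = value))
}

# Build a train matching a curve's abscissa (regular spacing assumed).
train_from_curve <- function(curve, n_pulses) {
  x <- curve$x_ms
  if (!is.null(x) && length(x) >= 2) {
    isi <- stats::median(diff(x))
    stimulus_train(n_pulses = n_pulses, frequency_hz = 1000 / isi)
  } else {
    stimulus_train(n_pulses = n_pulses)
  }
}
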