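#' Evaluate the product-of-exponentials description of a normalized train
#'
#' Normalized IPSC trains are described by a product of a recovery and a
#' depletion exponential,
#' \deqn{IPSC_n/IPSC_1 = (A - e^{-x/\tau_{Rec}}) (e^{-x/\tau_{Dep}} + B) + C,}
#' where `x` is the time of the nth stimulus from train onset (ms), `A` is
#' the initial steady-state value the recovery process approaches, `B` the
#' initial value of the depletion process, and `C` a balancing offset that
#' lets the fit start at 1. The two time constants here are descriptive
#' (they summarise the shape of the measured curve) and are kept distinct
#' from the mechanistic time constants of [release_params()].
#'
#' @param pars Named list or vector with `A`, `B`, `C`, `tau_rec_ms`,
#'   `tau_dep_ms` (time constants > 0).
#' @param x_ms Time from train onset, ms (vectorised, >= 0).
#' @return Numeric vector of normalized amplitudes.
#' @examples
#' eval_eq1(list(A = 2, B = 0, C = 0, tau_rec_ms = 100, tau_dep_ms = 20), 0)
#' @export
eval_eq1 <- function(pars, x_ms) {
  pars <- as.list(pars)
  if (pars$tau_rec_ms <= 0 || pars$tau_dep_ms <= 0) {
    stop("time constants must be > 0", call. = FALSE)
  }
  (pars$A - exp(-x_ms / pars$tau_rec_ms)) *
    (exp(-x_ms / pars$tau_dep_ms) + pars$B) + pars$C
}

# deterministic multistart grid used when no init is supplied
eq1_default_inits <- function() {
  grid <- expand.grid(A = c(1.5, 3, 5), B = c(-0.5, 1, 3),
                      tau_rec_ms = c(50, 150), tau_dep_ms = c(20, 100))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- as.list(grid[i, ])
    # balance C so the curve starts at 1
    g$C <- 1 - (g$A - 1) * (1 + g$B)
    g
  })
}

#' Fit the product-of-exponentials description to a normalized train
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of [eval_eq1()]
#' against a normalized IPSC curve. When the curve carries per-point SEMs,
#' residuals are weighted by 1/SEM^2. The starting offset `C` is always
#' rebalanced so the initial curve evaluates to 1 at `x = 0` (the fitting
#' procedure begins with value 1); the converged fit is unconstrained.
#'
#' With `init = NULL` a small deterministic grid of starting points is
#' tried and the fit with the lowest residual norm is returned; supplying
#' `init` makes the fit deterministic from that single start.
#'
#' @param curve A [normalized_curve()] with at least 5 points.
#' @param init Optional named list with `A`, `B`, `C`, `tau_rec_ms`,
#'   `tau_dep_ms` starting values.
#' @param weights `"sem"` (default; uses 1/SEM^2 when the curve has SEMs)
#'   or `"none"`.
#' @param control Passed to [minpack.lm::nls.lm.control()][minpack.lm::nls.lm].
#' @return An object of class `eq1_fit`: list with `pars` (named list of
#'   the five parameters), `std_error`, `residual_norm`, `converged`,
#'   `message`, `fitted` values.
#' @export
fit_eq1 <- function(curve, init = NULL, weights = c("sem", "none"),
                    control = list(maxiter = 500)) {
  weights <- match.arg(weights)
  value <- curve$value
  x <- curve$x_ms
  if (length(value) < 5) {
    stop("curve must have at least 5 points", call. = FALSE)
  }
  w <- rep(1, length(value))
  if (weights == "sem" && !is.null(curve$sem) && all(curve$sem > 0)) {
    w <- 1 / curve$sem^2
  }
  sw <- sqrt(w)

  lower <- c(A = -Inf, B = -Inf, C = -Inf, tau_rec_ms = 0.1, tau_dep_ms = 0.1)
  upper <- c(A = Inf, B = Inf, C = Inf, tau_rec_ms = 1e5, tau_dep_ms = 1e5)
  ord <- names(lower)

  one_fit <- function(start) {
    start <- as.list(start)
    start$C <- 1 - (start$A - 1) * (1 + start$B)  # begin with value 1 at x=0
    theta0 <- unlist(start[ord])
    resid_fun <- function(theta) {
      sw * (eval_eq1(as.list(theta), x) - value)
    }
    tryCatch(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = do.call(minpack.lm::nls.lm.control,
                                           control)),
      error = function(e) NULL
    )
  }

  inits <- if (is.null(init)) eq1_default_inits() else list(init)
  fits <- Filter(Negate(is.null), lapply(inits, one_fit))
  if (length(fits) == 0) {
    stop("all starting points failed in fit_eq1", call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]

  est <- as.list(best$par)
  se <- tryCatch(sqrt(diag(solve(best$hessian)) * best$deviance /
                        max(1, length(value) - 5)),
                 error = function(e) rep(NA_real_, 5))
  names(se) <- ord
  structure(
    list(pars = est, std_error = se,
         residual_norm = sqrt(best$deviance),
         converged = best$info %in% 1:4, message = best$message,
         fitted = eval_eq1(est, x), x_ms = x, value = value),
    class = "eq1_fit"
  )
}

#' @export
print.eq1_fit <- function(x, ...) {
  cat("<eq1_fit>", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(data.frame(parameter = names(x$pars),
                   estimate = unlist(x$pars),
                   std_error = unlist(x$std_error), row.names = NULL))
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' Sigmoid intensity-amplitude relationship
#'
#' Evaluates the three-parameter sigmoid
#' \deqn{A(I) = A_{max} / (1 + e^{-k (I - I_h)}),}
#' where `I` is stimulus intensity in threshold units (Tu), `a_max_pa` the
#' maximal IPSC amplitude, `i_h_tu` the intensity evoking half-maximal
#' amplitude, and `k` the slope factor (per Tu), proportional to how fast
#' release sites are recruited with stimulus strength.
#'
#' @param pars Named list or vector with `a_max_pa`, `k`, `i_h_tu`.
#' @param intensity_tu Stimulus intensities, Tu (vectorised).
#' @return Amplitudes in pA.
#' @export
eval_eq2 <- function(pars, intensity_tu) {
  pars <- as.list(pars)
  pars$a_max_pa / (1 + exp(-pars$k * (intensity_tu - pars$i_h_tu)))
}

#' Fit the intensity-amplitude sigmoid
#'
#' Least-squares fit of [eval_eq2()] to (intensity, amplitude) pairs by
#' Levenberg-Marquardt, with a data-driven default start (`a_max` at the
#' largest amplitude, `i_h` at the half-maximum crossing, `k = 1`).
#'
#' @param intensity_tu Stimulus intensities in threshold units (>= 1), at
#'   least 4 values.
#' @param amplitude_pa Evoked IPSC amplitudes, pA.
#' @param init Optional named list with `a_max_pa`, `k`, `i_h_tu`.
#' @param control Passed to [minpack.lm::nls.lm.control()][minpack.lm::nls.lm].
#' @return An object of class `ia_fit`: list with `pars`,
#'   `recruitment_index` (= k / i_h), `std_error`, `residual_norm`,
#'   `converged`, `degenerate` (TRUE when all amplitudes are equal, in
#'   which case no fit is attempted), `fitted`.
#' @export
fit_eq2 <- function(intensity_tu, amplitude_pa, init = NULL,
                    control = list(maxiter = 500)) {
  if (length(intensity_tu) != length(amplitude_pa) ||
      length(intensity_tu) < 4) {
    stop("need at least 4 (intensity, amplitude) pairs", call. = FALSE)
  }
  if (min(intensity_tu) < 1) {
    stop("intensities are in threshold units and must be >= 1", call. = FALSE)
  }
  if (diff(range(amplitude_pa)) == 0) {
    return(structure(
      list(pars = NULL, recruitment_index = NA_real_,
           std_error = NULL, residual_norm = NA_real_,
           converged = FALSE, degenerate = TRUE, fitted = NULL),
      class = "ia_fit"
    ))
  }
  if (is.null(init)) {
    half <- max(amplitude_pa) / 2
    i_half <- intensity_tu[which.min(abs(amplitude_pa - half))]
    init <- list(a_max_pa = max(amplitude_pa), k = 1, i_h_tu = i_half)
  }
  ord <- c("a_max_pa", "k", "i_h_tu")
  lower <- c(a_max_pa = 1e-9, k = 1e-6, i_h_tu = 1e-6)
  upper <- c(a_max_pa = Inf, k = Inf, i_h_tu = Inf)
  resid_fun <- function(theta) eval_eq2(as.list(theta), intensity_tu) -
    amplitude_pa
  res <- minpack.lm::nls.lm(par = unlist(init[ord]), lower = lower,
                            upper = upper, fn = resid_fun,
                            control = do.call(minpack.lm::nls.lm.control,
                                              control))
  est <- as.list(res$par)
  se <- tryCatch(sqrt(diag(solve(res$hessian)) * res$deviance /
                        max(1, length(amplitude_pa) - 3)),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- ord
  structure(
    list(pars = est,
         recruitment_index = est$k / est$i_h_tu,
         std_error = se, residual_norm = sqrt(res$deviance),
         converged = res$info %in% 1:4, degenerate = FALSE,
         fitted = eval_eq2(est, intensity_tu)),
    class = "ia_fit"
  )
}

#' @export
print.ia_fit <- function(x, ...) {
  cat("<ia_fit>")
  if (x$degenerate) {
    cat(" degenerate data (all amplitudes equal): no fit\n")
    return(invisible(x))
  }
  cat(if (x$converged) " (converged)\n" else " (NOT converged)\n")
  print(data.frame(parameter = names(x$pars), estimate = unlist(x$pars),
                   std_error = unlist(x$std_error), row.names = NULL))
  cat(sprintf("  recruitment index k/I_h = %.4g\n", x$recruitment_index))
  invisible(x)
}

#' Recruitment index of an intensity-amplitude fit
#'
#' The recruitment index is the sigmoid slope factor divided by the
#' half-maximal stimulus intensity, RI = k / I_h. Depressing striatal
#' inputs (which saturate quickly with stimulus strength) have RI > 1;
#' facilitating and biphasic inputs recruit release sites more slowly and
#' have RI < 1.
#'
#' @param fit An [fit_eq2()] result, or a named list with `k` and
#'   `i_h_tu`.
#' @return A single dimensionless index.
#' @examples
#' recruitment_index(list(k = 2.3, i_h_tu = 2))  # 1.15 -> depressing-like
#' @export
recruitment_index <- function(fit) {
  pars <- if (inherits(fit, "ia_fit")) fit$pars else as.list(fit)
  if (is.null(pars$k) || is.null(pars$i_h_tu)) {
    stop("need 'k' and 'i_h_tu'", call. = FALSE)
  }
  if (pars$i_h_tu <= 0) {
    stop("'i_h_tu' must be > 0", call. = FALSE)
  }
  pars$k / pars$i_h_tu
}

#' Classify short-term plasticity dynamics of a normalized train
#'
#' Labels a normalized IPSC curve as depressing (STD), facilitating (STF)
#' or biphasic (STB) from the shape of the curve. With peak value
#' `v_peak` at pulse `m` and final value `v_last`, and tolerance `delta`:
#' * STD: `v_last < 1 - delta` and the peak is the first pulse;
#' * STF: `v_last > 1 + delta` and the curve has not fallen from its peak
#'   by more than `delta`;
#' * STB: the peak comes after the first pulse, exceeds `1 + delta`, and
#'   the curve falls from it by at least `delta`.
#'
#' Curves matching none of the three patterns are assigned the nearest
#' label (by final value and peak drop) and flagged low-confidence.
#'
#' @param curve A [normalized_curve()] with at least 5 points.
#' @param delta Classification tolerance as a fraction of the first-pulse
#'   amplitude (> 0, default 0.1).
#' @return An object of class `stsp_label`: list with `label` (factor
#'   `"STD"`, `"STF"` or `"STB"`), `peak_pulse`, `low_confidence`, and an
#'   `evidence` list (`v_peak`, `v_last`, `peak_drop`).
#' @examples
#' classify_stsp(normalized_curve(c(1, 0.8, 0.6, 0.5, 0.45)))  # STD
#' @export
classify_stsp <- function(curve, delta = 0.1) {
  value <- curve$value
  if (length(value) < 5) {
    stop("classification needs at least 5 pulses", call. = FALSE)
  }
  if (delta <= 0) stop("'delta' must be > 0", call. = FALSE)
  m <- which.max(value)
  v_peak <- value[m]
  v_last <- value[length(value)]
  drop <- v_peak - v_last

  label <- NA_character_
  low_confidence <- FALSE
  if (v_last < 1 - delta && m == 1) {
    label <- "STD"
  } else if (v_last > 1 + delta && drop < delta) {
    label <- "STF"
  } else if (m > 1 && v_peak > 1 + delta && drop >= delta) {
    label <- "STB"
  } else {
    low_confidence <- TRUE
    label <- if (v_last < 1) "STD" else if (drop < delta) "STF" else "STB"
  }

  structure(
    list(label = factor(label, levels = c("STD", "STF", "STB")),
         peak_pulse = m, low_confidence = low_confidence,
         evidence = list(v_peak = v_peak, v_last = v_last,
                         peak_drop = drop, delta = delta)),
    class = "stsp_label"
  )
}

#' @export
print.stsp_label <- function(x, ...) {
  cat(sprintf("<stsp_label> %s%s (peak at pulse %d, v_peak = %.3g, v_last = %.3g)\n",
              as.character(x$label),
              if (x$low_confidence) " [low confidence]" else "",
              x$peak_pulse, x$evidence$v_peak, x$evidence$v_last))
  invisible(x)
}
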