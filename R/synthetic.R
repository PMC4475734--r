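#' Quantal generator parameters
#'
#' Parameters of the binomial quantal model used to synthesise sweep
#' sets: `n_sites` independent release sites, each releasing with the
#' per-pulse probability in `p_schedule` and contributing a quantum of
#' mean size `quantal_size_pa` (gamma-distributed with coefficient of
#' variation `cv_quantal`; a CV of 0 makes every quantum exactly
#' `quantal_size_pa`). Gaussian baseline noise of SD `baseline_sd_pa` is
#' added to every amplitude, emulating the recording noise floor that
#' produces apparent failures.
#'
#' @param n_sites Integer number of release sites N (>= 1).
#' @param quantal_size_pa Mean quantal amplitude Q, pA (> 0).
#' @param p_schedule Per-pulse release probabilities, each in `[0, 1]`;
#'   its length sets the number of pulses.
#' @param baseline_sd_pa Baseline noise SD, pA (>= 0).
#' @param cv_quantal Coefficient of variation of the quantal size (>= 0,
#'   default 0.3).
#' @return An object of class `quantal_params`.
#' @export
quantal_params <- function(n_sites, quantal_size_pa, p_schedule,
                           baseline_sd_pa = 0, cv_quantal = 0.3) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(n_sites >= 1, "'n_sites' must be >= 1")
  chk(quantal_size_pa > 0, "'quantal_size_pa' must be > 0")
  chk(length(p_schedule) >= 1 && all(p_schedule >= 0 & p_schedule <= 1),
      "'p_schedule' entries must lie in [0, 1]")
  chk(baseline_sd_pa >= 0, "'baseline_sd_pa' must be >= 0")
  chk(cv_quantal >= 0, "'cv_quantal' must be >= 0")
  structure(
    list(n_sites = as.integer(n_sites),
         quantal_size_pa = quantal_size_pa,
         p_schedule = p_schedule,
         n_pulses = length(p_schedule),
         baseline_sd_pa = baseline_sd_pa,
         cv_quantal = cv_quantal),
    class = "quantal_params"
  )
}

#' @export
print.quantal_params <- function(x, ...) {
  cat(sprintf("<quantal_params> N = %d sites, Q = %g pA (CV %g), baseline SD %g pA\n",
              x$n_sites, x$quantal_size_pa, x$cv_quantal, x$baseline_sd_pa))
  cat("  p_schedule:", round(x$p_schedule, 3), "\n")
  invisible(x)
}

#' Per-pulse release-probability schedule from a model simulation
#'
#' Turns a release-model simulation into a per-site probability schedule
#' for the quantal generator: the schedule is proportional to the
#' simulated normalized per-pulse release, scaled so the first pulse
#' equals `p1` (by default the model's initial release probability), and
#' clipped to `[0, 1]`. Clipping is reported through the `"saturated"`
#' attribute, which matters for strongly facilitating dopamine-depleted
#' regimes. The mapping from modeled release to per-site probability is a
#' proportionality convenience linking the two descriptions, not a
#' mechanistic identity.
#'
#' @param params A [release_params()] object.
#' @param train A [stimulus_train()].
#' @param p1 First-pulse per-site release probability; defaults to
#'   `params$p0`.
#' @param dt_ms Integration step for the underlying simulation.
#' @return Numeric vector of per-pulse probabilities with attribute
#'   `saturated` (TRUE if any value was clipped at 1).
#' @examples
#' schedule_from_model(stsp_model_params("control", "STF"))
#' @export
schedule_from_model <- function(params, train = stimulus_train(),
                                p1 = params$p0, dt_ms = 0.05) {
  sim <- simulate_release(params, train, dt_ms = dt_ms)
  sched <- p1 * sim$normalized_release
  saturated <- any(sched > 1)
  sched <- pmin(pmax(sched, 0), 1)
  attr(sched, "saturated") <- saturated
  sched
}

#' Generate synthetic quantal sweep sets
#'
#' Draws `n_sweeps` repetitions of a stimulus train from the binomial
#' quantal model: at each pulse the number of releasing sites is
#' `Binomial(n_sites, p_schedule[pulse])`, the summed quantal content is
#' gamma-distributed (the sum of k independent gamma quanta), and
#' Gaussian baseline noise is added. Output is reproducible for a fixed
#' seed; the seed is stretched into an operation-specific substream so
#' that different generator operations sharing one root seed stay
#' independent.
#'
#' @param q A [quantal_params()] object.
#' @param n_sweeps Number of sweeps (>= 1).
#' @param seed Integer seed.
#' @param frequency_hz Train frequency recorded in the sweep set.
#' @return A [sweep_set()] with attribute `seed`.
#' @examples
#' qp <- quantal_params(10, 15, rep(0.5, 10), baseline_sd_pa = 2)
#' gen_quantal_sweeps(qp, n_sweeps = 25, seed = 1)
#' @export
gen_quantal_sweeps <- function(q, n_sweeps, seed, frequency_hz = 20) {
  stopifnot(inherits(q, "quantal_params"))
  if (n_sweeps < 1) stop("'n_sweeps' must be >= 1", call. = FALSE)
  amp <- matrix(0, nrow = n_sweeps, ncol = q$n_pulses)
  with_substream(seed, "gen_quantal_sweeps", {
    for (j in seq_len(q$n_pulses)) {
      k <- stats::rbinom(n_sweeps, q$n_sites, q$p_schedule[j])
      quanta <- if (q$cv_quantal > 0) {
        # sum of k gamma quanta is gamma with shape k/cv^2
        shape <- k / q$cv_quantal^2
        out <- numeric(n_sweeps)
        nz <- k > 0
        out[nz] <- stats::rgamma(sum(nz), shape = shape[nz],
                                 scale = q$quantal_size_pa * q$cv_quantal^2)
        out
      } else {
        k * q$quantal_size_pa
      }
      noise <- if (q$baseline_sd_pa > 0) {
        stats::rnorm(n_sweeps, 0, q$baseline_sd_pa)
      } else 0
      amp[, j] <- quanta + noise
    }
  })
  out <- sweep_set(amp, baseline_sd_pa = q$baseline_sd_pa,
                   frequency_hz = frequency_hz)
  attr(out, "seed") <- seed
  out
}

#' Generate synthetic intensity-amplitude data
#'
#' Evaluates the intensity-amplitude sigmoid [eval_eq2()] at the given
#' stimulus intensities and adds Gaussian noise, emulating graded-
#' intensity input-output measurements in threshold units.
#'
#' @param pars Named list with `a_max_pa`, `k`, `i_h_tu` (e.g. one row of
#'   [stsp_ia_params()]).
#' @param intensity_tu Stimulus intensities, threshold units (>= 1).
#' @param noise_sd_pa Gaussian noise SD, pA (>= 0).
#' @param seed Integer seed.
#' @return A data frame with columns `intensity_tu` and `amplitude_pa`.
#' @export
gen_ia_data <- function(pars, intensity_tu, noise_sd_pa = 0, seed = 1) {
  if (min(intensity_tu) < 1) {
    stop("intensities are in threshold units and must be >= 1", call. = FALSE)
  }
  amp <- eval_eq2(pars, intensity_tu)
  if (noise_sd_pa > 0) {
    with_substream(seed, "gen_ia_data", {
      amp <- amp + stats::rnorm(length(amp), 0, noise_sd_pa)
    })
  }
  data.frame(intensity_tu = intensity_tu, amplitude_pa = amp)
}

# Run code under a deterministic, operation-specific RNG substream,
# restoring the caller's RNG state afterwards.
with_substream <- function(seed, op, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, op))
  eval.parent(substitute(code))
}

# Map (root seed, operation name) to a 31-bit substream seed.
substream_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op))) %% 104729
  (as.integer(seed) %% 2147483L) * 1000L + as.integer(h %% 1000L)
}
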