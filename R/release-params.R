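#' Presynaptic release-model parameters
#'
#' Bundles the parameters of the two-variable presynaptic release model: the
#' readily releasable pool (RRP) occupancy `x(t)` relaxes toward its steady
#' state with time constant `tau_rec_ms` and is consumed by release, while
#' the release probability `p(t)` relaxes with time constant `tau_dep_ms`
#' and is incremented by each pulse through a facilitation gain `q(h)`.
#'
#' By default the steady states equal the initial conditions
#' (`x_inf = x0`, `p_inf = p0`): a terminal at rest between trains sits at
#' its steady state, which is the regime of trains delivered every 10 s.
#' Supplying `x_inf` or `p_inf` explicitly decouples them; otherwise they
#' remain tied, so that a fit that moves `p0` moves `p_inf` with it.
#'
#' Two readings of the facilitation gain are available:
#' `q_form = "constant"` (default) uses \eqn{q(h) = \bar q h}, so with
#' \eqn{\bar q = 1} the tabulated `h` values act directly as per-pulse
#' facilitation gains; `q_form = "exponential"` uses
#' \eqn{q(h) = \bar q h e^{1 - h/\tau_{Dep}}}. Both are interpretations of
#' an ambiguously printed formula and are interchangeable as long as
#' generation and fitting use the same convention.
#'
#' Similarly, `relaxation` selects between the state-multiplied
#' ("logistic", default) recovery terms \eqn{x(x_\infty - x)/\tau_{Rec}}
#' and the linear terms \eqn{(x_\infty - x)/\tau_{Rec}}.
#'
#' @param tau_rec_ms RRP recovery time constant, ms (> 0).
#' @param tau_dep_ms Release-probability time constant, ms (> 0).
#' @param p0 Initial release probability in `[0, 1]`.
#' @param x0 Initial RRP occupancy (> 0), dimensionless.
#' @param h Facilitation parameter (>= 0), dimensionless.
#' @param x_inf Steady-state occupancy; defaults to `x0` (tied).
#' @param p_inf Steady-state release probability; defaults to `p0` (tied).
#' @param q_bar Maximum probability increment \eqn{\bar q} (>= 0).
#' @param q_form Facilitation-gain reading, `"constant"` or `"exponential"`.
#' @param relaxation Relaxation term form, `"logistic"` or `"linear"`.
#' @return An object of class `release_params`.
#' @seealso [simulate_release()], [fit_model_to_curve()],
#'   [stsp_model_params()] for the bundled reference parameter sets.
#' @examples
#' release_params(tau_rec_ms = 32, tau_dep_ms = 5, p0 = 0.35, x0 = 1, h = 0.1)
#' @export
release_params <- function(tau_rec_ms, tau_dep_ms, p0, x0, h,
                           x_inf = NULL, p_inf = NULL,
                           q_bar = 1,
                           q_form = c("constant", "exponential"),
                           relaxation = c("logistic", "linear")) {
  q_form <- match.arg(q_form)
  relaxation <- match.arg(relaxation)
  x_inf_tied <- is.null(x_inf)
  p_inf_tied <- is.null(p_inf)
  if (x_inf_tied) x_inf <- x0
  if (p_inf_tied) p_inf <- p0

  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(tau_rec_ms) && tau_rec_ms > 0, "'tau_rec_ms' must be > 0")
  chk(is.numeric(tau_dep_ms) && tau_dep_ms > 0, "'tau_dep_ms' must be > 0")
  chk(p0 >= 0 && p0 <= 1, "'p0' must lie in [0, 1]")
  chk(p_inf >= 0 && p_inf <= 1, "'p_inf' must lie in [0, 1]")
  chk(x0 > 0, "'x0' must be > 0")
  chk(x_inf > 0, "'x_inf' must be > 0")
  chk(h >= 0, "'h' must be >= 0")
  chk(q_bar >= 0, "'q_bar' must be >= 0")

  structure(
    list(tau_rec_ms = tau_rec_ms, tau_dep_ms = tau_dep_ms,
         p0 = p0, x0 = x0, h = h,
         x_inf = x_inf, p_inf = p_inf,
         x_inf_tied = x_inf_tied, p_inf_tied = p_inf_tied,
         q_bar = q_bar, q_form = q_form, relaxation = relaxation),
    class = "release_params"
  )
}

#' @export
print.release_params <- function(x, ...) {
  cat("<release_params>\n")
  cat(sprintf("  tau_rec = %g ms, tau_dep = %g ms\n", x$tau_rec_ms, x$tau_dep_ms))
  cat(sprintf("  p0 = %g (p_inf = %g%s), x0 = %g (x_inf = %g%s)\n",
              x$p0, x$p_inf, if (x$p_inf_tied) ", tied" else "",
              x$x0, x$x_inf, if (x$x_inf_tied) ", tied" else ""))
  cat(sprintf("  h = %g, q_bar = %g, q(h) = %g [%s], relaxation = %s\n",
              x$h, x$q_bar, q_gain(x), x$q_form, x$relaxation))
  invisible(x)
}

#' Facilitation gain q(h) of a parameter set
#'
#' @param params A [release_params()] object.
#' @return The per-pulse probability-increment gain implied by the chosen
#'   `q_form`.
#' @export
q_gain <- function(params) {
  switch(params$q_form,
         constant = params$q_bar * params$h,
         exponential = params$q_bar * params$h *
           exp(1 - params$h / params$tau_dep_ms))
}

# Update a subset of fields, re-tying steady states where they were tied.
update_release_params <- function(params, values) {
  for (nm in names(values)) params[[nm]] <- values[[nm]]
  release_params(
    tau_rec_ms = params$tau_rec_ms, tau_dep_ms = params$tau_dep_ms,
    p0 = params$p0, x0 = params$x0, h = params$h,
    x_inf = if (params$x_inf_tied) NULL else params$x_inf,
    p_inf = if (params$p_inf_tied) NULL else params$p_inf,
    q_bar = params$q_bar, q_form = params$q_form,
    relaxation = params$relaxation
  )
}

#' Reference release-model parameter sets
#'
#' Returns the bundled presynaptic model parameter sets for the six
#' condition-by-class regimes of striatal GABAergic inputs: control and
#' dopamine-depleted (6-OHDA) versions of depressing (STD), facilitating
#' (STF) and biphasic (STB) synapses. The sets are read from the package's
#' plain-text fixture table.
#'
#' @param condition `"control"` or `"6-OHDA"`.
#' @param class One of `"STD"`, `"STF"`, `"STB"`.
#' @param ... Passed on to [release_params()] (e.g. `q_form`, `relaxation`).
#' @return A [release_params()] object.
#' @examples
#' stsp_model_params("control", "STD")
#' @export
stsp_model_params <- function(condition = c("control", "6-OHDA"),
                              class = c("STD", "STF", "STB"), ...) {
  condition <- match.arg(condition)
  class <- match.arg(class)
  tab <- read_fixture_table("model_params.csv")
  row <- tab[tab$condition == condition & tab$class == class, ]
  release_params(tau_rec_ms = row$tau_rec_ms, tau_dep_ms = row$tau_dep_ms,
                 p0 = row$p0, x0 = row$x0, h = row$h, ...)
}

#' Reference descriptive-fit parameter sets for normalized IPSC trains
#'
#' Parameters of the product-of-exponentials description of normalized
#' IPSC trains (see [eval_eq1()]) for the six condition-by-class regimes,
#' as a data frame with one row per regime.
#'
#' @param condition Optional filter, `"control"` or `"6-OHDA"`.
#' @param class Optional filter, `"STD"`, `"STF"` or `"STB"`.
#' @return A data frame with columns `condition`, `class`, `A`,
#'   `tau_rec_ms`, `tau_dep_ms`, `B`, `C`.
#' @export
stsp_eq1_params <- function(condition = NULL, class = NULL) {
  tab <- read_fixture_table("eq1_params.csv")
  if (!is.null(condition)) tab <- tab[tab$condition == condition, ]
  if (!is.null(class)) tab <- tab[tab$class == class, ]
  tab
}

#' Reference intensity-amplitude sigmoid parameter sets
#'
#' Sigmoid input-output parameters (see [fit_eq2()]) for the six
#' condition-by-class regimes: maximal amplitude `a_max_pa` (pA), slope
#' factor `k` (per threshold unit) and half-maximal intensity `i_h_tu`
#' (threshold units).
#'
#' @inheritParams stsp_eq1_params
#' @return A data frame with columns `condition`, `class`, `a_max_pa`,
#'   `k`, `i_h_tu`.
#' @export
stsp_ia_params <- function(condition = NULL, class = NULL) {
  tab <- read_fixture_table("ia_params.csv")
  if (!is.null(condition)) tab <- tab[tab$condition == condition, ]
  if (!is.null(class)) tab <- tab[tab$class == class, ]
  tab
}

read_fixture_table <- function(name) {
  path <- system.file("extdata", name, package = "stspdyn")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", name)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read or write a release-parameter set as flat key-value YAML
#'
#' The on-disk dialect is a flat mapping with keys `tau_rec_ms`,
#' `tau_dep_ms`, `p0`, `x0`, `h`, and optionally `x_inf`, `p_inf`,
#' `q_bar`, `q_form`, `relaxation`. Tied steady states are omitted on
#' write so that re-reading preserves the tie.
#'
#' @param path File path.
#' @return `read_release_params()` returns a [release_params()] object;
#'   `write_release_params()` returns `path` invisibly.
#' @export
read_release_params <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  release_params(
    tau_rec_ms = y$tau_rec_ms, tau_dep_ms = y$tau_dep_ms,
    p0 = y$p0, x0 = y$x0, h = y$h,
    x_inf = y$x_inf, p_inf = y$p_inf,
    q_bar = if (is.null(y$q_bar)) 1 else y$q_bar,
    q_form = if (is.null(y$q_form)) "constant" else y$q_form,
    relaxation = if (is.null(y$relaxation)) "logistic" else y$relaxation
  )
}

#' @rdname read_release_params
#' @param params A [release_params()] object.
#' @export
write_release_params <- function(params, path) {
  y <- list(tau_rec_ms = params$tau_rec_ms, tau_dep_ms = params$tau_dep_ms,
            p0 = params$p0, x0 = params$x0, h = params$h,
            q_bar = params$q_bar, q_form = params$q_form,
            relaxation = params$relaxation)
  if (!params$x_inf_tied) y$x_inf <- params$x_inf
  if (!params$p_inf_tied) y$p_inf <- params$p_inf
  yaml::write_yaml(y, path)
  invisible(path)
}
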