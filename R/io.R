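#' Read and write sweep tables
#'
#' Sweep tables are comma-separated UTF-8 text with a mandatory header
#' row, one row per sweep and columns `pulse_1 .. pulse_n` of amplitudes
#' in pA. Recording metadata (train frequency, baseline noise SD) lives
#' in a YAML sidecar; by default `<path>` with a `.meta.yaml` extension.
#'
#' @param path Path to the sweep CSV.
#' @param meta_path Optional path of the metadata sidecar; if missing, a
#'   default sidecar path is tried and defaults are used when absent.
#' @return `read_sweep_table()` returns a [sweep_set()];
#'   `write_sweep_table()` returns `path` invisibly.
#' @export
read_sweep_table <- function(path, meta_path = NULL) {
  if (!file.exists(path)) {
    stop("sweep table not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("empty sweep table: ", path, call. = FALSE)
  }
  if (length(lines) == 1) {
    stop("sweep table has a header but no sweeps: ", path, call. = FALSE)
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (any(!is.na(suppressWarnings(as.numeric(header))))) {
    stop("sweep table must start with a non-numeric header row: ", path,
         call. = FALSE)
  }
  n_col <- length(header)
  rows <- lapply(seq_along(lines[-1]), function(i) {
    cells <- strsplit(lines[i + 1], ",", fixed = TRUE)[[1]]
    if (length(cells) != n_col) {
      stop(sprintf("malformed row %d in %s: expected %d cells, found %d",
                   i + 1, path, n_col, length(cells)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("non-numeric cell at row %d, column %d ('%s') in %s",
                   i + 1, bad, cells[bad], path), call. = FALSE)
    }
    vals
  })
  amp <- do.call(rbind, rows)
  colnames(amp) <- header

  if (is.null(meta_path)) {
    meta_path <- default_meta_path(path)
  }
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  sweep_set(amp,
            baseline_sd_pa = meta$baseline_sd_pa %||% 0,
            frequency_hz = meta$frequency_hz %||% 20)
}

#' @rdname read_sweep_table
#' @param sweeps A [sweep_set()].
#' @export
write_sweep_table <- function(sweeps, path, meta_path = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"))
  utils::write.csv(as.data.frame(sweeps$amplitudes), path,
                   row.names = FALSE, quote = FALSE)
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  yaml::write_yaml(list(frequency_hz = sweeps$frequency_hz,
                        baseline_sd_pa = sweeps$baseline_sd_pa),
                   meta_path)
  invisible(path)
}

default_meta_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0(".meta.yaml")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write normalized curves as delimited text
#'
#' Columns: `pulse_index`, `x_ms`, `value` and optionally `sem`.
#'
#' @param path File path.
#' @return `read_normalized_curve()` returns a [normalized_curve()];
#'   `write_normalized_curve()` returns `path` invisibly.
#' @export
read_normalized_curve <- function(path) {
  if (!file.exists(path)) {
    stop("curve file not found: ", path, call. = FALSE)
  }
  d <- utils::read.csv(path)
  normalized_curve(d$value, x_ms = d$x_ms,
                   sem = if ("sem" %in% names(d)) d$sem else NULL)
}

#' @rdname read_normalized_curve
#' @param curve A [normalized_curve()].
#' @export
write_normalized_curve <- function(curve, path) {
  d <- data.frame(pulse_index = curve$pulse_index, x_ms = curve$x_ms,
                  value = curve$value)
  if (!is.null(curve$sem)) d$sem <- curve$sem
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report
#'
#' Writes a `(parameter, estimate, estimation_error)` CSV for any of the
#' package's fit objects ([fit_eq1()], [fit_eq2()],
#' [fit_model_to_curve()]).
#'
#' @param fit A fit object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  tab <- fit_report_table(fit)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_report_table <- function(fit) {
  if (inherits(fit, "eq1_fit") || inherits(fit, "ia_fit")) {
    if (isTRUE(fit$degenerate)) {
      return(data.frame(parameter = character(), estimate = numeric(),
                        estimation_error = numeric()))
    }
    data.frame(parameter = names(fit$pars),
               estimate = unname(unlist(fit$pars)),
               estimation_error = unname(unlist(fit$std_error)))
  } else if (inherits(fit, "release_model_fit")) {
    data.frame(parameter = fit$free_params,
               estimate = unname(fit$estimate),
               estimation_error = unname(fit$std_error))
  } else {
    stop("unsupported fit object of class ", paste(class(fit), collapse = "/"),
         call. = FALSE)
  }
}

#' Export a simulated trajectory as delimited text
#'
#' Writes the full time course (`time_ms`, `x`, `p`, `release`) and,
#' optionally, the per-pulse table (`pulse_index`, `t_on_ms`,
#' `max_release`, `normalized_release`).
#'
#' @param traj A [simulate_release()] trajectory.
#' @param path Output CSV path for the time course.
#' @param pulse_path Optional output CSV path for the per-pulse table.
#' @param thin Keep every `thin`-th time sample (default 1, keep all).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, pulse_path = NULL, thin = 1) {
  stopifnot(inherits(traj, "release_trajectory"))
  keep <- seq(1, length(traj$time_ms), by = thin)
  utils::write.csv(
    data.frame(time_ms = traj$time_ms[keep], x = traj$x[keep],
               p = traj$p[keep], release = traj$release[keep]),
    path, row.names = FALSE, quote = FALSE)
  if (!is.null(pulse_path)) {
    utils::write.csv(
      data.frame(pulse_index = seq_along(traj$per_pulse_release),
                 t_on_ms = traj$pulse_times_ms,
                 max_release = traj$per_pulse_release,
                 normalized_release = traj$normalized_release),
      pulse_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
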