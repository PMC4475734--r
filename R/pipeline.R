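#' Run the full analysis pipeline
#'
#' Executes the package's stages end to end and writes every product to
#' an output directory with a JSON manifest: synthetic sweep generation
#' (or reading of an existing sweep table), train normalization,
#' descriptive exponential-product fitting, release-model refitting,
#' variance-mean analysis, intensity-amplitude fitting on generated
#' sigmoid data, and STSP classification. Numeric outputs are
#' bit-reproducible for a fixed seed.
#'
#' @param config A named list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{out_dir}{Output directory (created if needed). Mandatory.}
#'     \item{seed}{Integer root seed (default 1).}
#'     \item{sweep_table}{Optional path to an existing sweep CSV; when
#'       absent, sweeps are generated from the model regime below.}
#'     \item{condition, class}{Model regime for synthesis, e.g.
#'       `"control"` / `"STD"` (defaults).}
#'     \item{n_sweeps}{Sweeps to generate (default 200).}
#'     \item{n_sites, quantal_size_pa, baseline_sd_pa, cv_quantal}{Quantal
#'       generator settings (defaults 10, 15, 2, 0.3).}
#'     \item{dt_ms}{Integration step (default 0.05).}
#'     \item{q_form}{Facilitation-gain reading (default `"constant"`).}
#'     \item{delta_classify}{Classification tolerance (default 0.1).}
#'     \item{threshold_sd}{Failure threshold in baseline SDs (default 3).}
#'     \item{model_free_params}{Parameters refitted on the normalized
#'       curve (default `"p0"`).}
#'   }
#' @return The manifest, invisibly: a list with the config, seed, package
#'   version, config hash, per-stage status and the files written. Also
#'   saved as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(seed = 1L, condition = "control", class = "STD",
         n_sweeps = 200L, n_sites = 10L, quantal_size_pa = 15,
         baseline_sd_pa = 2, cv_quantal = 0.3, dt_ms = 0.05,
         q_form = "constant", delta_classify = 0.1, threshold_sd = 3,
         model_free_params = "p0", sweep_table = NULL),
    config)
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- character()
  stages <- list()
  emit <- function(name, path) {
    files[[name]] <<- path
    path
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE,
                                             value = conditionMessage(e)))
    stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$value)
    if (!res$ok) NULL else res$value
  }

  params <- stsp_model_params(cfg$condition, cfg$class, q_form = cfg$q_form)
  train <- stimulus_train()

  # --- input sweeps: read or synthesise ------------------------------
  sweeps <- if (!is.null(cfg$sweep_table)) {
    read_sweep_table(cfg$sweep_table)
  } else {
    sched <- schedule_from_model(params, train, dt_ms = cfg$dt_ms)
    qp <- quantal_params(cfg$n_sites, cfg$quantal_size_pa, sched,
                         baseline_sd_pa = cfg$baseline_sd_pa,
                         cv_quantal = cfg$cv_quantal)
    gen_quantal_sweeps(qp, cfg$n_sweeps, seed = cfg$seed)
  }
  run_stage("sweeps", {
    write_sweep_table(sweeps, emit("sweeps", file.path(cfg$out_dir, "sweeps.csv")))
  })

  # --- normalization -------------------------------------------------
  curve <- run_stage("normalize", normalize_train(sweeps))
  if (!is.null(curve)) {
    write_normalized_curve(curve, emit("curve",
                                       file.path(cfg$out_dir, "normalized_curve.csv")))
  }

  # --- descriptive train fit ----------------------------------------
  if (!is.null(curve)) {
    eq1 <- run_stage("fit_eq1", fit_eq1(curve))
    if (!is.null(eq1)) {
      write_fit_report(eq1, emit("eq1_fit",
                                 file.path(cfg$out_dir, "eq1_fit.csv")))
    }
  }

  # --- mechanistic model refit --------------------------------------
  if (!is.null(curve)) {
    mfit <- run_stage("fit_model", fit_model_to_curve(
      curve, params, cfg$model_free_params, train = train,
      dt_ms = cfg$dt_ms))
    if (!is.null(mfit)) {
      write_fit_report(mfit, emit("model_fit",
                                  file.path(cfg$out_dir, "model_fit.csv")))
    }
  }

  # --- variance-mean analysis ---------------------------------------
  vm <- run_stage("variance_mean", variance_mean(sweeps))
  if (!is.null(vm)) {
    utils::write.csv(
      data.frame(quantity = c("q_hat_pa", "n_hat", "pw",
                              "failure_rate_pulse1"),
                 value = c(vm$q_hat, vm$n_hat, vm$pw,
                           failure_rate(sweeps, 1, cfg$threshold_sd))),
      emit("vmean", file.path(cfg$out_dir, "variance_mean.csv")),
      row.names = FALSE, quote = FALSE)
  }

  # --- intensity-amplitude fit on generated sigmoid data ------------
  ia <- run_stage("fit_ia", {
    truth <- stsp_ia_params(cfg$condition, cfg$class)
    d <- gen_ia_data(as.list(truth[, c("a_max_pa", "k", "i_h_tu")]),
                     intensity_tu = 1:8, noise_sd_pa = 2, seed = cfg$seed)
    fit_eq2(d$intensity_tu, d$amplitude_pa)
  })
  if (!is.null(ia)) {
    write_fit_report(ia, emit("ia_fit", file.path(cfg$out_dir, "ia_fit.csv")))
  }

  # --- classification ------------------------------------------------
  if (!is.null(curve)) {
    label <- run_stage("classify", classify_stsp(curve, cfg$delta_classify))
    if (!is.null(label)) {
      utils::write.csv(
        data.frame(condition = cfg$condition, generating_class = cfg$class,
                   label = as.character(label$label),
                   peak_pulse = label$peak_pulse,
                   low_confidence = label$low_confidence),
        emit("classification", file.path(cfg$out_dir, "classification.csv")),
        row.names = FALSE, quote = FALSE)
    }
  }

  manifest <- list(
    package = "stspdyn",
    version = as.character(utils::packageVersion("stspdyn")),
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    config_hash = config_hash(cfg),
    stages = stages,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

# order-independent hash of the analysis config (no digest dependency);
# output location does not change what is computed, so it is excluded
config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  cfg <- cfg[order(names(cfg))]
  s <- paste(names(cfg),
             vapply(cfg, function(v) paste(format(v), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}
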