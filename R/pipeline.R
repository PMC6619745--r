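#' Validated run configuration for the end-to-end pipeline
#'
#' All parameters are validated against their documented ranges before any
#' computation starts.
#'
#' @param seed integer seed for every source of randomness.
#' @param design a [study_design].
#' @param fatigue a [fatigue_params].
#' @param noise a [noise_params].
#' @param n_basis b-spline basis size for fPCA.
#' @param lambda common smoothing penalty (`NULL`: GCV-selected median).
#' @param lambda_grid positive log-spaced GCV grid.
#' @param n_grid common curve grid size (>= 21).
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @param verbose print stage progress.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, design = study_design(),
                       fatigue = fatigue_params(), noise = noise_params(),
                       n_basis = 20, lambda = NULL,
                       lambda_grid = 10^seq(-8, 2, by = 0.5),
                       n_grid = 101, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(design, "study_design"), inherits(fatigue, "fatigue_params"),
            inherits(noise, "noise_params"))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) stop("seed must be a single integer")
  if (any(lambda_grid <= 0)) stop("lambda grid must be strictly positive")
  if (n_grid < 21) stop("n_grid must be at least 21")
  if (n_basis < 4 || n_basis >= n_grid) stop("need 4 <= n_basis < n_grid")
  if (!is.null(lambda) && lambda < 0) stop("lambda must be non-negative")
  structure(list(seed = as.integer(seed), design = design, fatigue = fatigue,
                 noise = noise, n_basis = n_basis, lambda = lambda,
                 lambda_grid = lambda_grid, n_grid = n_grid,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  el <- proc.time()[["elapsed"]] - t0
  if (verbose) message(sprintf("[%s] done in %.1f s", name, el))
  attr(res, "elapsed_s") <- el
  res
}

#' Run the full analysis pipeline
#'
#' Simulates the synthetic cohort, extracts concentric features and
#' time-normalised curves, runs the stratified PCA and multivariate fPCA,
#' and fits the eight fatigue-prediction models. Deterministic given the
#' configuration seed. When `out_dir` is set, all result tables, the model
#' report and a reproducibility manifest (seed, configuration, versions,
#' stage timings) are written there; a stage failure aborts with the stage
#' name, preserving outputs of earlier stages.
#'
#' @param config a [run_config].
#' @return List of class `cmj_pipeline`: `features`, `matrix`, `pca`,
#'   `curves`, `fpca`, `report`, `study`, `config`, `timings`.
#' @export
pipeline_run <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tick <- function(x, name) { timings[[name]] <<- attr(x, "elapsed_s"); x }

  study <- tick(stage("simulate", v,
                      simulate_study(config$design, config$fatigue,
                                     seed = config$seed, noise = config$noise)),
                "simulate")
  features <- tick(stage("extract", v, extract_study_features(study)), "extract")
  if (!is.null(out)) write_features(features, file.path(out, "features.tsv"))
  sm <- tick(stage("stratify", v, build_feature_matrix(features)), "stratify")
  pca <- tick(stage("pca", v, run_pca(sm)), "pca")
  if (!is.null(out)) write_scores(pca, out, "pca")
  curves <- tick(stage("curves", v, study_curves(study, n_grid = config$n_grid)),
                 "curves")
  fpca <- tick(stage("fpca", v,
                     run_fpca(curves, n_basis = config$n_basis,
                              lambda = config$lambda,
                              lambda_grid = config$lambda_grid)),
               "fpca")
  if (!is.null(out)) write_scores(fpca, out, "fpca")
  report <- tick(stage("models", v,
                       run_fatigue_models(features, curves,
                                          n_basis = config$n_basis,
                                          lambda = config$lambda)),
                 "models")
  if (!is.null(out)) {
    write_model_report(report, file.path(out, "model_report.json"))
    cfg_json <- jsonlite::toJSON(list(seed = config$seed,
                                      design = unclass(config$design),
                                      fatigue = unclass(config$fatigue),
                                      noise = unclass(config$noise),
                                      n_basis = config$n_basis,
                                      lambda = config$lambda,
                                      n_grid = config$n_grid),
                                 auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(
      package = "cmjfatigue",
      package_version = as.character(utils::packageVersion("cmjfatigue")),
      r_version = R.version.string,
      seed = config$seed,
      config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
      config_fingerprint = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                                 seq_along(utf8ToInt(cfg_json))) %% 4294967291),
      timings_s = timings)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(features = features, matrix = sm, pca = pca, curves = curves,
                 fpca = fpca, report = report, study = study, config = config,
                 timings = timings),
            class = "cmj_pipeline")
}

#' @export
print.cmj_pipeline <- function(x, ...) {
  cat("CMJ fatigue pipeline (seed ", x$config$seed, ")\n\n", sep = "")
  print(x$pca)
  cat("\n")
  print(x$fpca)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' One-command reproduction of the synthetic study at full scale
#'
#' Runs [pipeline_run] on the default design (10 athletes x 3 workloads x
#' 8 time points x 5 jumps at 600 Hz).
#'
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param ... further arguments to [run_config].
#' @return A `cmj_pipeline`.
#' @export
reproduce_study <- function(seed = 1, out_dir = NULL, ...) {
  pipeline_run(run_config(seed = seed, out_dir = out_dir, ...))
}

#' Reproduce the analysis from a deposited feature table
#'
#' Adapter for an externally deposited CMJ data file. The analysis needs
#' jump-level rows (repeated jumps per athlete, workload and time point) to
#' form its sample unit; a file holding only session-level summaries (one
#' row per athlete, workload and time point) cannot support it, in which
#' case the published-value targets are reported as not evaluable.
#'
#' @param path feature file (CSV/TSV).
#' @param mapping a [column_mapping] adapting the file's schema.
#' @param inspect if `TRUE`, only report the file's columns and row
#'   structure without running the analysis.
#' @return If evaluable, a list with `pca` (a `cmj_pca`), `report` (PCA-based
#'   model configurations only; curve-level fPCA needs raw traces) and
#'   `evaluable = TRUE`; otherwise a list with `evaluable = FALSE`, a
#'   `reason`, and the names of the quantities (`targets`) that would have
#'   been computed.
#' @export
reproduce_from_deposit <- function(path, mapping = column_mapping(),
                              inspect = FALSE) {
  targets <- c("pca_cumulative_variance_2pc", "pca_cumulative_variance_4pc",
               "pca_cumulative_variance_10pc", "model_mse_cv", "model_r2",
               "model_likelihood_ratios")
  if (inspect) {
    x <- read_delim_auto(path)
    return(list(columns = names(x), n_rows = nrow(x),
                head = utils::head(x, 3)))
  }
  feats <- tryCatch(read_features(path, mapping), error = function(e) e)
  if (inherits(feats, "error")) {
    return(list(evaluable = FALSE,
                reason = paste("could not read the feature table:",
                               conditionMessage(feats)),
                targets = targets))
  }
  per_cell <- stats::aggregate(jump ~ athlete_id + workload + time_point,
                               feats, function(j) length(unique(j)))
  if (all(per_cell$jump <= 1)) {
    return(list(evaluable = FALSE,
                reason = paste("file contains only session-level summaries",
                               "(one row per athlete, workload and time",
                               "point); jump-level rows are required"),
                targets = targets))
  }
  sm <- build_feature_matrix(feats)
  pca <- run_pca(sm)
  specs <- model_specs()
  report <- run_fatigue_models(feats, curves = NULL,
                               specs = specs[specs$source == "PCA", ])
  list(evaluable = TRUE, pca = pca, report = report, targets = targets)
}
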