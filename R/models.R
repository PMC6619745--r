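#' The eight predictive model configurations
#'
#' Each model predicts relative peak force at one horizon (6 h, metabolic
#' fatigue; 48 h, neuromuscular fatigue) from PC1 and PC2 scores of one
#' score source (PCA of stratified features, or fPCA of force curves)
#' computed on one information window (baseline: all time points;
#' practical: only pre-, immediately post- and 0.5 h post-training), always
#' with an athlete random intercept.
#'
#' @return Data frame with columns `model`, `name`, `horizon`, `source`,
#'   `window`.
#' @export
model_specs <- function() {
  data.frame(
    model = 1:8,
    name = c("6 h fPCA Baseline", "6 h PCA Baseline",
             "6 h fPCA Practical", "6 h PCA Practical",
             "48 h fPCA Baseline", "48 h PCA Baseline",
             "48 h fPCA Practical", "48 h PCA Practical"),
    horizon = rep(c("6", "48"), each = 4),
    source = rep(c("fPCA", "PCA"), 4),
    window = rep(rep(c("baseline", "practical"), each = 2), 2),
    stringsAsFactors = FALSE)
}

PRACTICAL_WINDOW <- c("PRE", "0", "0.5")

#' Assemble response and design for one model configuration
#'
#' The PC scores are recomputed on the configuration's information window
#' (for the practical window, PCA runs on the restricted 4-features x
#' 3-time-points stratified matrix and fPCA on the 3 restricted curve
#' slots), never by projecting onto full-data components. The response is
#' each sample's relative peak force at the horizon time point; samples
#' missing the horizon measurement are dropped with a message.
#'
#' @param features long-format feature table.
#' @param spec one row of [model_specs] (or a list with `horizon`, `source`,
#'   `window`).
#' @param curves a `curve_stack` (required for fPCA sources).
#' @param n_basis,lambda passed to [run_fpca].
#' @return List: `y`, `X` (intercept, PC1, PC2), `groups` (athlete ids),
#'   `info` (sample labels), `scores_result` (the `cmj_pca`/`cmj_fpca`
#'   object used).
#' @export
build_model_inputs <- function(features, spec, curves = NULL,
                               n_basis = 20, lambda = NULL) {
  window_tp <- if (spec$window == "practical") PRACTICAL_WINDOW else NULL
  if (spec$source == "PCA") {
    feats <- features
    if (!is.null(window_tp)) feats <- feats[feats$time_point %in% window_tp, ]
    sm <- build_feature_matrix(feats, time_points = window_tp)
    res <- run_pca(sm)
    key <- paste(sm$row_info$athlete_id, sm$row_info$workload,
                 sm$row_info$jump, sep = "|")
    sc <- res$scores[, 1:2, drop = FALSE]
    info <- sm$row_info
  } else {
    if (is.null(curves)) stop("fPCA model configurations need a curve_stack")
    vals <- curves$values
    if (!is.null(window_tp)) {
      keep <- match(window_tp, curves$time_points)
      if (anyNA(keep)) stop("curve stack lacks the practical-window time points")
      vals <- vals[, keep, , drop = FALSE]
    }
    res <- run_fpca(vals, n_basis = n_basis, lambda = lambda)
    key <- curves$sample_info$key
    sc <- res$scores[, 1:2, drop = FALSE]
    info <- curves$sample_info
  }
  resp <- features[features$time_point == spec$horizon, ]
  rkey <- paste(resp$athlete_id, resp$workload, resp$jump, sep = "|")
  m <- match(key, rkey)
  if (anyNA(m)) {
    message(sum(is.na(m)), " sample(s) dropped: no ", spec$horizon,
            " h measurement")
  }
  ok <- !is.na(m)
  y <- resp$rel_peak_force[m[ok]]
  X <- cbind(`(Intercept)` = 1, PC1 = sc[ok, 1], PC2 = sc[ok, 2])
  list(y = y, X = X, groups = info$athlete_id[ok], info = info[ok, ],
       scores_result = res)
}

#' Fit, cross-validate and compare all eight fatigue-prediction models
#'
#' Fits the eight random-intercept models of [model_specs] by maximum
#' likelihood, computes the leave-one-athlete-out cross-validated MSE and
#' R-squared of each, and performs the six likelihood-ratio comparisons
#' (fPCA vs PCA per horizon and window; baseline vs practical per horizon).
#'
#' @param features long-format feature table.
#' @param curves a `curve_stack` for the fPCA-based configurations.
#' @param specs model configurations; defaults to all eight.
#' @param n_basis,lambda passed to [run_fpca].
#' @return Object of class `fatigue_model_report`: `models` (data frame:
#'   name, horizon, source, window, mse_cv, r2, loglik, converged),
#'   `comparisons` (data frame: comparison, lr, delta_mse, p_value, nested),
#'   `fits` (list of `cmj_lme`).
#' @export
run_fatigue_models <- function(features, curves = NULL, specs = model_specs(),
                               n_basis = 20, lambda = NULL) {
  fits <- vector("list", nrow(specs))
  names(fits) <- specs$name
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    row <- tryCatch({
      inp <- build_model_inputs(features, sp, curves, n_basis, lambda)
      fit <- fit_lme(inp$y, inp$X, inp$groups)
      fits[[i]] <- fit
      data.frame(name = sp$name, horizon = sp$horizon, source = sp$source,
                 window = sp$window,
                 mse_cv = as.numeric(loocv_lme(inp$y, inp$X, inp$groups)),
                 r2 = r_squared(fit), loglik = fit$loglik,
                 converged = fit$converged, failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(name = sp$name, horizon = sp$horizon, source = sp$source,
                 window = sp$window, mse_cv = NA_real_, r2 = NA_real_,
                 loglik = NA_real_, converged = FALSE, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  models <- do.call(rbind, rows)
  pair_names <- list(
    c("6 h fPCA Baseline", "6 h PCA Baseline"),
    c("48 h fPCA Baseline", "48 h PCA Baseline"),
    c("6 h PCA Practical", "6 h fPCA Practical"),
    c("48 h PCA Practical", "48 h fPCA Practical"),
    c("6 h fPCA Baseline", "6 h fPCA Practical"),
    c("48 h fPCA Baseline", "48 h fPCA Practical"))
  pair_idx <- Filter(function(pr) !anyNA(pr),
                     lapply(pair_names, match, table = specs$name))
  comps <- lapply(pair_idx, function(pr) {
    a <- fits[[pr[1]]]; b <- fits[[pr[2]]]
    lab <- paste(specs$name[pr[1]], "vs", specs$name[pr[2]])
    if (is.null(a) || is.null(b)) {
      return(data.frame(comparison = lab, lr = NA_real_, delta_mse = NA_real_,
                        p_value = NA_real_, nested = NA,
                        stringsAsFactors = FALSE))
    }
    # every tabulated pair compares PC scores from different constructions
    # (source or window), so none of them is a nested comparison
    lrt <- withCallingHandlers(likelihood_ratio_test(a, b, nested = FALSE),
                               warning = function(w) invokeRestart("muffleWarning"))
    data.frame(comparison = lab, lr = lrt$lr,
               delta_mse = abs(models$mse_cv[pr[1]] - models$mse_cv[pr[2]]),
               p_value = lrt$p_value, nested = lrt$nested,
               stringsAsFactors = FALSE)
  })
  comparisons <- if (length(comps)) do.call(rbind, comps) else {
    data.frame(comparison = character(0), lr = numeric(0),
               delta_mse = numeric(0), p_value = numeric(0),
               nested = logical(0))
  }
  structure(list(models = models, comparisons = comparisons, fits = fits),
            class = "fatigue_model_report")
}

#' @export
print.fatigue_model_report <- function(x, digits = 3, ...) {
  cat("Fatigue-prediction model report\n\nCross-validated fit:\n")
  m <- x$models
  m$mse_cv <- round(m$mse_cv, digits)
  m$r2 <- round(m$r2, digits)
  m$loglik <- round(m$loglik, 1)
  print(m[c("name", "mse_cv", "r2", "loglik")], row.names = FALSE)
  cat("\nLikelihood-ratio comparisons:\n")
  cm <- x$comparisons
  cm$lr <- round(cm$lr, 2)
  cm$delta_mse <- signif(cm$delta_mse, 2)
  cm$p_value <- signif(cm$p_value, 2)
  print(cm[c("comparison", "lr", "delta_mse", "p_value", "nested")],
        row.names = FALSE)
  invisible(x)
}

#' Serialise a model report to JSON
#' @param report a `fatigue_model_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  jsonlite::write_json(list(models = report$models,
                            comparisons = report$comparisons),
                       path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read back a serialised model report
#' @param path JSON file written by [write_model_report].
#' @return List with `models` and `comparisons` data frames.
#' @export
read_model_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$models <- as.data.frame(x$models)
  x$comparisons <- as.data.frame(x$comparisons)
  x
}
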