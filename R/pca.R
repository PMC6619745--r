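FEATURE_COLS <- c("rel_peak_force", "rel_peak_power", "t_con_s", "t_peak_force_s")

#' Build the stratified feature matrix
#'
#' Spreads the long-format feature table into a wide samples-by-variables
#' matrix in which each of the four concentric features is stratified by
#' measurement time point (4 features x 8 time points = 32 variables under
#' the default design). The sample unit is the jump repetition paired across
#' time points by repetition order (jump k before training is matched to
#' jump k at every later time point), giving athletes x workloads x jumps
#' rows (150 in the default design); `pairing = "session_mean"` averages the
#' jumps of each occasion first (30 rows). Rows missing any cell are dropped
#' with a message.
#'
#' @param features long-format feature table (see [extract_study_features]).
#' @param pairing `"jump"` (repetition-order pairing) or `"session_mean"`.
#' @param time_points time-point labels defining the column order.
#' @param feature_cols feature columns to stratify.
#' @return Object of class `stratified_matrix`: list with `x` (raw wide
#'   matrix), `scaled` (centred + unit-variance columns), `center`, `scale`,
#'   `row_info` (athlete_id, workload, jump), `dropped` (row count).
#'   Columns are ordered feature-major: all time points of feature 1, then
#'   feature 2, and so on.
#' @export
build_feature_matrix <- function(features, pairing = c("jump", "session_mean"),
                                 time_points = NULL,
                                 feature_cols = FEATURE_COLS) {
  pairing <- match.arg(pairing)
  req <- c("athlete_id", "workload", "time_point", "jump", feature_cols)
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(time_points)) {
    tp <- unique(as.character(features$time_point))
    h <- time_point_hours(tp)
    time_points <- c(tp[is.na(h)], tp[!is.na(h)][order(h[!is.na(h)])])
  }
  if (pairing == "session_mean") {
    agg <- stats::aggregate(features[feature_cols],
                            features[c("athlete_id", "workload", "time_point")],
                            mean)
    agg$jump <- 1L
    features <- agg
  }
  key <- interaction(features$athlete_id, features$workload, features$jump,
                     drop = TRUE, sep = "|")
  samples <- unique(data.frame(key = as.character(key),
                               athlete_id = features$athlete_id,
                               workload = features$workload,
                               jump = features$jump,
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$key), ]
  cols <- unlist(lapply(feature_cols, function(f) paste(f, time_points, sep = "@")))
  x <- matrix(NA_real_, nrow(samples), length(cols),
              dimnames = list(samples$key, cols))
  fkey <- as.character(key)
  for (f in feature_cols) {
    for (tp in time_points) {
      sel <- as.character(features$time_point) == tp
      if (!any(sel)) next
      x[cbind(match(fkey[sel], samples$key), match(paste(f, tp, sep = "@"), cols))] <-
        features[[f]][sel]
    }
  }
  complete <- stats::complete.cases(x)
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(dropped, " sample row(s) dropped for missing time-point cells")
  }
  x <- x[complete, , drop = FALSE]
  if (nrow(x) == 0) stop("no complete samples after pairing")
  samples <- samples[complete, ]
  sds <- apply(x, 2, stats::sd)
  constant <- names(which(sds == 0))
  scaled <- if (length(constant)) NULL else scale(x)
  structure(list(x = x, scaled = scaled,
                 center = colMeans(x), scale = sds,
                 constant_columns = constant,
                 row_info = samples[c("athlete_id", "workload", "jump")],
                 time_points = time_points, feature_cols = feature_cols,
                 dropped = dropped),
            class = "stratified_matrix")
}

#' @export
print.stratified_matrix <- function(x, ...) {
  cat(sprintf("Stratified matrix: %d samples x %d variables (%d features x %d time points)\n",
              nrow(x$x), ncol(x$x), length(x$feature_cols), length(x$time_points)))
  if (x$dropped) cat("  ", x$dropped, "incomplete rows dropped\n")
  invisible(x)
}

#' Principal component analysis of the stratified matrix
#'
#' Centred, unit-variance PCA (correlation-structure decomposition) via
#' [stats::prcomp]. Eigenvector signs are fixed by flipping each loading
#' vector so that its largest-magnitude element is positive.
#'
#' @param sm a `stratified_matrix` (or a plain numeric matrix).
#' @return Object of class `cmj_pca`: `loadings` (variables x PCs,
#'   orthonormal), `scores` (samples x PCs), `sdev`, `prop` (explained
#'   variance proportions), `cumprop`, `row_info`, `center`, `scale`.
#' @export
run_pca <- function(sm) {
  if (inherits(sm, "stratified_matrix")) {
    if (length(sm$constant_columns)) {
      stop("constant column(s) cannot be scaled: ",
           paste(sm$constant_columns, collapse = ", "))
    }
    x <- sm$x
    row_info <- sm$row_info
  } else {
    x <- as.matrix(sm)
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) cannot be scaled: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
    row_info <- NULL
  }
  if (nrow(x) < 2) stop("PCA needs at least 2 rows")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  ev <- p$sdev^2
  structure(list(loadings = rot, scores = scores, sdev = p$sdev,
                 prop = ev / sum(ev), cumprop = cumsum(ev) / sum(ev),
                 center = p$center, scale = p$scale, row_info = row_info),
            class = "cmj_pca")
}

#' @export
print.cmj_pca <- function(x, digits = 3, ...) {
  k <- min(6, length(x$prop))
  cat("Stratified PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "variables\n")
  cat("Proportion of variance (first", k, "PCs):",
      paste(format(round(100 * x$prop[1:k], 1)), collapse = " "), "%\n")
  cat("Cumulative:",
      paste(format(round(100 * x$cumprop[1:k], 1)), collapse = " "), "%\n")
  invisible(x)
}

#' Cumulative explained-variance proportion
#'
#' @param result a `cmj_pca` or `cmj_fpca` object.
#' @param k number of leading components.
#' @return Proportion in \[0, 1\].
#' @export
cumulative_variance <- function(result, k) {
  prop <- result$prop
  if (k < 1 || k > length(prop)) stop("k out of range [1, ", length(prop), "]")
  sum(prop[seq_len(k)])
}

#' Grouped PC scores for athlete/workload capability maps
#'
#' Projects samples onto a pair of PCs and summarises each group (athlete or
#' workload) by its centroid and within-group dispersion, the structure used
#' to map a squad's fatigue-response capability; plotting is left to the
#' caller.
#'
#' @param result a `cmj_pca` with `row_info`.
#' @param pcs integer pair of PC indices.
#' @param group_by `"athlete"` or `"workload"`.
#' @return List of class `capability_map`: `scores` (data frame with group
#'   labels), `centroids`, `dispersion` (mean within-group squared distance
#'   to centroid).
#' @export
capability_map <- function(result, pcs = c(1, 2),
                           group_by = c("athlete", "workload")) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(result, "cmj_pca"), length(pcs) == 2)
  if (any(pcs < 1 | pcs > ncol(result$scores))) stop("invalid PC indices")
  if (is.null(result$row_info)) stop("PCA result carries no sample labels")
  g <- if (group_by == "athlete") result$row_info$athlete_id else result$row_info$workload
  sc <- data.frame(group = g,
                   athlete_id = result$row_info$athlete_id,
                   workload = result$row_info$workload,
                   x = result$scores[, pcs[1]], y = result$scores[, pcs[2]],
                   stringsAsFactors = FALSE)
  cent <- stats::aggregate(sc[c("x", "y")], list(group = sc$group), mean)
  disp <- vapply(split(sc, sc$group), function(d) {
    mean((d$x - mean(d$x))^2 + (d$y - mean(d$y))^2)
  }, numeric(1))
  structure(list(scores = sc, centroids = cent,
                 dispersion = data.frame(group = names(disp),
                                         within_var = unname(disp)),
                 pcs = pcs, group_by = group_by),
            class = "capability_map")
}

#' @export
print.capability_map <- function(x, ...) {
  cat(sprintf("Capability map on PC%d-PC%d grouped by %s: %d groups\n",
              x$pcs[1], x$pcs[2], x$group_by, nrow(x$centroids)))
  invisible(x)
}

#' Mean silhouette width of a labelling on PC scores
#'
#' @param scores numeric matrix (samples x dims).
#' @param labels grouping vector.
#' @return Mean silhouette width.
#' @export
silhouette_width <- function(scores, labels) {
  f <- as.integer(factor(labels))
  s <- cluster::silhouette(f, stats::dist(scores))
  mean(s[, "sil_width"])
}
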