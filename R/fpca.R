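#' Time-normalise a concentric segment onto a common grid
#'
#' Linearly rescales the segment's time axis onto \[0, 1\] and interpolates
#' the force values onto a common grid, so that concentric phases of unequal
#' duration become comparable curves; the original duration is kept as
#' metadata.
#'
#' @param segment a `concentric_segment`, or a list with `time` and `force`.
#' @param n_grid number of grid points (>= 21).
#' @return List with `grid` (on \[0,1\]), `values` (force, N), `duration`
#'   (s), `meta`.
#' @export
time_normalize <- function(segment, n_grid = 101) {
  if (n_grid < 21) stop("n_grid must be at least 21")
  t <- segment$time
  if (max(t) <= 0) stop("segment duration must be positive")
  grid <- seq(0, 1, length.out = n_grid)
  vals <- stats::approx(t / max(t), segment$force, xout = grid, rule = 2)$y
  list(grid = grid, values = vals,
       duration = if (!is.null(segment$takeoff_index)) {
         (segment$takeoff_index - segment$onset_index) / segment$sample_rate
       } else max(t),
       meta = segment$meta %||% list())
}

# Gauss-Legendre nodes/weights (4-point), exact through polynomial degree 7
.gl4 <- list(x = c(-0.8611363115940526, -0.3399810435848563,
                   0.3399810435848563, 0.8611363115940526),
             w = c(0.3478548451374538, 0.6521451548625461,
                   0.6521451548625461, 0.3478548451374538))

#' Cubic b-spline basis with exact Gram and roughness-penalty matrices
#'
#' Builds an order-`order` b-spline basis with equally spaced interior knots
#' on \[0, 1\], its evaluation matrix on the grid, the Gram matrix
#' `G = \int B B'` (Gauss-Legendre per knot interval, exact for cubics) and
#' the second-derivative penalty `P = \int B'' B''^T` (Simpson per interval,
#' exact since the second derivative of a cubic spline is piecewise linear).
#'
#' @param n_basis number of basis functions (>= order).
#' @param order spline order (4 = cubic).
#' @param grid evaluation grid on \[0, 1\].
#' @return List of class `bspline_basis`: `B` (grid x n_basis), `G`, `P`,
#'   `knots`, `order`, `n_basis`, `grid`, `int_B` (vector of basis-function
#'   integrals).
#' @export
bspline_basis <- function(n_basis = 20, order = 4,
                          grid = seq(0, 1, length.out = 101)) {
  if (order < 4) stop("basis order must be at least 4")
  if (n_basis < order) stop("n_basis must be at least the order")
  n_int <- n_basis - order
  inner <- if (n_int > 0) seq(0, 1, length.out = n_int + 2)[-c(1, n_int + 2)] else numeric(0)
  knots <- c(rep(0, order), inner, rep(1, order))
  B <- splines::splineDesign(knots, grid, ord = order)
  u <- c(0, inner, 1)                       # breakpoints
  G <- matrix(0, n_basis, n_basis)
  P <- matrix(0, n_basis, n_basis)
  int_B <- numeric(n_basis)
  for (i in seq_len(length(u) - 1)) {
    a <- u[i]; b <- u[i + 1]; h <- b - a
    xg <- (a + b) / 2 + (h / 2) * .gl4$x
    Bg <- splines::splineDesign(knots, xg, ord = order)
    for (k in 1:4) {
      G <- G + (h / 2) * .gl4$w[k] * tcrossprod(Bg[k, ])
      int_B <- int_B + (h / 2) * .gl4$w[k] * Bg[k, ]
    }
    xs <- c(a, (a + b) / 2, b)
    B2 <- splines::splineDesign(knots, xs, ord = order, derivs = rep(2L, 3))
    P <- P + (h / 6) * (tcrossprod(B2[1, ]) + 4 * tcrossprod(B2[2, ]) +
                          tcrossprod(B2[3, ]))
  }
  structure(list(B = B, G = G, P = P, knots = knots, order = order,
                 n_basis = n_basis, grid = grid, int_B = int_B),
            class = "bspline_basis")
}

#' Penalised b-spline smoothing of gridded curve values
#'
#' Coefficients minimise the penalised least-squares criterion
#' `sum (y - B c)^2 + lambda * \int (c'' B'')^2`, solved in closed form as
#' `c = (B'B + lambda P)^{-1} B'y`.
#'
#' @param y numeric vector (grid values of one curve) or matrix with one
#'   curve per column.
#' @param basis a [bspline_basis] (its grid must match `length(y)`), or
#'   `NULL` to build one with `n_basis`.
#' @param lambda roughness-penalty weight (>= 0).
#' @param n_basis used when `basis` is `NULL`.
#' @return For a vector `y`, an object of class `functional_curve` (`coef`,
#'   `basis`, `lambda`, `fitted`); for a matrix, the coefficient matrix
#'   (n_basis x n_curves).
#' @export
fit_bspline <- function(y, basis = NULL, lambda = 0, n_basis = 20) {
  ymat <- as.matrix(y)
  if (is.null(basis)) {
    basis <- bspline_basis(n_basis, grid = seq(0, 1, length.out = nrow(ymat)))
  }
  if (nrow(ymat) != nrow(basis$B)) stop("y length must match the basis grid")
  if (basis$n_basis >= nrow(ymat) + 1) stop("n_basis must be below n_grid")
  M <- crossprod(basis$B) + lambda * basis$P
  cf <- tryCatch(solve(M, crossprod(basis$B, ymat)),
                 error = function(e) stop("penalised system is singular; ",
                                          "try a lower n_basis", call. = FALSE))
  if (is.matrix(y) && ncol(y) > 1) return(cf)
  structure(list(coef = drop(cf), basis = basis, lambda = lambda,
                 fitted = drop(basis$B %*% cf)),
            class = "functional_curve")
}

#' Evaluate a smoothed functional curve
#' @param object a `functional_curve`.
#' @param x abscissae in \[0, 1\]; default the basis grid.
#' @param ... unused.
#' @return Numeric values.
#' @export
predict.functional_curve <- function(object, x = NULL, ...) {
  if (is.null(x)) return(object$fitted)
  drop(splines::splineDesign(object$basis$knots, x, ord = object$basis$order) %*%
         object$coef)
}

#' Choose the roughness penalty by generalised cross-validation
#'
#' Minimises `GCV(lambda) = n RSS / (n - tr H)^2` with
#' `H = B (B'B + lambda P)^{-1} B'` over a positive, log-spaced grid.
#'
#' @param y curve values on the basis grid (vector) or matrix (one curve per
#'   column; the criterion is then summed per curve and a per-curve minimiser
#'   returned).
#' @param basis a [bspline_basis].
#' @param lambda_grid positive penalty grid.
#' @return For a vector, the minimising lambda (with the score path as
#'   attribute `"gcv"`); for a matrix, the vector of per-curve minimisers.
#' @export
select_lambda_gcv <- function(y, basis,
                              lambda_grid = 10^seq(-8, 2, by = 0.5)) {
  if (any(lambda_grid <= 0)) stop("lambda grid must be positive")
  lambda_grid <- sort(lambda_grid)
  ymat <- as.matrix(y)
  n <- nrow(ymat)
  if (n != nrow(basis$B)) stop("y length must match the basis grid")
  BtB <- crossprod(basis$B)
  Bty <- crossprod(basis$B, ymat)
  scores <- matrix(NA_real_, length(lambda_grid), ncol(ymat))
  for (i in seq_along(lambda_grid)) {
    M <- BtB + lambda_grid[i] * basis$P
    Minv <- solve(M)
    edf <- sum(Minv * BtB)                 # tr(M^-1 B'B) = tr(H)
    fit <- basis$B %*% (Minv %*% Bty)
    rss <- colSums((ymat - fit)^2)
    scores[i, ] <- n * rss / (n - edf)^2
  }
  pick <- apply(scores, 2, which.min)
  lam <- lambda_grid[pick]
  if (ncol(ymat) == 1) {
    lam <- lam[1]
    attr(lam, "gcv") <- data.frame(lambda = lambda_grid, gcv = scores[, 1])
  }
  lam
}

#' Build time-normalised curve stacks from a study
#'
#' Extracts the concentric segment of every trace, time-normalises it onto a
#' common grid, and stacks curves into a samples x time-points x grid array,
#' pairing jumps across time points by repetition order (the same sample
#' unit as [build_feature_matrix]). Samples with any missing time-point
#' curve are dropped with a message.
#'
#' @param study a `cmj_study` or named list of `force_trace`s with complete
#'   metadata.
#' @param n_grid common grid size.
#' @param time_points slot order; defaults to the study design's.
#' @param units `"BW"` (curves expressed in bodyweight multiples, so that
#'   between-athlete body-mass differences do not dominate the curve
#'   variance) or `"N"` (raw force).
#' @param ... passed to [extract_concentric].
#' @return List of class `curve_stack`: `values` (array n x slots x grid),
#'   `durations` (n x slots), `sample_info`, `grid`, `time_points`.
#' @export
study_curves <- function(study, n_grid = 101, time_points = NULL,
                         units = c("BW", "N"), ...) {
  units <- match.arg(units)
  traces <- if (inherits(study, "cmj_study")) study$traces else study
  if (is.null(time_points)) {
    time_points <- if (inherits(study, "cmj_study")) study$design$time_points else {
      tp <- unique(vapply(traces, function(tr) as.character(tr$meta$time_point),
                          character(1)))
      h <- time_point_hours(tp)
      c(tp[is.na(h)], tp[!is.na(h)][order(h[!is.na(h)])])
    }
  }
  meta <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(athlete_id = tr$meta$athlete_id, workload = tr$meta$workload,
               time_point = as.character(tr$meta$time_point),
               jump = tr$meta$jump, stringsAsFactors = FALSE)
  }))
  meta$key <- paste(meta$athlete_id, meta$workload, meta$jump, sep = "|")
  keys <- sort(unique(meta$key))
  grid <- seq(0, 1, length.out = n_grid)
  vals <- array(NA_real_, c(length(keys), length(time_points), n_grid),
                dimnames = list(keys, time_points, NULL))
  dur <- matrix(NA_real_, length(keys), length(time_points),
                dimnames = list(keys, time_points))
  for (i in seq_along(traces)) {
    slot <- match(meta$time_point[i], time_points)
    row <- match(meta$key[i], keys)
    if (is.na(slot)) next
    seg <- extract_concentric(traces[[i]], ...)
    nc <- time_normalize(seg, n_grid)
    vals[row, slot, ] <- if (units == "BW") nc$values / seg$bodyweight else nc$values
    dur[row, slot] <- nc$duration
  }
  complete <- apply(vals, 1, function(m) all(is.finite(m)))
  if (any(!complete)) {
    message(sum(!complete), " sample(s) dropped for missing time-point curves")
  }
  vals <- vals[complete, , , drop = FALSE]
  dur <- dur[complete, , drop = FALSE]
  info <- meta[!duplicated(meta$key), c("key", "athlete_id", "workload", "jump")]
  info <- info[match(rownames(dur), info$key), ]
  rownames(info) <- NULL
  structure(list(values = vals, durations = dur, sample_info = info,
                 grid = grid, time_points = time_points),
            class = "curve_stack")
}

#' Multivariate functional PCA of concentric force curves
#'
#' Each sample is represented by one smoothed curve per measurement time
#' point (the "slots"). Curves are expanded in a common penalised b-spline
#' basis; the concatenated, centred coefficient vectors are decomposed under
#' the concatenated L2 inner product (b-spline Gram matrix, block-diagonal
#' over slots). Components are eigenfunction vectors — one function per time
#' point — with samples scored by the inner product with the centred sample.
#' Signs are fixed so that the integral of each component's mean slot
#' function is positive.
#'
#' @param curves a `curve_stack` (see [study_curves]) or a plain 3-d array
#'   (samples x slots x grid).
#' @param n_basis number of b-spline basis functions.
#' @param order spline order (4 = cubic).
#' @param lambda common smoothing penalty; `NULL` selects per-curve GCV
#'   minimisers and applies their median to all curves.
#' @param lambda_grid grid for GCV selection.
#' @return Object of class `cmj_fpca`: `eigenfunctions` (array n_basis x
#'   slots x k of coefficients), `scores` (samples x k), `prop`, `cumprop`,
#'   `lambda`, `mean_coef`, `basis`, `sample_info`, `time_points`,
#'   `degenerate` flag; internal centred coefficients retained for
#'   slot-restricted scores.
#' @export
run_fpca <- function(curves, n_basis = 20, order = 4, lambda = NULL,
                     lambda_grid = 10^seq(-8, 2, by = 0.5)) {
  if (inherits(curves, "curve_stack")) {
    vals <- curves$values
    info <- curves$sample_info
    grid <- curves$grid
    tps <- curves$time_points
  } else {
    vals <- curves
    info <- NULL
    grid <- seq(0, 1, length.out = dim(vals)[3])
    tps <- dimnames(vals)[[2]] %||% paste0("slot", seq_len(dim(vals)[2]))
  }
  n <- dim(vals)[1]; n_slot <- dim(vals)[2]; n_grid <- dim(vals)[3]
  if (n < 2) stop("fPCA needs at least 2 samples")
  basis <- bspline_basis(n_basis, order, grid)
  # one column per (sample, slot) curve, grid running down the rows
  Y <- matrix(aperm(vals, c(3, 2, 1)), n_grid, n_slot * n)
  if (is.null(lambda)) {
    lambda <- stats::median(select_lambda_gcv(Y, basis, lambda_grid))
  }
  cf <- fit_bspline(Y, basis, lambda)        # n_basis x (n_slot*n)
  # concatenated coefficient matrix: samples x (slots * n_basis)
  C <- t(matrix(cf, n_basis * n_slot, n))
  mu <- colMeans(C)
  Cc <- sweep(C, 2, mu)
  eg <- eigen(basis$G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Gh <- eg$vectors %*% (sqrt(d) * t(eg$vectors))
  Ghi <- eg$vectors %*% (1 / sqrt(pmax(d, 1e-300)) * t(eg$vectors))
  idx <- function(j) ((j - 1) * n_basis + 1):(j * n_basis)
  U <- Cc
  for (j in seq_len(n_slot)) U[, idx(j)] <- Cc[, idx(j)] %*% Gh
  sv <- svd(U)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  degenerate <- total < 1e-10
  prop <- if (degenerate) rep(NA_real_, length(ev)) else ev / total
  if (degenerate) warning("all samples (numerically) identical: variance is zero")
  k <- length(ev)
  Phi <- array(NA_real_, c(n_basis, n_slot, k))
  for (j in seq_len(n_slot)) Phi[, j, ] <- Ghi %*% sv$v[idx(j), , drop = FALSE]
  scores <- U %*% sv$v
  # sign convention: integral of the component's mean slot function positive
  for (m in seq_len(k)) {
    s <- sum(basis$int_B * rowMeans(matrix(Phi[, , m], n_basis, n_slot)))
    if (s < 0) {
      Phi[, , m] <- -Phi[, , m]
      scores[, m] <- -scores[, m]
      sv$v[, m] <- -sv$v[, m]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenfunctions = Phi, scores = scores, prop = prop,
                 cumprop = if (degenerate) prop else cumsum(prop),
                 lambda = lambda, mean_coef = matrix(mu, n_basis, n_slot),
                 basis = basis, sample_info = info, time_points = tps,
                 degenerate = degenerate,
                 .Cc = Cc, .v = sv$v, .Gh = Gh),
            class = "cmj_fpca")
}

#' @export
print.cmj_fpca <- function(x, ...) {
  cat("Multivariate fPCA:", nrow(x$scores), "samples,",
      dim(x$eigenfunctions)[2], "time-point slots,",
      x$basis$n_basis, "basis functions (lambda =",
      format(x$lambda, digits = 3), ")\n")
  if (x$degenerate) {
    cat("  degenerate: zero variance across samples\n")
  } else {
    k <- min(6, length(x$prop))
    cat("Proportion of variance (first", k, "PCs):",
        paste(format(round(100 * x$prop[1:k], 1)), collapse = " "), "%\n")
  }
  invisible(x)
}

#' Evaluate an fPCA eigenfunction on the grid
#' @param result a `cmj_fpca`.
#' @param pc component index.
#' @return Matrix (grid x slots) of eigenfunction values.
#' @export
eval_eigenfunction <- function(result, pc) {
  stopifnot(inherits(result, "cmj_fpca"))
  result$basis$B %*% result$eigenfunctions[, , pc]
}

#' Per-time-point score contributions of an fPCA component
#'
#' Restricts the concatenated inner product to each time-point slot: entry
#' (i, j) is the contribution of sample i's slot-j curve to its total score
#' on the component (rows sum to the scores).
#'
#' @param result a `cmj_fpca`.
#' @param pc component index.
#' @return Matrix samples x slots.
#' @export
fpca_slot_scores <- function(result, pc) {
  stopifnot(inherits(result, "cmj_fpca"))
  nb <- result$basis$n_basis
  n_slot <- dim(result$eigenfunctions)[2]
  out <- matrix(NA_real_, nrow(result$scores), n_slot,
                dimnames = list(rownames(result$scores), result$time_points))
  for (j in seq_len(n_slot)) {
    ix <- ((j - 1) * nb + 1):(j * nb)
    out[, j] <- (result$.Cc[, ix] %*% result$.Gh) %*% result$.v[ix, pc]
  }
  out
}

#' Hierarchical clustering of fPCA scores
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage by default) of
#' the per-time-point score contributions of one component: samples are
#' clustered as rows and measurement time points as columns, mirroring the
#' heat-map-with-dendrograms view of fatigue structure.
#'
#' @param result a `cmj_fpca`.
#' @param pc component index.
#' @param k_samples,k_time flat cluster counts at the cut.
#' @param linkage linkage method for [stats::hclust].
#' @return Object of class `score_clustering`: `sample_tree`, `time_tree`
#'   (`hclust` or `NULL` when trivial), `sample_clusters`, `time_clusters`,
#'   `slot_scores`, `pc`, `linkage`.
#' @export
cluster_scores <- function(result, pc = 1, k_samples = 3, k_time = 3,
                           linkage = "ward.D2") {
  M <- fpca_slot_scores(result, pc)
  time_tree <- stats::hclust(stats::dist(t(M)), method = linkage)
  time_clusters <- stats::cutree(time_tree, k = min(k_time, ncol(M)))
  if (nrow(M) >= 2) {
    sample_tree <- stats::hclust(stats::dist(M), method = linkage)
    sample_clusters <- stats::cutree(sample_tree, k = min(k_samples, nrow(M)))
  } else {
    sample_tree <- NULL
    sample_clusters <- stats::setNames(1L, rownames(M))
  }
  structure(list(sample_tree = sample_tree, time_tree = time_tree,
                 sample_clusters = sample_clusters,
                 time_clusters = time_clusters,
                 slot_scores = M, pc = pc, linkage = linkage,
                 distance = "euclidean"),
            class = "score_clustering")
}

#' @export
print.score_clustering <- function(x, ...) {
  cat("Score clustering (PC", x$pc, ", ", x$linkage, " linkage)\n", sep = "")
  cat("  time-point clusters:\n")
  print(x$time_clusters)
  invisible(x)
}
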