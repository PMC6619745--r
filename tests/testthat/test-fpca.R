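test_that("time normalisation is dilation-invariant and interpolation-accurate", {
  seg <- list(time = seq(0, 0.4, by = 0.002), force = NULL)
  seg$force <- 700 + 500 * sin(pi * seg$time / 0.4)
  nc <- time_normalize(seg, 101)
  expect_equal(length(nc$values), 101)
  # constant force stays constant
  ncc <- time_normalize(list(time = seq(0, 0.3, 0.001), force = rep(5, 301)), 41)
  expect_true(all(ncc$values == 5))
  # two segments identical up to time dilation give identical curves
  seg2 <- list(time = seg$time * 2.5, force = seg$force)
  expect_equal(time_normalize(seg2, 101)$values, nc$values, tolerance = 1e-12)
  # against the analytic curve at scaled abscissae: O(1/n_grid^2)
  expect_lt(max(abs(nc$values - (700 + 500 * sin(pi * nc$grid)))), 1e-3)
  expect_error(time_normalize(seg, 10), "at least 21")
})

test_that("penalised b-spline smoothing solves the closed-form ridge problem", {
  basis <- bspline_basis(20, 4, seq(0, 1, length.out = 101))
  # exact representation: residuals vanish for a curve already in the span
  set.seed(7)
  cf_true <- rnorm(20)
  y_in <- drop(basis$B %*% cf_true)
  fit0 <- fit_bspline(y_in, basis, lambda = 0)
  expect_lt(max(abs(fit0$fitted - y_in)), 1e-8)
  # noisy sine against the independent augmented-regression oracle
  y <- sin(2 * pi * basis$grid) + rnorm(101, 0, 0.1)
  for (lam in c(1e-6, 1e-2, 1)) {
    fit <- fit_bspline(y, basis, lambda = lam)
    expect_equal(fit$coef, penalised_ridge_oracle(basis$B, basis$P, y, lam),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # lambda -> infinity approaches the least-squares straight line (the
  # null space of the curvature penalty): the fit is affine and close to
  # the direct line fit (exact only in the infinite-penalty limit)
  fit_inf <- fit_bspline(y, basis, lambda = 1e9)
  line <- fitted(lm(y ~ basis$grid))
  expect_lt(max(abs(resid(lm(fit_inf$fitted ~ basis$grid)))), 1e-4)
  expect_lt(max(abs(fit_inf$fitted - line)), 5e-3)
})

test_that("the basis Gram and penalty matrices integrate exactly", {
  basis <- bspline_basis(12, 4, seq(0, 1, length.out = 81))
  # trapezoid-rule cross-check on a very fine grid
  xf <- seq(0, 1, length.out = 20001)
  w <- c(0.5, rep(1, length(xf) - 2), 0.5) / (length(xf) - 1)
  Bf <- splines::splineDesign(basis$knots, xf, ord = 4)
  expect_equal(basis$G, t(Bf) %*% (w * Bf), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(basis$int_B, colSums(w * Bf), tolerance = 1e-7,
               ignore_attr = TRUE)
  B2f <- splines::splineDesign(basis$knots, xf, ord = 4,
                               derivs = rep(2L, length(xf)))
  expect_equal(basis$P, t(B2f) %*% (w * B2f), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("GCV selects small penalties for smooth signal and large for noise", {
  basis <- bspline_basis(20, 4, seq(0, 1, length.out = 101))
  grid_l <- 10^seq(-8, 2, by = 0.5)
  # noise-free curve in the basis span: smallest lambda wins
  y_smooth <- drop(basis$B %*% rnorm(20))
  expect_equal(select_lambda_gcv(y_smooth, basis, grid_l)[1], min(grid_l))
  # pure noise: the modal selection over seeds is among the largest lambdas
  picks <- vapply(1:20, function(s) {
    set.seed(100 + s)
    select_lambda_gcv(rnorm(101), basis, grid_l)[1]
  }, numeric(1))
  mode_pick <- as.numeric(names(which.max(table(picks))))
  expect_gte(mode_pick, sort(grid_l, decreasing = TRUE)[3])
  # the returned lambda minimises the reported score path
  lam <- select_lambda_gcv(sin(4 * basis$grid) + rnorm(101, 0, 0.2), basis, grid_l)
  path <- attr(lam, "gcv")
  expect_equal(path$gcv[path$lambda == as.numeric(lam)], min(path$gcv))
  expect_error(select_lambda_gcv(y_smooth, basis, c(-1, 1)), "positive")
})

test_that("fPCA with an interpolating basis reduces to discrete PCA", {
  set.seed(12)
  n <- 30; n_grid <- 41; n_slot <- 3
  vals <- array(0, c(n, n_slot, n_grid))
  g <- seq(0, 1, length.out = n_grid)
  # endpoint-vanishing curves so that grid summation and exact integration
  # agree up to the stated tolerance
  for (i in 1:n) for (j in 1:n_slot) {
    vals[i, j, ] <- rnorm(1, 1, 0.3) * sin(pi * g) +
      rnorm(1, 0, 0.2) * sin(2 * pi * g) + j * 0.1 * sin(3 * pi * g)
  }
  fp <- run_fpca(vals, n_basis = n_grid, lambda = 0)
  oracle <- discrete_pca_prop(matrix(aperm(vals, c(1, 2, 3)), n, n_slot * n_grid))
  k <- 6
  expect_equal(fp$prop[1:k], oracle[1:k], tolerance = 1e-3)
})

test_that("eigenfunctions are orthonormal and reconstruct the samples", {
  fp <- default_fpca()
  G <- fp$basis$G
  nb <- fp$basis$n_basis
  K <- 6
  # concatenated L2 inner products of the first K eigenfunctions
  ip <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K) {
    ip[a, b] <- sum(vapply(seq_len(dim(fp$eigenfunctions)[2]), function(j) {
      drop(t(fp$eigenfunctions[, j, a]) %*% G %*% fp$eigenfunctions[, j, b])
    }, numeric(1)))
  }
  expect_equal(ip, diag(K), tolerance = 1e-6, ignore_attr = TRUE)
  # slot scores sum to the total score
  for (pc in 1:3) {
    expect_equal(rowSums(fpca_slot_scores(fp, pc)), unname(fp$scores[, pc]),
                 tolerance = 1e-8)
  }
  # residual norm decreases as more components are retained
  n_slot <- dim(fp$eigenfunctions)[2]
  U <- fp$.Cc
  for (j in seq_len(n_slot)) {
    ix <- ((j - 1) * nb + 1):(j * nb)
    U[, ix] <- fp$.Cc[, ix] %*% fp$.Gh
  }
  res <- vapply(c(2, 5, 10, 20), function(k) {
    sum((U - fp$scores[, 1:k, drop = FALSE] %*% t(fp$.v[, 1:k, drop = FALSE]))^2)
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("degenerate inputs are flagged and trivial clusterings handled", {
  vals <- array(rep(sin(seq(0, pi, length.out = 31)), each = 8), c(8, 2, 31))
  expect_warning(fp <- run_fpca(vals, n_basis = 10), "identical")
  expect_true(fp$degenerate)
  # two identical time-point columns merge at height zero
  fp2 <- default_fpca()
  M <- fpca_slot_scores(fp2, 2)
  M2 <- cbind(M, M[, ncol(M)])
  colnames(M2) <- c(colnames(M), "dup")
  hc <- hclust(dist(t(M2)), method = "ward.D2")
  expect_equal(min(hc$height), 0)
})

test_that("time points cluster into early, middle and late fatigue phases", {
  fp <- default_fpca()
  cl <- cluster_scores(fp, pc = 1, k_time = 3)
  expect_s3_class(cl, "score_clustering")
  expect_equal(sort(unique(cl$time_clusters)), 1:3)
  expect_length(cl$sample_clusters, nrow(fp$scores))
  # on the default cohort the leading components separate the pre/early
  # window from the 24-48 h neuromuscular window
  splits <- vapply(1:2, function(pc) {
    early_late_split(cluster_scores(fp, pc = pc)$time_clusters)
  }, logical(1))
  expect_true(any(splits))
})
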