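sim_lme_data <- function(seed, n_g = 10, n_per = 15, beta = c(2.3, 0.1, -0.05),
                         sd_b = 0.1, sd_e = 0.08) {
  set.seed(seed)
  g <- rep(seq_len(n_g), each = n_per)
  X <- cbind(1, rnorm(n_g * n_per), rnorm(n_g * n_per))
  colnames(X) <- c("(Intercept)", "PC1", "PC2")
  b <- rnorm(n_g, 0, sd_b)
  y <- drop(X %*% beta) + b[g] + rnorm(n_g * n_per, 0, sd_e)
  list(y = y, X = X, g = g, beta = beta)
}

test_that("profiled ML matches the brute-force likelihood grid", {
  d <- sim_lme_data(21, n_g = 5, n_per = 6)
  fit <- fit_lme(d$y, d$X, d$g)
  oracle <- lme_grid_oracle(d$y, d$X, d$g)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
  expect_equal(fit$sigma2_b, oracle$sigma2_b, tolerance = 1e-3)
  # direct likelihood at the fitted components reproduces the fitted value
  expect_equal(lme_loglik_direct(d$y, d$X, d$g, fit$sigma2_b, fit$sigma2_e),
               fit$loglik, tolerance = 1e-6)
})

test_that("ML estimates agree with nlme on a balanced toy problem", {
  skip_if_not_installed("nlme")
  d <- sim_lme_data(3, n_g = 8, n_per = 10)
  fit <- fit_lme(d$y, d$X, d$g)
  df <- data.frame(y = d$y, x1 = d$X[, 2], x2 = d$X[, 3], g = factor(d$g))
  ref <- nlme::lme(y ~ x1 + x2, random = ~ 1 | g, data = df, method = "ML")
  expect_equal(unname(fit$beta), unname(nlme::fixef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$sigma2_e, ref$sigma^2, tolerance = 1e-4)
})

test_that("zero athlete variance is recovered and equals least squares", {
  hits <- 0
  for (s in 1:100) {
    d <- sim_lme_data(1000 + s, n_g = 8, n_per = 8, sd_b = 0, sd_e = 0.01)
    fit <- fit_lme(d$y, d$X, d$g)
    se <- sqrt(diag(fit$vcov_beta))
    # slope coefficients each inside their own 2-SE interval
    hits <- hits + (fit$sigma2_b < 1e-4 &&
                      all((abs(fit$beta - d$beta) <= 2 * se)[2:3]))
  }
  expect_gte(hits / 100, 0.9)
  # with the boundary solution the fixed effects equal OLS
  d0 <- sim_lme_data(77, n_g = 6, n_per = 10, sd_b = 0, sd_e = 0.2)
  fit0 <- fit_lme(d0$y, d0$X, d0$g)
  if (fit0$lambda == 0) {
    expect_equal(unname(fit0$beta),
                 unname(coef(lm(d0$y ~ d0$X - 1))), tolerance = 1e-8)
  }
  ls_direct <- qr.solve(d0$X, d0$y)
  expect_equal(unname(fit0$beta), unname(ls_direct), tolerance = 1e-2)
})

test_that("non-identifiable and degenerate designs are flagged or rejected", {
  set.seed(9)
  y <- rnorm(6)
  X <- cbind(1, rnorm(6))
  expect_false(fit_lme(y, X, 1:6)$converged)   # one observation per group
  expect_error(fit_lme(y, X, rep(1, 6)), "2 groups")
  expect_error(fit_lme(y, cbind(X, X[, 2]), rep(1:2, 3)), "rank deficient")
})

test_that("leave-one-athlete-out CV pools fixed-effect predictions", {
  # perfectly linear noise-free data: CV error vanishes
  d <- sim_lme_data(5, n_g = 5, n_per = 8, sd_b = 0, sd_e = 0)
  expect_lt(loocv_lme(d$y, d$X, d$g), 1e-10)
  # one fold per athlete
  d2 <- sim_lme_data(6)
  mse <- loocv_lme(d2$y, d2$X, d2$g)
  expect_equal(nrow(attr(mse, "per_group")), 10)
  # relabelling athletes does not change the pooled MSE
  relab <- paste0("ath_", 11 - as.integer(factor(d2$g)))
  expect_equal(as.numeric(loocv_lme(d2$y, d2$X, relab)), as.numeric(mse),
               tolerance = 1e-8)
  expect_error(loocv_lme(d$y, d$X, rep(1:2, 20)), "3 groups")
})

test_that("restricting the information window cannot improve prediction on average", {
  wins <- 0
  n_rep <- 50
  for (seed in seq_len(n_rep)) {
    f <- simulate_features(seed = seed)
    ib <- suppressMessages(build_model_inputs(
      f, list(horizon = "6", source = "PCA", window = "baseline")))
    ip <- suppressMessages(build_model_inputs(
      f, list(horizon = "6", source = "PCA", window = "practical")))
    wins <- wins + (loocv_lme(ip$y, ip$X, ip$groups) >=
                      loocv_lme(ib$y, ib$X, ib$groups))
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("R-squared is the squared observed-fitted correlation", {
  d <- sim_lme_data(8, sd_b = 0, sd_e = 0)
  fit <- fit_lme(d$y, d$X, d$g)
  expect_equal(r_squared(fit), 1, tolerance = 1e-8)
  # uncorrelated predictors at large n: R2 near zero
  set.seed(10)
  y <- rnorm(2000)
  X <- cbind(1, rnorm(2000))
  fit2 <- fit_lme(y, X, rep(1:10, each = 200))
  expect_lt(r_squared(fit2), 0.05)
  expect_warning(r_squared(fit, rep(1, length(d$y))), "zero variance")
})

test_that("likelihood-ratio tests follow the chi-squared reference", {
  d <- sim_lme_data(11)
  fit_a <- fit_lme(d$y, d$X, d$g)
  lrt0 <- likelihood_ratio_test(fit_a, fit_a)
  expect_equal(lrt0$lr, 0)
  # known likelihoods -10 vs -12 with one extra parameter: LR 4, p ~ 0.0455
  fit_b <- fit_lme(d$y, d$X[, 1:2], d$g)
  fake_a <- fit_a; fake_a$loglik <- -10
  fake_b <- fit_b; fake_b$loglik <- -12
  lrt <- likelihood_ratio_test(fake_a, fake_b)
  expect_equal(lrt$lr, 4)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(lrt$p_value, 4), 0.0455)
  # non-nested equal-size models: NA p-value and a warning
  fit_c <- fit_lme(d$y, cbind(d$X[, 1:2], Z = rnorm(length(d$y))), d$g)
  expect_warning(lrt_nn <- likelihood_ratio_test(fit_a, fit_c), "not nested")
  expect_true(is.na(lrt_nn$p_value))
  expect_error(likelihood_ratio_test(fit_a, fit_lme(d$y[1:50], d$X[1:50, ],
                                                    d$g[1:50])),
               "different response lengths")
})

test_that("Wald intervals for fixed effects attain nominal coverage", {
  covered <- matrix(FALSE, 200, 2)
  for (s in 1:200) {
    d <- sim_lme_data(2000 + s)     # 10 athletes x 15 rows, the study scale
    fit <- fit_lme(d$y, d$X, d$g)
    se <- sqrt(diag(fit$vcov_beta))
    lo <- fit$beta - 1.96 * se
    hi <- fit$beta + 1.96 * se
    covered[s, ] <- (d$beta >= lo & d$beta <= hi)[2:3]
  }
  cov_rate <- mean(covered)
  expect_gte(cov_rate, 0.88)
  expect_lte(cov_rate, 0.99)
})

test_that("the eight-model report is complete and serialises losslessly", {
  rep8 <- suppressMessages(
    run_fatigue_models(default_features(), default_curves()))
  expect_equal(nrow(rep8$models), 8)
  expect_false(any(rep8$models$failed))
  expect_true(all(rep8$models$mse_cv >= 0))
  expect_true(all(rep8$models$r2 <= 1))
  expect_equal(nrow(rep8$comparisons), 6)
  path <- tempfile(fileext = ".json")
  write_model_report(rep8, path)
  back <- read_model_report(path)
  expect_equal(back$models$mse_cv, rep8$models$mse_cv, tolerance = 1e-12)
  expect_equal(back$comparisons$lr, rep8$comparisons$lr, tolerance = 1e-12)
})

test_that("noise-free cohorts with uniform susceptibility are fit almost exactly", {
  des <- study_design()
  ath <- simulate_athletes(des, seed = 5, susceptibility_sd = 0)
  sn <- simulate_study(des, seed = 5, noise = noise_free(), athletes = ath)
  fn <- extract_study_features(sn)
  cvn <- suppressMessages(study_curves(sn))
  repn <- suppressMessages(run_fatigue_models(fn, cvn))
  expect_true(all(repn$models$r2 > 0.99))
})

test_that("practical windows use the 12-variable matrix, baselines all 32", {
  f <- default_features()
  ip <- suppressMessages(build_model_inputs(
    f, list(horizon = "6", source = "PCA", window = "practical")))
  expect_equal(ncol(ip$scores_result$loadings), 12)
  ib <- suppressMessages(build_model_inputs(
    f, list(horizon = "48", source = "PCA", window = "baseline")))
  expect_equal(nrow(ib$scores_result$loadings), 32)
  expect_equal(colnames(ip$X), c("(Intercept)", "PC1", "PC2"))
  expect_equal(length(ib$y), 150)
})
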