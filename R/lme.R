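#' Random-intercept linear mixed model by profiled maximum likelihood
#'
#' Fits `y = X beta + Z b + e` with one random intercept per group,
#' `b ~ N(0, sigma2_b)`, `e ~ N(0, sigma2_e)`, by maximum likelihood (not
#' REML). The likelihood is profiled over the variance ratio
#' `lambda = sigma2_b / sigma2_e`: for fixed lambda the GLS estimate of
#' `beta` and the ML estimate of `sigma2_e` are closed-form, and the
#' one-dimensional profile is maximised numerically over `log(lambda)`
#' (including the boundary `lambda = 0`, ordinary least squares).
#'
#' @param y response vector (relative peak force, bodyweight multiples).
#' @param X fixed-effects design matrix including the intercept column.
#' @param groups grouping factor (athlete), length `length(y)`.
#' @return Object of class `cmj_lme`: `beta`, `sigma2_b`, `sigma2_e`,
#'   `lambda`, `loglik`, `fitted` (conditional on predicted random
#'   intercepts), `ranef`, `vcov_beta`, `converged`, plus the inputs.
#' @export
fit_lme <- function(y, X, groups) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(groups) == n)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design matrix is rank deficient")
  gi <- split(seq_len(n), g)
  ni <- lengths(gi)
  converged <- TRUE
  note <- NULL
  if (all(ni == 1)) {
    converged <- FALSE
    note <- "one observation per group: sigma2_b and sigma2_e are not separately identifiable"
  }

  # profile negative log-likelihood at variance ratio lambda
  prof <- function(lambda) {
    XtVX <- matrix(0, ncol(X), ncol(X))
    XtVy <- numeric(ncol(X))
    for (k in seq_along(gi)) {
      ix <- gi[[k]]
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      w <- lambda / (1 + lambda * ni[k])
      sx <- colSums(Xi)
      sy <- sum(yi)
      XtVX <- XtVX + crossprod(Xi) - w * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xi, yi) - w * sx * sy
    }
    beta <- solve(XtVX, XtVy)
    rss <- 0
    for (k in seq_along(gi)) {
      ix <- gi[[k]]
      r <- y[ix] - X[ix, , drop = FALSE] %*% beta
      w <- lambda / (1 + lambda * ni[k])
      rss <- rss + sum(r^2) - w * sum(r)^2
    }
    # floor guards the log for noise-free (perfectly fitted) responses
    sigma2_e <- max(as.numeric(rss / n), 1e-300)
    ll <- -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sigma2_e) -
      0.5 * sum(log(1 + lambda * ni))
    list(beta = drop(beta), sigma2_e = sigma2_e, loglik = unname(ll),
         XtVX = XtVX)
  }
  nll <- function(theta) -prof(exp(theta))$loglik
  opt <- stats::optimize(nll, c(-14, 14), tol = 1e-10)
  lambda <- exp(opt$minimum)
  if (-opt$objective < prof(0)$loglik) lambda <- 0     # boundary: no athlete variance
  if (opt$minimum > 13.9) {
    converged <- FALSE
    note <- c(note, "variance ratio diverged to the upper bound")
  }
  fit <- prof(lambda)
  sigma2_e <- fit$sigma2_e
  sigma2_b <- lambda * sigma2_e
  resid_m <- y - drop(X %*% fit$beta)
  bhat <- vapply(gi, function(ix) {
    lambda * length(ix) / (1 + lambda * length(ix)) * mean(resid_m[ix])
  }, numeric(1))
  fitted <- drop(X %*% fit$beta) + bhat[as.integer(g)]
  structure(list(beta = stats::setNames(fit$beta, colnames(X)),
                 sigma2_b = sigma2_b, sigma2_e = sigma2_e, lambda = lambda,
                 loglik = fit$loglik, fitted = fitted,
                 ranef = stats::setNames(bhat, levels(g)),
                 vcov_beta = sigma2_e * solve(fit$XtVX),
                 converged = converged, note = note,
                 y = y, X = X, groups = g, n = n, p = ncol(X)),
            class = "cmj_lme")
}

#' @export
print.cmj_lme <- function(x, digits = 4, ...) {
  cat("Random-intercept LME (ML), ", x$n, " obs, ",
      nlevels(x$groups), " groups\n", sep = "")
  cat("Fixed effects:\n")
  print(round(x$beta, digits))
  cat(sprintf("sigma2_b = %.*g, sigma2_e = %.*g, logLik = %.*f\n",
              digits, x$sigma2_b, digits, x$sigma2_e, 2, x$loglik))
  if (!x$converged) cat("NOT converged:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.cmj_lme <- function(object, ...) object$beta

#' @export
fitted.cmj_lme <- function(object, ...) object$fitted

#' @export
residuals.cmj_lme <- function(object, ...) object$y - object$fitted

#' @export
logLik.cmj_lme <- function(object, ...) {
  structure(object$loglik, df = object$p + 2, nobs = object$n,
            class = "logLik")
}

#' Predict from a fitted random-intercept model
#'
#' @param object a `cmj_lme`.
#' @param newdata design matrix for the fixed effects.
#' @param groups optional group labels; predicted random intercepts are
#'   added for groups seen at fit time, and 0 is used for unseen groups
#'   (fixed-effects-only prediction).
#' @param ... unused.
#' @return Predicted responses.
#' @export
predict.cmj_lme <- function(object, newdata, groups = NULL, ...) {
  mu <- drop(as.matrix(newdata) %*% object$beta)
  if (!is.null(groups)) {
    b <- object$ranef[as.character(groups)]
    b[is.na(b)] <- 0
    mu <- mu + unname(b)
  }
  mu
}

#' @export
summary.cmj_lme <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  tab <- cbind(Estimate = object$beta, `Std.Error` = se,
               z = object$beta / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$beta / se)))
  var_fix <- stats::var(drop(object$X %*% object$beta))
  denom <- var_fix + object$sigma2_b + object$sigma2_e
  out <- list(coefficients = tab, sigma2_b = object$sigma2_b,
              sigma2_e = object$sigma2_e, loglik = object$loglik,
              r2_marginal = var_fix / denom,
              r2_conditional = (var_fix + object$sigma2_b) / denom,
              converged = object$converged)
  class(out) <- "summary.cmj_lme"
  out
}

#' @export
print.summary.cmj_lme <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("sigma2_b = %.4g  sigma2_e = %.4g  logLik = %.2f\n",
              x$sigma2_b, x$sigma2_e, x$loglik))
  cat(sprintf("pseudo-R2: marginal %.3f, conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Leave-one-athlete-out cross-validated MSE
#'
#' For each group in turn, the model is refitted on the remaining groups and
#' the held-out responses are predicted from the fixed effects only (an
#' unseen athlete has no estimable random intercept). The MSE is pooled over
#' all held-out observations.
#'
#' @inheritParams fit_lme
#' @return The pooled cross-validated MSE, with attributes `per_group`
#'   (data frame of per-fold MSEs) and `skipped` (folds with degenerate
#'   designs, if any).
#' @export
loocv_lme <- function(y, X, groups) {
  X <- as.matrix(X)
  g <- factor(groups)
  if (nlevels(g) < 3) stop("leave-one-group-out needs at least 3 groups")
  lev <- levels(g)
  se <- numeric(0)
  per <- data.frame(group = character(0), n = integer(0), mse = numeric(0))
  skipped <- character(0)
  for (l in lev) {
    hold <- g == l
    fit <- tryCatch(fit_lme(y[!hold], X[!hold, , drop = FALSE],
                            droplevels(g[!hold])),
                    error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, l)
      message("fold ", l, " skipped: degenerate design")
      next
    }
    pred <- predict(fit, X[hold, , drop = FALSE])
    err <- (y[hold] - pred)^2
    se <- c(se, err)
    per <- rbind(per, data.frame(group = l, n = sum(hold), mse = mean(err)))
  }
  mse <- mean(se)
  attr(mse, "per_group") <- per
  attr(mse, "skipped") <- skipped
  mse
}

#' Coefficient of determination of a fitted model
#'
#' Squared Pearson correlation between observed responses and fitted values
#' conditional on the predicted random intercepts.
#'
#' @param fit a `cmj_lme`.
#' @param y observed responses; defaults to those used at fit time.
#' @return R-squared in \[0, 1\]; `NA` (with a warning) when `y` has zero
#'   variance.
#' @export
r_squared <- function(fit, y = fit$y) {
  if (stats::sd(y) == 0 || stats::sd(fit$fitted) == 0) {
    warning("zero variance: R-squared undefined")
    return(NA_real_)
  }
  stats::cor(y, fit$fitted)^2
}

#' Likelihood-ratio test between two fitted models
#'
#' `LR = 2 |ll_a - ll_b|`, referred to a chi-squared distribution with
#' degrees of freedom equal to the difference in fixed-effect counts. When
#' neither model's predictor set contains the other's, the comparison is not
#' a nested test: a warning is attached, and when the parameter counts are
#' equal (df = 0) the p-value is reported as `NA` alongside the raw LR.
#'
#' @param fit_a,fit_b `cmj_lme` fits of the same response vector.
#' @param nested override for the nestedness determination; by default it is
#'   inferred from the design column names, which cannot detect that two
#'   identically named predictors (e.g. PC1 from different score sources)
#'   are different variables.
#' @return List of class `cmj_lrt`: `lr`, `df`, `p_value`, `nested`.
#' @export
likelihood_ratio_test <- function(fit_a, fit_b, nested = NULL) {
  stopifnot(inherits(fit_a, "cmj_lme"), inherits(fit_b, "cmj_lme"))
  if (fit_a$n != fit_b$n) stop("models fit different response lengths")
  if (!isTRUE(all.equal(fit_a$y, fit_b$y))) {
    warning("response vectors differ between the two fits")
  }
  if (is.null(nested)) {
    nested <- all(colnames(fit_b$X) %in% colnames(fit_a$X)) ||
      all(colnames(fit_a$X) %in% colnames(fit_b$X))
  }
  lr <- 2 * abs(fit_a$loglik - fit_b$loglik)
  df <- abs(fit_a$p - fit_b$p)
  p <- if (df == 0) NA_real_ else stats::pchisq(lr, df, lower.tail = FALSE)
  if (!nested) {
    warning("models are not nested: the chi-squared reference is descriptive only")
  }
  structure(list(lr = lr, df = df, p_value = p, nested = nested),
            class = "cmj_lrt")
}

#' @export
print.cmj_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio = %.3f (df = %d), p = %s%s\n", x$lr, x$df,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value),
              if (!x$nested) " [non-nested comparison]" else ""))
  invisible(x)
}
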