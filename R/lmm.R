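#' Gaussian linear mixed model with a single random intercept, fit by ML
#'
#' Fits `y = X beta + b[group] + e`, with `b ~ N(0, sigma2_subject)` per
#' grouping level and `e ~ N(0, sigma2_resid)`, by maximum likelihood (not
#' REML — likelihood-ratio tests on fixed effects require ML, and reported
#' standard errors use the ML `1/n` variance scaling throughout).
#'
#' The log-likelihood is profiled over the single variance ratio
#' `lambda = sigma2_subject / sigma2_resid`: for fixed `lambda`, the GLS
#' estimates of `beta` and the residual variance have closed forms via the
#' Woodbury identity on the block-diagonal marginal covariance, so the fit
#' reduces to a 1-D bounded optimization over `log(lambda)` plus an
#' explicit evaluation at the `lambda = 0` boundary. At the boundary the
#' fit coincides with ordinary least squares (with ML variance scaling).
#'
#' Fixed-effect factors use whatever contrasts the data's factor levels
#' imply (treatment contrasts by default); relevel the data to choose the
#' reference category.
#'
#' @param formula fixed-effects formula, e.g. `relative_ugc ~ behaviour`.
#' @param data data frame with the model variables and the grouping column.
#' @param group name of the grouping column (random-intercept factor).
#' @param lambda_interval search interval for `log(lambda)`.
#' @param tol convergence tolerance on `log(lambda)`.
#' @return An object of class `ugc_lmm` with elements `beta`, `se`, `t`
#'   (named by design-matrix columns), `sigma2_subject`, `sigma2_resid`,
#'   `loglik`, `converged`, `n_obs`, `n_groups`, `lambda`, `fitted`,
#'   `residuals`, plus the pieces needed to refit (`formula`, `group`).
#' @examples
#' fit <- fit_lmm(relative_ugc ~ behaviour, budongo_ugc(), group = "subject_id")
#' fit$beta["behaviouraggression"]   # 26.91
#' @seealso [lrt()], [stability_check()], [reference_models()]
#' @export
fit_lmm <- function(formula, data, group,
                    lambda_interval = c(-15, 15), tol = 1e-10) {
  if (!group %in% names(data))
    stop("fit_lmm: grouping column '", group, "' not in data", call. = FALSE)
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[, c(vars, group), drop = FALSE])
  d2 <- data[cc, , drop = FALSE]
  mf <- stats::model.frame(formula, d2)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  g <- factor(d2[[group]])
  if (nlevels(g) < 2)
    stop("fit_lmm: need at least 2 groups, got ", nlevels(g), call. = FALSE)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fit_lmm: design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  n <- length(y)
  p <- ncol(X)
  idx <- split(seq_len(n), g)
  ni <- lengths(idx)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  ## per-group sums for the Woodbury correction terms
  Gx <- t(vapply(idx, function(ii) colSums(X[ii, , drop = FALSE]),
                 numeric(p)))      # n_groups x p
  if (p == 1) Gx <- matrix(Gx, ncol = 1)
  Gy <- vapply(idx, function(ii) sum(y[ii]), numeric(1))

  profile_at <- function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    A <- XtX - crossprod(Gx * sqrt(ci))          # X' V^-1 X
    b <- Xty - colSums(Gx * (ci * Gy))           # X' V^-1 y
    q <- yty - sum(ci * Gy^2)                    # y' V^-1 y
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta)) return(list(loglik = -Inf))
    rss <- as.numeric(q - 2 * sum(beta * b) + t(beta) %*% A %*% beta)
    rss <- max(rss, 0)
    ## an exact fit (identical responses within a group structure) leaves
    ## numerical dust in rss; snap it to the degenerate zero-variance case
    if (rss < 1e-14 * max(yty, 1)) rss <- 0
    s2 <- rss / n
    logdet <- sum(log1p(lambda * ni))
    loglik <- if (s2 <= 0) Inf else
      -n / 2 * (log(2 * pi * s2) + 1) - logdet / 2
    list(loglik = loglik, beta = drop(beta), s2 = s2, A = A)
  }

  at0 <- profile_at(0)
  opt <- stats::optimize(function(l) {
    ll <- profile_at(exp(l))$loglik
    if (ll > 1e300) ll <- 1e300   # exact fit: keep the objective finite
    -ll
  }, lambda_interval, tol = tol)
  lam_int <- exp(opt$minimum)
  at_int <- profile_at(lam_int)
  if (is.finite(at0$loglik) && at0$loglik >= at_int$loglik) {
    lambda <- 0; best <- at0
  } else {
    lambda <- lam_int; best <- at_int
  }

  se <- if (best$s2 > 0) sqrt(diag(solve(best$A)) * best$s2)
        else rep(0, p)
  beta <- best$beta
  names(beta) <- names(se) <- colnames(X)
  tval <- ifelse(se > 0, beta / se, NA_real_)

  ## conditional fitted values use only the marginal mean (BLUPs omitted:
  ## diagnostics in this package are on marginal residuals)
  fitted <- drop(X %*% beta)

  structure(list(
    beta = beta, se = se, t = tval,
    sigma2_subject = lambda * best$s2, sigma2_resid = best$s2,
    lambda = lambda, loglik = best$loglik,
    converged = is.finite(best$loglik) || best$s2 == 0,
    n_obs = n, n_groups = nlevels(g), p = p,
    fitted = fitted, residuals = y - fitted,
    formula = formula, group = group, response = y, groups = g
  ), class = "ugc_lmm")
}

#' @export
print.ugc_lmm <- function(x, ...) {
  cat("Gaussian LMM (ML), random intercept by '", x$group, "'\n", sep = "")
  cat(deparse(x$formula), "\n")
  tab <- data.frame(beta = x$beta, SE = x$se, t = x$t)
  print(round(tab, 3))
  cat(sprintf("sigma2_subject = %.4g, sigma2_resid = %.4g, logLik = %.4f\n",
              x$sigma2_subject, x$sigma2_resid, x$loglik))
  cat(sprintf("n = %d observations, %d groups%s\n", x$n_obs, x$n_groups,
              if (x$sigma2_subject == 0) " (variance on zero boundary)" else ""))
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' `chi2 = 2 * (loglik_full - loglik_null)` referenced to a chi-square
#' distribution with `df` = difference in fixed-effect parameter count.
#' No boundary correction is applied (the test concerns fixed effects; the
#' random-effect structure is identical in both models).
#'
#' @param full,null `ugc_lmm` fits on the same data and grouping, the
#'   null's fixed effects nested in the full's.
#' @return List of class `ugc_lrt`: `chi2`, `df`, `p`.
#' @export
lrt <- function(full, null) {
  stopifnot(inherits(full, "ugc_lmm"), inherits(null, "ugc_lmm"))
  if (full$n_obs != null$n_obs ||
      !isTRUE(all.equal(sort(full$response), sort(null$response))))
    stop("lrt: models must be fitted to the same data", call. = FALSE)
  if (full$group != null$group)
    stop("lrt: models must share the grouping factor", call. = FALSE)
  if (!all(names(null$beta) %in% names(full$beta)))
    stop("lrt: null model fixed effects are not nested in the full model",
         call. = FALSE)
  chi2 <- 2 * (full$loglik - null$loglik)
  if (chi2 < -1e-8)
    stop("lrt: negative chi-square beyond numerical tolerance (", chi2,
         "); models are not nested ML fits", call. = FALSE)
  chi2 <- max(chi2, 0)
  df <- full$p - null$p
  if (df < 1) stop("lrt: full model has no extra parameters", call. = FALSE)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "ugc_lrt")
}

#' @export
print.ugc_lrt <- function(x, ...) {
  cat(sprintf("likelihood ratio test: chi2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Variance inflation factors (no random effect)
#'
#' Collinearity diagnostic computed from a standard linear model excluding
#' the random effect: each non-intercept design column is regressed on all
#' the others, and `VIF = 1 / (1 - R^2)`. A single predictor has VIF 1 by
#' definition; perfectly collinear predictors are reported as `Inf`, not
#' raised as an error.
#'
#' @param formula fixed-effects formula (response is ignored beyond
#'   defining the frame).
#' @param data data frame.
#' @return Named numeric vector of VIFs, one per non-intercept design
#'   column.
#' @export
vif_check <- function(formula, data) {
  X <- stats::model.matrix(formula, stats::model.frame(formula, data))
  keep <- colnames(X) != "(Intercept)"
  Xp <- X[, keep, drop = FALSE]
  k <- ncol(Xp)
  if (k == 0) stop("vif_check: no predictors", call. = FALSE)
  out <- stats::setNames(rep(1, k), colnames(Xp))
  if (k == 1) return(out)
  for (j in seq_len(k)) {
    fit <- stats::lm.fit(cbind(1, Xp[, -j, drop = FALSE]), Xp[, j])
    v <- Xp[, j]
    tss <- sum((v - mean(v))^2)
    r2 <- if (tss <= 0) 1 else 1 - sum(fit$residuals^2) / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Leave-one-subject-out model stability
#'
#' Refits the model once per grouping level with that subject's rows
#' removed. The model is flagged stable when every refit is estimable
#' (at least two groups remain), converges, and no fixed-effect estimate
#' (beyond the intercept) changes sign relative to the all-data fit.
#'
#' @param formula fixed-effects formula.
#' @param data data frame.
#' @param group grouping column name.
#' @return List of class `ugc_stability`: `fit` (all-data fit),
#'   `refits` (per-excluded-subject `ugc_lmm` or `NULL` if non-estimable),
#'   `estimates` (matrix of refit fixed effects), `stable`, `reasons`.
#' @export
stability_check <- function(formula, data, group) {
  g <- factor(data[[group]])
  if (nlevels(g) < 3)
    stop("stability_check: need at least 3 groups", call. = FALSE)
  fit <- fit_lmm(formula, data, group)
  ref <- fit$beta[names(fit$beta) != "(Intercept)"]
  refits <- list()
  est <- matrix(NA_real_, nlevels(g), length(fit$beta),
                dimnames = list(levels(g), names(fit$beta)))
  reasons <- character(0)
  for (lev in levels(g)) {
    sub <- data[g != lev, , drop = FALSE]
    f <- tryCatch(fit_lmm(formula, sub, group), error = function(e) e)
    if (inherits(f, "error")) {
      refits[[lev]] <- NULL
      reasons <- c(reasons, sprintf("excluding %s: non-estimable (%s)",
                                    lev, conditionMessage(f)))
      next
    }
    refits[[lev]] <- f
    est[lev, names(f$beta)] <- f$beta
    if (!f$converged)
      reasons <- c(reasons, sprintf("excluding %s: did not converge", lev))
    b <- f$beta[names(ref)]
    flip <- sign(b) * sign(ref) < 0
    if (any(flip, na.rm = TRUE))
      reasons <- c(reasons,
                   sprintf("excluding %s: sign flip in %s", lev,
                           paste(names(ref)[which(flip)], collapse = ", ")))
  }
  structure(list(fit = fit, refits = refits, estimates = est,
                 stable = length(reasons) == 0, reasons = reasons),
            class = "ugc_stability")
}

#' @export
print.ugc_stability <- function(x, ...) {
  cat("leave-one-subject-out stability: ",
      if (x$stable) "stable" else "UNSTABLE", "\n", sep = "")
  if (length(x$reasons)) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}
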