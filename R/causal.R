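# Causal pipeline, part 1: covariate-balancing weights for a continuous
# exposure (entropy balancing), weighted average causal effects with
# sandwich errors, and a simulated-confounder sensitivity scan with the
# tau1/tau2 robustness summaries.

# Expand a covariate data.frame to a numeric design matrix (one-hot for
# factors/characters, no intercept), dropping constant columns.
design_matrix <- function(covariates) {
  d <- as.data.frame(covariates)
  for (nm in names(d)) {
    if (is.character(d[[nm]]) || is.logical(d[[nm]])) {
      d[[nm]] <- factor(d[[nm]])
    }
  }
  # full-rank coding: k-1 dummies per factor (drop the intercept column)
  x <- stats::model.matrix(~ ., data = d)[, -1, drop = FALSE]
  keep <- apply(x, 2, function(c) stats::sd(c) > 0)
  x[, keep, drop = FALSE]
}

standardize <- function(x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, stats::sd), "/")
}

#' Entropy-balancing weights for a continuous exposure
#'
#' Finds the weights of minimum Kullback-Leibler divergence from uniform
#' that zero out the weighted covariance between the exposure (and, for
#' `moments = c(1, 2)`, its square) and every covariate column, while
#' also preserving zero weighted means of the standardized covariates and
#' exposure.  Solved in the convex dual (log-partition minimization) with
#' BFGS; this is the balancing contract of covariate-balancing generalized
#' propensity scores, implemented as moment constraints.
#'
#' @param exposure Numeric vector (continuous treatment).
#' @param covariates data.frame or matrix of covariates (factors are
#'   one-hot encoded, all columns standardized internally).
#' @param moments Exposure moments to balance against every covariate
#'   (`1`, or `c(1, 2)`).
#' @param tol Feasibility tolerance on the balanced moments.
#' @return Object of class `balancing_weights`: `weights` (positive,
#'   summing to n), `balance_report` (weighted covariate-exposure
#'   correlations), `effective_sample_size`, `converged`.
#' @export
balancing_weights <- function(exposure, covariates, moments = c(1, 2),
                              tol = 1e-6) {
  e <- as.numeric(exposure)
  if (stats::sd(e) == 0) stop("exposure has zero variance", call. = FALSE)
  x <- standardize(design_matrix(covariates))
  n <- length(e)
  es <- (e - mean(e)) / stats::sd(e)
  g <- cbind(x, es)
  if (2 %in% moments) g <- cbind(g, es^2 - mean(es^2))
  for (mom in intersect(moments, 1:2)) {
    em <- if (mom == 1) es else es^2 - mean(es^2)
    g <- cbind(g, x * em)
  }
  if (n <= ncol(g)) {
    stop("infeasible: more balance constraints (", ncol(g),
         ") than samples; reduce `moments`", call. = FALSE)
  }
  # Newton iteration on the convex dual (log-partition function); the
  # Hessian is the weighted covariance of the constraint columns.
  theta <- numeric(ncol(g))
  wts <- function(theta) {
    z <- as.numeric(g %*% theta)
    w <- exp(z - max(z))
    w / sum(w)
  }
  for (it in seq_len(100)) {
    w <- wts(theta)
    gr <- as.numeric(crossprod(g, w))
    if (max(abs(gr)) < 1e-12) break
    gw <- g * w
    H <- crossprod(g, gw) - tcrossprod(gr)
    step <- tryCatch(
      solve(H + diag(1e-10, ncol(g)), -gr),
      error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    f0 <- {
      z <- as.numeric(g %*% theta)
      mz <- max(z)
      log(mean(exp(z - mz))) + mz
    }
    repeat {
      cand <- theta + lambda * step
      z <- as.numeric(g %*% cand)
      mz <- max(z)
      f1 <- log(mean(exp(z - mz))) + mz
      if (is.finite(f1) && f1 <= f0 + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
    theta <- cand
  }
  w <- as.numeric(wts(theta)) * n
  resid <- max(abs(crossprod(g, w / n)))
  if (!is.finite(resid) || resid > tol) {
    stop("infeasible balance constraints (residual ",
         format(resid, digits = 3),
         "): covariates may be collinear with the exposure; ",
         "try `moments = 1`", call. = FALSE)
  }
  ess <- sum(w)^2 / sum(w^2)
  if (ess < n / 5) {
    warning("extreme weights: effective sample size ",
            round(ess, 1), " < n/5")
  }
  wc <- function(a, b) {
    ma <- sum(w * a) / sum(w)
    mb <- sum(w * b) / sum(w)
    va <- sum(w * (a - ma)^2)
    vb <- sum(w * (b - mb)^2)
    sum(w * (a - ma) * (b - mb)) / sqrt(va * vb)
  }
  report <- apply(x, 2, wc, b = es)
  structure(list(weights = w, balance_report = report,
                 effective_sample_size = ess, converged = resid <= tol),
            class = "balancing_weights")
}

#' @export
print.balancing_weights <- function(x, ...) {
  cat("balancing_weights: n =", length(x$weights),
      "ESS =", round(x$effective_sample_size, 1),
      "max |weighted cor| =", format(max(abs(x$balance_report)),
                                     digits = 3), "\n")
  invisible(x)
}

# Weighted least squares of y on (1, t, covariates) with HC0 sandwich
# errors; returns the exposure slope.  Under balancing weights the
# covariates are orthogonal to the exposure in the weighted inner
# product, so including them leaves the slope essentially unchanged
# while removing covariate-explained variance from the residuals (a
# correctly sized sandwich instead of a conservative one).
wls_slope <- function(y, t, w, x = NULL) {
  X <- cbind(1, t, x)
  A <- crossprod(X, X * w)
  beta <- solve(A, crossprod(X, y * w))
  r <- as.numeric(y - X %*% beta)
  meat <- crossprod(X, X * (w * r)^2)
  V <- solve(A, t(solve(A, meat)))
  list(gamma = beta[2], se = sqrt(V[2, 2]))
}

#' Average causal effect of a continuous exposure
#'
#' The weighted least-squares slope of (log) outcome on (log) exposure
#' under balancing weights: an elasticity, interpretable as the
#' percentage change in the outcome per one percent change in the
#' exposure.  Standard errors are robust (HC0 sandwich, weights treated
#' as fixed); p is two-sided normal.
#'
#' @param outcome,exposure Numeric vectors on the log scale.
#' @param w A [balancing_weights()] object (or numeric weights).
#' @param covariates Optional covariate data.frame/matrix included in
#'   the regression for variance estimation; under balancing weights
#'   they are orthogonal to the exposure, so the slope is unchanged but
#'   the sandwich error is correctly sized rather than conservative.
#' @return One-row data.frame `gamma`, `se`, `ci_lo`, `ci_hi`, `p`, `q`
#'   (`q` filled by panel wrappers).
#' @export
average_causal_effect <- function(outcome, exposure, w,
                                  covariates = NULL) {
  wt <- if (inherits(w, "balancing_weights")) w$weights else as.numeric(w)
  if (stats::sd(exposure) == 0) {
    stop("exposure has zero variance", call. = FALSE)
  }
  x <- if (is.null(covariates)) {
    NULL
  } else {
    standardize(design_matrix(covariates))
  }
  fit <- wls_slope(as.numeric(outcome), as.numeric(exposure), wt, x)
  z <- fit$gamma / fit$se
  data.frame(gamma = fit$gamma, se = fit$se,
             ci_lo = fit$gamma - 1.96 * fit$se,
             ci_hi = fit$gamma + 1.96 * fit$se,
             p = 2 * stats::pnorm(-abs(z)), q = NA_real_)
}

#' Average causal effects over an outcome panel
#'
#' Computes balancing weights once for the exposure, applies
#' [average_causal_effect()] to every outcome column and attaches Storey
#' q-values across the panel.
#'
#' @param t A [cohort_table()] (preprocessed: log-scale features).
#' @param outcomes Character vector of outcome columns.
#' @param exposure Exposure column name.
#' @param covariates Covariate columns (default: covariate role plus
#'   group).
#' @param moments Passed to [balancing_weights()].
#' @return data.frame, one row per outcome, plus attribute `weights`.
#' @export
ace_panel <- function(t, outcomes, exposure, covariates = NULL,
                      moments = c(1, 2)) {
  roles <- cohort_roles(t)
  if (is.null(covariates)) covariates <- roles$covariates
  d <- as.data.frame(t)
  cov_df <- d[, covariates, drop = FALSE]
  cov_df$group <- d$group
  w <- balancing_weights(d[[exposure]], cov_df, moments = moments)
  res <- do.call(rbind, lapply(outcomes, function(o) {
    r <- average_causal_effect(d[[o]], d[[exposure]], w,
                               covariates = cov_df)
    cbind(data.frame(outcome = o, stringsAsFactors = FALSE), r)
  }))
  res$q <- adjust_fdr(res$p)
  attr(res, "weights") <- w
  res
}

#' Sensitivity of a causal estimate to unmeasured confounding
#'
#' Simulation-based scan: for each point `(zeta_t, zeta_y)` of a lattice
#' over `[0, 1]^2`, a latent standard-normal confounder `U` is drawn with
#' marginal correlations `zeta_t` with the (standardized) exposure and
#' `zeta_y` with the (standardized) outcome, the outcome regression is
#' re-fit with `U` added to the adjustment set, and the exposure
#' coefficient is recorded (averaged over `n_draws` draws).  The
#' robustness parameters are read off the `x = y` diagonal by linear
#' interpolation: `tau1` where the estimate crosses 0 and `tau2` where
#' two-sided significance is lost (`p > alpha`).  `tau2` is reported only
#' when the unperturbed estimate is significant; `tau2 <= tau1` whenever
#' both exist.  The zero-confounding corner reproduces the unperturbed
#' estimate exactly.
#'
#' @param outcome,exposure Numeric vectors.
#' @param covariates data.frame/matrix of measured covariates.
#' @param grid Increasing lattice values in `[0, 1]` (default 11 points).
#' @param n_draws Confounder draws per grid point (default 20).
#' @param alpha Significance level for `tau2`.
#' @param weights Optional regression weights (e.g. balancing weights).
#' @return List `estimate` and `p` (grid matrices, treatment axis in
#'   rows), `grid`, `tau1`, `tau2`, `base` (unperturbed one-row fit),
#'   `tau1_censored`, `tau2_censored`.
#' @export
sensitivity_scan <- function(outcome, exposure, covariates,
                             grid = seq(0, 1, length.out = 11),
                             n_draws = 20, alpha = 0.05, weights = NULL) {
  if (length(grid) < 5) warning("sensitivity grid coarser than 5 points")
  y <- as.numeric(scale(outcome))
  t <- as.numeric(scale(exposure))
  x <- standardize(design_matrix(covariates))
  n <- length(y)
  wt <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  fit_coef <- function(extra = NULL) {
    X <- cbind(1, t, x, extra)
    A <- crossprod(X, X * wt)
    beta <- solve(A, crossprod(X, y * wt))
    r <- as.numeric(y - X %*% beta)
    meat <- crossprod(X, X * (wt * r)^2)
    V <- solve(A, t(solve(A, meat)))
    est <- beta[2]
    se <- sqrt(V[2, 2])
    c(est = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
  }
  base <- fit_coef()
  # The confounder's outcome association is signed with the baseline
  # estimate, so that increasing confounding attenuates the estimate
  # toward (and past) zero rather than inflating it.
  s0 <- if (base[["est"]] < 0) -1 else 1
  r_ty <- stats::cor(t, y)
  est_m <- matrix(NA_real_, length(grid), length(grid),
                  dimnames = list(paste0("zt_", grid), paste0("zy_", grid)))
  p_m <- est_m
  se_m <- est_m
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      zt <- grid[i]
      zy <- grid[j] * s0
      if (zt == 0 && zy == 0) {
        est_m[i, j] <- base[["est"]]
        se_m[i, j] <- base[["se"]]
        p_m[i, j] <- base[["p"]]
        next
      }
      a <- (zt - zy * r_ty) / (1 - r_ty^2)
      b <- (zy - zt * r_ty) / (1 - r_ty^2)
      c2 <- 1 - (a^2 + b^2 + 2 * a * b * r_ty)
      # floor the noise share so U never exactly duplicates a regressor
      cc <- sqrt(max(c2, 1e-4))
      draws <- vapply(seq_len(n_draws), function(k) {
        u <- a * t + b * y + cc * stats::rnorm(n)
        tryCatch(fit_coef(u),
                 error = function(e) c(est = NA_real_, se = NA_real_,
                                       p = NA_real_))
      }, numeric(3))
      est_m[i, j] <- mean(draws["est", ], na.rm = TRUE)
      se_m[i, j] <- mean(draws["se", ], na.rm = TRUE)
      p_m[i, j] <- mean(draws["p", ], na.rm = TRUE)
    }
  }
  diag_est <- diag(est_m)
  diag_p <- diag(p_m)
  cross <- function(vals, level) {
    s <- vals - level
    for (k in seq_len(length(s) - 1)) {
      if (s[k] == 0) return(grid[k])
      if (s[k] * s[k + 1] < 0) {
        return(grid[k] + (grid[k + 1] - grid[k]) *
                 abs(s[k]) / (abs(s[k]) + abs(s[k + 1])))
      }
    }
    NA_real_
  }
  tau1 <- if (abs(base[["est"]]) < .Machine$double.eps) 0 else {
    cross(s0 * diag_est, 0)
  }
  tau1_cens <- is.na(tau1)
  if (tau1_cens) tau1 <- max(grid)
  if (base[["p"]] < alpha) {
    # tau2: loss of significance of the ORIGINAL-sign effect, read from
    # the signed z statistic falling through the two-sided critical
    # value (a narrow two-sided p dip can fall between grid points).
    z_crit <- stats::qnorm(1 - alpha / 2)
    diag_z <- s0 * diag_est / diag(se_m)
    tau2 <- if (diag_z[1] < z_crit) 0 else cross(diag_z, z_crit)
    tau2_cens <- is.na(tau2)
    if (tau2_cens) tau2 <- max(grid)
  } else {
    tau2 <- NA_real_
    tau2_cens <- FALSE
  }
  list(estimate = est_m, p = p_m, grid = grid, tau1 = tau1, tau2 = tau2,
       tau1_censored = tau1_cens, tau2_censored = tau2_cens,
       base = base)
}
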