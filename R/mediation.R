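# Causal pipeline, part 2: natural-effects mediation with a joint
# mediator complex, via counterfactual data expansion and weighted
# regression (the expanded-data estimator of natural effect models with
# density-ratio / inverse-probability weights).

#' Mediation analysis design
#'
#' Declares the causal structure exposure -> joint mediators -> outcome
#' with a covariate adjustment set, optional extra controls and a group
#' (disease-status) control.  Exposure, mediators and outcomes must be
#' disjoint.
#'
#' @param exposure Exposure column (default `"cortisol_suppression"`).
#' @param mediators Joint mediator columns (default the four-component
#'   complex HOMA-IR, hs-CRP, GGT, hypoxanthine).
#' @param outcomes Outcome columns.
#' @param covariates Adjustment covariates.
#' @param extra_controls Additional controls (e.g. urinary
#'   catecholamines, DHEA) appended to the adjustment set when present.
#' @param group_control Group column controlled for population-level
#'   estimates (`NULL` to disable).
#' @return Object of class `mediation_design`.
#' @export
mediation_design <- function(exposure = "cortisol_suppression",
                             mediators = c("homa_ir", "hs_crp", "ggt",
                                           "hypoxanthine"),
                             outcomes = character(),
                             covariates = character(),
                             extra_controls = character(),
                             group_control = "group") {
  if (exposure %in% mediators || exposure %in% outcomes ||
      length(intersect(mediators, outcomes))) {
    stop("exposure, mediators and outcomes must be disjoint",
         call. = FALSE)
  }
  structure(list(exposure = exposure, mediators = mediators,
                 outcomes = outcomes, covariates = covariates,
                 extra_controls = extra_controls,
                 group_control = group_control),
            class = "mediation_design")
}

design_covariate_df <- function(design, d) {
  cols <- c(design$covariates, design$extra_controls)
  cov_df <- d[, intersect(cols, names(d)), drop = FALSE]
  if (!is.null(design$group_control) &&
      design$group_control %in% names(d)) {
    cov_df[[design$group_control]] <- d[[design$group_control]]
  }
  cov_df
}

#' Expand a cohort over hypothetical exposure levels
#'
#' Implements the data expansion of natural effect models: every sample
#' is replicated once per shift in `shifts`, carrying the pair
#' (actual exposure `exposure_actual`, hypothetical exposure
#' `exposure_hyp = actual + shift`).  Row weights combine
#' \itemize{
#'   \item a mediator density ratio
#'     `f(M_i | exposure_hyp, X_i) / f(M_i | actual, X_i)` (Gaussian
#'     linear working models, working independence across the joint
#'     mediator complex), which transports the observed outcome to the
#'     counterfactual mediator level, and
#'   \item a stabilized inverse-probability factor
#'     `f(T_i) / f(T_i | X_i)` from a Gaussian linear conditional
#'     exposure-density model, giving population-level estimates.
#' }
#' Weights are truncated at the stated percentiles and the truncation is
#' logged in the `truncation` attribute.
#'
#' @param design A [mediation_design()].
#' @param data A [cohort_table()] or data.frame on the analysis (log)
#'   scale.
#' @param shifts Hypothetical exposure shifts (default `c(0, 0.01)`: the
#'   observed level and a 1% log-scale increase).
#' @param truncate Weight truncation quantiles (default 1st/99th).
#' @return Expanded data.frame with attributes `design` and
#'   `truncation`.
#' @export
expand_counterfactuals <- function(design, data, shifts = c(0, 0.01),
                                   truncate = c(0.01, 0.99)) {
  stopifnot(inherits(design, "mediation_design"))
  d <- as.data.frame(data)
  need <- c(design$exposure, design$mediators, design$covariates)
  cc <- stats::complete.cases(d[, intersect(need, names(d)), drop = FALSE])
  d <- d[cc, , drop = FALSE]
  n <- nrow(d)
  tt <- d[[design$exposure]]
  x <- standardize(design_matrix(design_covariate_df(design, d)))
  xdf <- as.data.frame(x)
  # conditional exposure density (Gaussian linear in covariates)
  efit <- stats::lm(tt ~ ., data = xdf)
  mu_t <- stats::fitted(efit)
  sd_t <- sqrt(sum(stats::resid(efit)^2) / efit$df.residual)
  sw <- stats::dnorm(tt, mean(tt), stats::sd(tt)) /
    stats::dnorm(tt, mu_t, sd_t)
  # mediator working models (Gaussian linear, independence working
  # assumption within the joint complex)
  med_fits <- lapply(design$mediators, function(mk) {
    fit <- stats::lm(d[[mk]] ~ tt + ., data = xdf)
    list(coef_t = stats::coef(fit)[["tt"]],
         fitted = stats::fitted(fit),
         sd = sqrt(sum(stats::resid(fit)^2) / fit$df.residual))
  })
  rows <- lapply(shifts, function(s) {
    out <- d
    out$exposure_actual <- tt
    out$exposure_hyp <- tt + s
    lw <- 0
    for (k in seq_along(med_fits)) {
      mf <- med_fits[[k]]
      mk <- d[[design$mediators[k]]]
      lw <- lw + stats::dnorm(mk, mf$fitted + mf$coef_t * s, mf$sd,
                              log = TRUE) -
        stats::dnorm(mk, mf$fitted, mf$sd, log = TRUE)
    }
    out$.weight <- sw * exp(lw)
    out$.shift <- s
    out
  })
  ex <- do.call(rbind, rows)
  lim <- stats::quantile(ex$.weight, truncate)
  n_trunc <- sum(ex$.weight < lim[1] | ex$.weight > lim[2])
  ex$.weight <- pmin(pmax(ex$.weight, lim[1]), lim[2])
  attr(ex, "design") <- design
  attr(ex, "truncation") <- list(limits = lim, n_truncated = n_trunc)
  ex
}

ne_point_fit <- function(ex, outcome, design, xnames) {
  f <- stats::as.formula(paste(
    "`", outcome, "` ~ exposure_actual + exposure_hyp + ",
    paste(sprintf("`%s`", xnames), collapse = " + "), sep = ""))
  fit <- stats::lm(f, data = ex, weights = ex$.weight)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular natural-effects design; aliased: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  psi_d <- cf[["exposure_actual"]]
  psi_i <- cf[["exposure_hyp"]]
  c(psi_d = psi_d, psi_i = psi_i, psi_t = psi_d + psi_i)
}

#' Fit a natural effect model on an expanded table
#'
#' Weighted regression of the outcome on the exposure pair plus
#' covariates.  The coefficient on the actual exposure (the level the
#' outcome was generated under, i.e. the direct pathway) is the natural
#' direct effect `psi_d`; the coefficient on the hypothetical exposure
#' (which indexes the mediator distribution through the density-ratio
#' weights) is the natural indirect effect `psi_i`; `psi_t = psi_d +
#' psi_i` exactly, on every fit and every bootstrap replicate.
#' Confidence intervals are by nonparametric bootstrap over samples (not
#' expanded rows).
#'
#' @param ex Expanded table from [expand_counterfactuals()].
#' @param outcome Outcome column name.
#' @param boot Bootstrap resamples (default 1000; 0 disables).
#' @return data.frame with rows `psi_d`, `psi_i`, `psi_t`: columns
#'   `component`, `estimate`, `se`, `ci_lo`, `ci_hi`, `p`, `q`.
#' @export
natural_effects_fit <- function(ex, outcome, boot = 1000) {
  design <- attr(ex, "design")
  xnames <- colnames(design_matrix(design_covariate_df(design, ex)))
  xd <- as.data.frame(design_matrix(design_covariate_df(design, ex)))
  ex2 <- cbind(ex[, c(outcome, "exposure_actual", "exposure_hyp",
                      ".weight")], xd)
  est <- ne_point_fit(ex2, outcome, design, xnames)
  # bootstrap clusters are samples, not expanded rows
  key <- if ("sample_id" %in% names(ex)) {
    ex$sample_id
  } else {
    n_shift <- length(unique(ex$.shift))
    rep(seq_len(nrow(ex) / n_shift), times = n_shift)
  }
  bs <- NULL
  if (boot > 0) {
    split_rows <- split(seq_len(nrow(ex2)), key)
    bs <- vapply(seq_len(boot), function(b) {
      take <- sample(length(split_rows), replace = TRUE)
      idx <- unlist(split_rows[take], use.names = FALSE)
      tryCatch(ne_point_fit(ex2[idx, , drop = FALSE], outcome, design,
                            xnames),
               error = function(e) c(psi_d = NA_real_, psi_i = NA_real_,
                                     psi_t = NA_real_))
    }, numeric(3))
  }
  mk_row <- function(nm) {
    e <- est[[nm]]
    if (!is.null(bs)) {
      v <- bs[nm, ]
      v <- v[is.finite(v)]
      se <- stats::sd(v)
      ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      p <- 2 * stats::pnorm(-abs(e / se))
    } else {
      se <- NA_real_
      ci <- c(NA_real_, NA_real_)
      p <- NA_real_
    }
    data.frame(component = nm, estimate = e, se = se, ci_lo = ci[1],
               ci_hi = ci[2], p = p, q = NA_real_,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c("psi_d", "psi_i", "psi_t"), mk_row))
}

#' Joint-mediator natural effects over an outcome panel
#'
#' Expands the cohort once and fits the natural effect model for every
#' outcome with the full mediator complex treated as a single joint
#' indirect pathway; q-values are computed per component across the
#' panel.
#'
#' @param design A [mediation_design()] with non-empty `outcomes`.
#' @param data Cohort data on the analysis (log) scale.
#' @param boot Bootstrap resamples per outcome.
#' @param shifts,truncate Passed to [expand_counterfactuals()].
#' @return data.frame panel: `outcome`, `component`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `p`, `q`.
#' @export
joint_mediation <- function(design, data, boot = 500, shifts = c(0, 0.01),
                            truncate = c(0.01, 0.99)) {
  stopifnot(length(design$outcomes) > 0)
  ex <- expand_counterfactuals(design, data, shifts = shifts,
                               truncate = truncate)
  panel <- do.call(rbind, lapply(design$outcomes, function(o) {
    r <- natural_effects_fit(ex, o, boot = boot)
    cbind(data.frame(outcome = o, stringsAsFactors = FALSE), r)
  }))
  for (comp in unique(panel$component)) {
    i <- panel$component == comp
    if (!anyNA(panel$p[i])) panel$q[i] <- adjust_fdr(panel$p[i])
  }
  rownames(panel) <- NULL
  panel
}
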