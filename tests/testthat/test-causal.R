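test_that("balancing weights satisfy and report their contract", {
  set.seed(101)
  n <- 500
  covs <- data.frame(a = rnorm(n), b = rnorm(n),
                     f = sample(c("x", "y", "z"), n, TRUE))
  e <- rnorm(n)
  w <- balancing_weights(e, covs)
  expect_equal(sum(w$weights), n)
  expect_true(all(w$weights > 0))
  # independence: weights near uniform, correlations near zero
  expect_gt(w$effective_sample_size, 0.9 * n)
  expect_lt(max(abs(w$balance_report)), 1e-6)
  # the balance report is externally auditable from the weights
  x <- gcmet:::standardize(gcmet:::design_matrix(covs))
  es <- as.numeric(scale(e))
  audit <- apply(x, 2, function(col) {
    ww <- w$weights
    ma <- sum(ww * col) / sum(ww)
    mb <- sum(ww * es) / sum(ww)
    sum(ww * (col - ma) * (es - mb)) /
      sqrt(sum(ww * (col - ma)^2) * sum(ww * (es - mb)^2))
  })
  expect_equal(unname(audit), unname(w$balance_report),
               tolerance = 1e-10)
})

test_that("collinear exposure-covariate designs are rejected", {
  set.seed(5)
  e <- rnorm(100)
  expect_error(balancing_weights(e, data.frame(c1 = e)), "infeasible")
  expect_error(balancing_weights(rep(1, 50), data.frame(a = rnorm(50))),
               "variance")
})

test_that("weighted ACE removes measured confounding", {
  set.seed(202)
  errs <- replicate(6, {
    d <- oracle_ace_dgp(1000, slope = 0.5)
    w <- balancing_weights(d$e, d$z)
    r_w <- average_causal_effect(d$y, d$e, w)
    r_u <- average_causal_effect(d$y, d$e, rep(1, 1000))
    expect_lt(abs(r_w$gamma - 0.5), 4 * r_w$se)
    expect_true(r_w$ci_lo < r_w$gamma && r_w$gamma < r_w$ci_hi)
    c(w = abs(r_w$gamma - 0.5), u = abs(r_u$gamma - 0.5))
  })
  expect_lt(mean(errs["w", ]), mean(errs["u", ]))
})

test_that("ACE bias shrinks with sample size", {
  set.seed(303)
  bias_at <- function(n, reps = 8) {
    mean(replicate(reps, {
      d <- oracle_ace_dgp(n, slope = 0.5)
      w <- balancing_weights(d$e, d$z)
      average_causal_effect(d$y, d$e, w)$gamma - 0.5
    }))
  }
  b <- vapply(c(200, 1000, 5000), bias_at, numeric(1))
  expect_lt(abs(b[3]), 0.03)
  expect_lt(abs(b[3]), abs(b[1]) + 0.03)
})

test_that("ace_panel computes q across outcomes and stores weights", {
  set.seed(41)
  co <- generate_cohort(cohort_config(seed = 41))
  pp <- preprocess(co$table)
  outs <- cohort_roles(pp)$metabolites[1:5]
  res <- ace_panel(pp, outs, "cortisol_suppression")
  expect_equal(nrow(res), 5)
  expect_true(all(!is.na(res$q)))
  expect_s3_class(attr(res, "weights"), "balancing_weights")
})

test_that("sensitivity scan honors its corner, continuity and ordering
           contracts", {
  set.seed(404)
  d <- oracle_ace_dgp(400, slope = 0.5)
  sc <- sensitivity_scan(d$y, d$e, d$z, grid = seq(0, 1, 0.25),
                         n_draws = 6)
  # zero-confounding corner equals the unperturbed estimate exactly
  expect_identical(sc$estimate[1, 1], sc$base[["est"]])
  expect_true(all(is.finite(sc$estimate)))
  # strong effect: attenuation is monotone enough to order tau2 <= tau1
  expect_gt(sc$tau2, 0)
  expect_lte(sc$tau2, sc$tau1)
  # non-significant baseline: tau2 is not reported.  The outcome is
  # orthogonalized against exposure and covariates so the baseline
  # coefficient is exactly zero.
  set.seed(405)
  d0 <- oracle_ace_dgp(200, slope = 0)
  y0 <- stats::resid(stats::lm(d0$y ~ d0$e + as.matrix(d0$z)))
  sc0 <- sensitivity_scan(y0, d0$e, d0$z, grid = seq(0, 1, 0.25),
                          n_draws = 4)
  expect_true(is.na(sc0$tau2))
  expect_warning(sensitivity_scan(d0$y, d0$e, d0$z,
                                  grid = seq(0, 1, 0.5), n_draws = 2),
                 "coarser")
})

test_that("counterfactual expansion replicates samples with positive
           weights", {
  set.seed(55)
  n <- 200
  d <- data.frame(sample_id = seq_len(n), t = rnorm(n),
                  m = rnorm(n), y = rnorm(n), c1 = rnorm(n))
  d$m <- 0.5 * d$t + rnorm(n)
  des <- mediation_design(exposure = "t", mediators = "m",
                          outcomes = "y", covariates = "c1",
                          group_control = NULL)
  ex <- expand_counterfactuals(des, d)
  expect_equal(nrow(ex), 2 * n)
  expect_true(all(is.finite(ex$.weight) & ex$.weight > 0))
  expect_true(!is.null(attr(ex, "truncation")))
  ex3 <- expand_counterfactuals(des, d, shifts = c(-0.01, 0, 0.01))
  expect_equal(nrow(ex3), 3 * n)
  expect_error(mediation_design(exposure = "m", mediators = "m"),
               "disjoint")
})

test_that("natural effects recover the linear SEM decomposition", {
  set.seed(66)
  n <- 1500
  tt <- rnorm(n)
  m <- 0.5 * tt + rnorm(n)
  y <- 0.3 * tt + 0.8 * m + rnorm(n)
  d <- data.frame(sample_id = seq_len(n), t = tt, m = m, y = y,
                  c1 = rnorm(n))
  des <- mediation_design(exposure = "t", mediators = "m",
                          outcomes = "y", covariates = "c1",
                          group_control = NULL)
  ex <- expand_counterfactuals(des, d)
  fit <- natural_effects_fit(ex, "y", boot = 120)
  est <- stats::setNames(fit$estimate, fit$component)
  se <- stats::setNames(fit$se, fit$component)
  expect_lt(abs(est["psi_d"] - 0.3), 3 * se["psi_d"])
  expect_lt(abs(est["psi_i"] - 0.4), 3 * se["psi_i"])
  # the sum rule is exact on every fit
  expect_identical(unname(est["psi_t"]),
                   unname(est["psi_d"] + est["psi_i"]))
})

test_that("a null mediator pathway yields psi_i near zero", {
  set.seed(77)
  n <- 1000
  tt <- rnorm(n)
  m <- 0.5 * tt + rnorm(n)      # mediator responds to exposure
  y <- 0.4 * tt + rnorm(n)      # but the outcome ignores the mediator
  d <- data.frame(sample_id = seq_len(n), t = tt, m = m, y = y,
                  c1 = rnorm(n))
  des <- mediation_design(exposure = "t", mediators = "m",
                          outcomes = "y", covariates = "c1",
                          group_control = NULL)
  fit <- natural_effects_fit(expand_counterfactuals(des, d), "y",
                             boot = 120)
  est <- stats::setNames(fit$estimate, fit$component)
  se <- stats::setNames(fit$se, fit$component)
  expect_lt(abs(est["psi_i"]), 3 * se["psi_i"])
})

test_that("joint mediation panels are bookkept per component", {
  set.seed(88)
  co <- generate_cohort(cohort_config(seed = 88))
  pp <- preprocess(co$table)
  roles <- cohort_roles(pp)
  des <- mediation_design(exposure = roles$exposure,
                          mediators = roles$mediators,
                          outcomes = roles$metabolites[1:3],
                          covariates = roles$covariates)
  panel <- joint_mediation(des, pp, boot = 60)
  expect_equal(nrow(panel), 9)
  expect_setequal(unique(panel$component), c("psi_d", "psi_i", "psi_t"))
  expect_true(all(!is.na(panel$q)))
  sums <- tapply(panel$estimate, panel$outcome, function(v) v[3] -
                   (v[1] + v[2]))
  expect_true(all(abs(sums) < 1e-12))
})
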