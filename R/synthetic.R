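# Synthetic-data generators: two-group cohorts with a linear-Gaussian
# structure on the log scale (covariates -> exposure -> joint mediators
# -> outcomes, plus direct paths and group shifts) whose causal
# estimands have closed forms; signature-shift cohorts for power checks;
# and toy models with closed-form steady states for control-analysis
# oracles.

sig_feature_names <- function() md_signature()$features

#' Synthetic cohort configuration
#'
#' The default configuration emulates the target study design: 83 cases
#' and 82 controls, 8 confounding covariates (age, BMI, education, race,
#' ethnicity, a 10-indicator medication block, smoking, alcohol use), a
#' continuous exposure (cortisol suppression) that loads on the
#' covariates and the group, four mediators (HOMA-IR, hs-CRP, GGT,
#' hypoxanthine) with exposure loadings echoing the reported
#' elasticities, and 35 log-normal metabolite outcomes with direct and
#' mediated exposure effects plus small-to-moderate group shifts
#' (Cohen's d roughly 0.3-0.7).
#'
#' @param n_case,n_control Group sizes (defaults 83 / 82).
#' @param exposure_group_shift Group shift of the exposure (log scale).
#' @param exposure_sd Exposure noise SD.
#' @param mediator_loadings Length-4 exposure->mediator loadings.
#' @param mediator_sd Mediator noise SD.
#' @param direct_effects Length-35 direct exposure->outcome loadings
#'   (`psi_d`); scalar recycled.
#' @param mediator_outcome_loadings 35 x 4 matrix of mediator->outcome
#'   loadings; scalar recycled.
#' @param outcome_sd Outcome noise SD.
#' @param group_d Cohen's d scale of outcome group shifts (signs follow
#'   the MD signature for the first 12 outcomes, alternating afterward).
#' @param confounding Scale of covariate loadings on exposure, mediators
#'   and outcomes (0 disables confounding).
#' @param seed Optional RNG seed applied by the generators (generation is
#'   deterministic given the seed).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 83, n_control = 82, seed = NULL,
                          exposure_group_shift = 0.3, exposure_sd = 0.5,
                          mediator_loadings = c(homa_ir = 0.4,
                                                hs_crp = 1.4,
                                                ggt = 0.32,
                                                hypoxanthine = 0.3),
                          mediator_sd = 0.5,
                          direct_effects = 0.15,
                          mediator_outcome_loadings = 0.12,
                          outcome_sd = 0.5,
                          group_d = 0.5,
                          confounding = 0.15) {
  stopifnot(n_case > 0, n_control > 0, exposure_sd > 0, mediator_sd > 0,
            outcome_sd > 0, length(mediator_loadings) == 4)
  n_out <- 35
  outcomes <- c(sig_feature_names(),
                paste0("met_", seq(13, n_out)))
  sig_signs <- md_signature()$signs
  group_signs <- c(unname(sig_signs), rep_len(c(1, -1), n_out - 12))
  # scalar loadings are expanded with signature-direction signs so the
  # exposure effect is not common-mode across the metabolite panel
  # (common-mode signal would be removed by median normalization)
  if (length(direct_effects) == 1) {
    direct_effects <- direct_effects * group_signs
  }
  if (length(mediator_outcome_loadings) == 1) {
    mediator_outcome_loadings <- matrix(mediator_outcome_loadings,
                                        n_out, 4) * group_signs
  }
  stopifnot(length(direct_effects) == n_out,
            all(dim(mediator_outcome_loadings) == c(n_out, 4)),
            all(is.finite(direct_effects)),
            all(is.finite(mediator_outcome_loadings)))
  structure(list(n_case = n_case, n_control = n_control,
                 exposure_group_shift = exposure_group_shift,
                 exposure_sd = exposure_sd,
                 mediator_loadings = mediator_loadings,
                 mediator_sd = mediator_sd,
                 direct_effects = stats::setNames(direct_effects, outcomes),
                 mediator_outcome_loadings = mediator_outcome_loadings,
                 outcome_sd = outcome_sd, group_d = group_d,
                 group_signs = stats::setNames(group_signs, outcomes),
                 confounding = confounding, outcomes = outcomes,
                 seed = seed),
            class = "cohort_config")
}

# Fixed (non-random) covariate loading pattern, scaled by `scale`.
cov_loadings <- function(p, scale) {
  scale * rep_len(c(0.8, -0.5, 0.3, -0.2, 0.6, -0.4, 0.2, 0.5), p) /
    sqrt(p)
}

generate_covariates <- function(n) {
  data.frame(
    age = stats::rnorm(n, 35, 8),
    bmi = stats::rnorm(n, 27, 4),
    education = sample(1:5, n, replace = TRUE,
                       prob = c(0.1, 0.2, 0.3, 0.25, 0.15)),
    race = sample(paste0("race", 1:4), n, replace = TRUE,
                  prob = c(0.45, 0.3, 0.15, 0.1)),
    ethnicity = sample(paste0("eth", 1:3), n, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)),
    medications = rowSums(matrix(stats::rbinom(n * 10, 1, 0.15), n, 10)),
    smoking = stats::rbinom(n, 1, 0.3),
    alcohol = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort with known causal ground truth
#'
#' Linear-Gaussian data-generating process on the log scale:
#' covariates -> exposure -> mediators -> outcomes, plus direct
#' exposure->outcome paths and group shifts.  The truth report's causal
#' quantities are the closed-form path products of the generating
#' loadings: `psi_d = direct loading`, `psi_i = sum_k b_jk a_k`,
#' `psi_t = psi_d + psi_i` (exact by construction), and the covariate-
#' adjusted total elasticity `gamma = psi_t`.  Metabolite columns are
#' exponentiated (log-normal), so every generated value is strictly
#' positive and [preprocess()] never errors.
#'
#' @param cfg A [cohort_config()].
#' @return List `table` (a [cohort_table()]) and `truth` (a data.frame
#'   `outcome`, `gamma`, `psi_d`, `psi_i`, `psi_t`, `group_direction`).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_case + cfg$n_control
  group <- c(rep("PTSD", cfg$n_case), rep("control", cfg$n_control))
  g <- as.numeric(group == "PTSD")
  covs <- generate_covariates(n)
  z <- standardize(design_matrix(covs))
  bz_e <- cov_loadings(ncol(z), cfg$confounding)
  cs <- as.numeric(z %*% bz_e) + cfg$exposure_group_shift * g +
    stats::rnorm(n, 0, cfg$exposure_sd)
  a <- cfg$mediator_loadings
  med_names <- names(a)
  m <- sapply(seq_along(a), function(k) {
    bz_m <- cov_loadings(ncol(z), cfg$confounding) * (-1)^k
    a[k] * cs + as.numeric(z %*% bz_m) + 0.2 * g +
      stats::rnorm(n, 0, cfg$mediator_sd)
  })
  colnames(m) <- med_names
  b <- cfg$mediator_outcome_loadings
  cdir <- cfg$direct_effects
  logy <- sapply(seq_along(cfg$outcomes), function(j) {
    bz_y <- cov_loadings(ncol(z), cfg$confounding) * (-1)^(j %% 3)
    cdir[j] * cs + as.numeric(m %*% b[j, ]) + as.numeric(z %*% bz_y) +
      cfg$group_d * cfg$group_signs[j] * g +
      stats::rnorm(n, 0, cfg$outcome_sd)
  })
  colnames(logy) <- cfg$outcomes
  d <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                  group = group, covs,
                  cortisol_suppression = exp(cs),
                  exp(m), exp(logy),
                  stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cohort_table(d, metabolites = cfg$outcomes,
                      mediators = med_names,
                      exposure = "cortisol_suppression",
                      covariates = names(covs))
  psi_i <- as.numeric(b %*% a)
  truth <- data.frame(outcome = cfg$outcomes,
                      gamma = unname(cdir) + psi_i,
                      psi_d = unname(cdir), psi_i = psi_i,
                      psi_t = unname(cdir) + psi_i,
                      group_direction = unname(cfg$group_signs),
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Generate a cohort with injected signature-direction group shifts
#'
#' Log-normal features with a group mean shift of `effect_size` standard
#' deviations in the signature's direction for every signature feature;
#' used to verify end-to-end that the group-difference pipeline recovers
#' the injected directions.
#'
#' @param cfg A [cohort_config()] (group sizes are taken from it).
#' @param signature An [md_signature()].
#' @param effect_size Cohen's d of the injected shift (log scale).
#' @return A [cohort_table()].
#' @export
generate_md_cohort <- function(cfg = cohort_config(),
                               signature = md_signature(),
                               effect_size = 0.5) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_case + cfg$n_control
  group <- c(rep("PTSD", cfg$n_case), rep("control", cfg$n_control))
  g <- as.numeric(group == "PTSD")
  x <- sapply(signature$features, function(f) {
    exp(stats::rnorm(n, 0, 1) + effect_size * signature$signs[[f]] * g)
  })
  d <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                  group = group, x, stringsAsFactors = FALSE,
                  check.names = FALSE)
  cohort_table(d, metabolites = signature$features)
}

#' Toy models with closed-form steady states
#'
#' Small model instances used as analytic oracles for the control
#' analysis:
#' \describe{
#'   \item{linear_chain}{constant source `v_in` feeding `s1 -> s2 -> s3`
#'     with first-order steps `k1, k2, k3`; steady state
#'     `s_j = v_in / k_j`, so the concentration response of `s3` to
#'     `v_in` is exactly +1 at any fold and to `k3` exactly `-1/fold`.}
#'   \item{feedback_loop}{stress-driven hormone `h` under Hill negative
#'     feedback from its product `c` (the central-feedback motif);
#'     raising the Hill exponent `n_fb` flattens the steady response of
#'     `c` to the clamped input.}
#'   \item{clamp_demo}{a clamped glycogen-like store feeding a single
#'     pool; the clamped species' derivative is 0 under any
#'     perturbation.}
#' }
#'
#' @param kind One of `"linear_chain"`, `"feedback_loop"`,
#'   `"clamp_demo"`.
#' @return A [model_spec()].
#' @export
generate_toy_model <- function(kind = c("linear_chain", "feedback_loop",
                                        "clamp_demo")) {
  kind <- match.arg(kind)
  comp <- data.frame(id = "cell", volume = 1, stringsAsFactors = FALSE)
  spdf <- function(ids, init = 1) {
    data.frame(id = ids, compartment = "cell", initial = init,
               role = "metabolite", stringsAsFactors = FALSE)
  }
  switch(kind,
    linear_chain = model_spec(
      species = spdf(c("s1", "s2", "s3")),
      compartments = comp,
      reactions = list(
        rxn("src", "v_in", c(s1 = 1)),
        rxn("step1", "k1", c(s1 = -1, s2 = 1), list(sub("s1")),
            law = "mass_action"),
        rxn("step2", "k2", c(s2 = -1, s3 = 1), list(sub("s2")),
            law = "mass_action"),
        rxn("step3", "k3", c(s3 = -1), list(sub("s3")),
            law = "mass_action")
      ),
      parameters = c(v_in = 2, k1 = 1, k2 = 0.8, k3 = 0.5)),
    feedback_loop = model_spec(
      species = rbind(spdf("u"), spdf(c("h", "c"))),
      compartments = comp,
      reactions = list(
        rxn("h_prod", "v_h", c(h = 1),
            regulators = list(
              act("u", "K_u"),
              deact("c", "K_fb", n = "n_fb"))),
        rxn("h_deg", "kd_h", c(h = -1), list(sub("h")),
            law = "mass_action"),
        rxn("c_prod", "k_hc", c(c = 1), list(sub("h")),
            law = "mass_action"),
        rxn("c_deg", "kd_c", c(c = -1), list(sub("c")),
            law = "mass_action")
      ),
      parameters = c(v_h = 2, K_u = 1, K_fb = 1, n_fb = 2, kd_h = 1,
                     k_hc = 1, kd_c = 1),
      clamps = "u"),
    clamp_demo = model_spec(
      species = rbind(spdf("store"), spdf("pool")),
      compartments = comp,
      reactions = list(
        rxn("release", "k_rel", c(pool = 1), list(sub("store")),
            law = "mass_action"),
        rxn("use", "k_use", c(pool = -1), list(sub("pool")),
            law = "mass_action")
      ),
      parameters = c(k_rel = 1, k_use = 0.5),
      clamps = "store"))
}
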