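# Metabolic control analysis: finite-perturbation metabolite
# concentration response coefficients (MCRCs), parameter screening
# against the metabolic-dysfunction signature, signature direction
# matching, and the trichotomized regulatory-state matrix.

#' Metabolic-dysfunction signature
#'
#' Ordered feature list with direction-of-change signs for the PTSD-like
#' metabolic-dysfunction pattern.  The 12-feature core covers glucose,
#' pyruvate, lactate, citrate, alanine, glutamine, long-chain fatty acids,
#' triglycerides, carnitines, arginine, ornithine and insulin; the
#' 16-feature extension adds IL-6, TNF, ACTH and cortisol (all increased).
#'
#' Default signs: pyruvate, lactate, alanine, ornithine, triglycerides and
#' carnitines increased; citrate, arginine and fatty acids decreased.
#' The glucose, glutamine and insulin directions are not pinned down by
#' the core pattern and default to increased (gluconeognesis up,
#' proteolysis up, compensatory hyperinsulinemia); they can be overridden
#' via `signs`.
#'
#' @param extended Include the 4 neuroendocrine/cytokine features.
#' @param signs Optional named numeric (+1/-1) overriding default signs.
#' @return Object of class `md_signature` with `features`, `signs`,
#'   `core_12`, `extended_16`.
#' @export
md_signature <- function(extended = FALSE, signs = NULL) {
  core <- c(glucose = +1, pyruvate = +1, lactate = +1, citrate = -1,
            alanine = +1, glutamine = +1, fatty_acids = -1,
            triglycerides = +1, carnitines = +1, arginine = -1,
            ornithine = +1, insulin = +1)
  ext <- c(il6 = +1, tnf = +1, acth = +1, cortisol = +1)
  s <- if (extended) c(core, ext) else core
  if (!is.null(signs)) {
    bad <- setdiff(names(signs), names(s))
    if (length(bad)) stop("unknown signature feature '", bad[1], "'",
                          call. = FALSE)
    s[names(signs)] <- signs
  }
  if (!all(s %in% c(-1, 1))) {
    stop("signature signs must be +1 or -1", call. = FALSE)
  }
  structure(list(features = names(s), signs = s,
                 core_12 = names(core), extended_16 = c(names(core),
                                                        names(ext))),
            class = "md_signature")
}

#' Construct a custom direction-of-change signature
#'
#' Generalization of [md_signature()] to arbitrary feature sets, mainly
#' for screening and matching on user or toy models.
#'
#' @param signs Named numeric vector of +1/-1 expected directions.
#' @return Object of class `md_signature`.
#' @export
signature_spec <- function(signs) {
  if (is.null(names(signs)) || !all(signs %in% c(-1, 1))) {
    stop("`signs` must be a named vector of +1/-1", call. = FALSE)
  }
  structure(list(features = names(signs), signs = signs,
                 core_12 = NULL, extended_16 = NULL),
            class = "md_signature")
}

steady_or_null <- function(m, initial = NULL, tol = 1e-6) {
  ss <- tryCatch(find_steady_state(m, initial = initial, tol = tol),
                 error = function(e) NULL)
  if (is.null(ss) || !ss$converged) NULL else ss
}

#' Metabolite concentration response coefficient
#'
#' Finite-perturbation normalized sensitivity of a steady-state
#' concentration to a parameter:
#' `MCRC = [(C(fold * P) - C(P)) / ((fold - 1) * P)] * [P / C(P)]`,
#' evaluated between the baseline steady state and the steady state with
#' the parameter scaled by `fold`.  Clamps declared in the model (e.g.
#' glycogen) are honoured in both solves.
#'
#' @param m A [model_spec()].
#' @param param Parameter name (a character vector perturbs jointly).
#' @param metabolite Species id (or vector of ids).
#' @param fold Positive fold factor, different from 1.
#' @param baseline Optional precomputed baseline `steady_state`.
#' @return Named coefficient vector over `metabolite`; `NA` with a warning
#'   when the perturbed steady state fails to converge (never a silent
#'   zero).
#' @export
mcrc <- function(m, param, metabolite, fold, baseline = NULL) {
  stopifnot(fold > 0, fold != 1)
  if (is.null(baseline)) baseline <- find_steady_state(m)
  if (!baseline$converged) {
    stop("baseline steady state did not converge (residual ",
         format(baseline$residual_norm, digits = 3), ")", call. = FALSE)
  }
  c0 <- baseline$concentrations[metabolite]
  ss <- steady_or_null(perturb_parameters(m, param, fold),
                       initial = baseline$concentrations)
  if (is.null(ss)) {
    warning("perturbed steady state for '", paste(param, collapse = "+"),
            "' at fold ", fold, " did not converge; MCRC flagged NA")
    return(stats::setNames(rep(NA_real_, length(metabolite)), metabolite))
  }
  c1 <- ss$concentrations[metabolite]
  stats::setNames((c1 - c0) / (c0 * (fold - 1)), metabolite)
}

#' Scan MCRCs over a parameter list
#'
#' Computes the full parameter-by-metabolite coefficient matrices at the
#' decreasing (`folds[1]`, default 0.5) and increasing (`folds[2]`,
#' default 1.5) perturbations plus their elementwise mean (the net
#' coefficient).  The scan order is deterministic; per-entry convergence
#' failures are collected in the `failures` report and surface as `NA`
#' rows, never as zeros.  A partial result can be passed back in to
#' resume.
#'
#' @param m A [model_spec()].
#' @param params Character vector of parameter names.
#' @param signature An [md_signature()] or character vector of species ids.
#' @param folds Length-2 perturbation folds.
#' @param partial Optional previous `mcrc_matrix` to resume from.
#' @param verbose Log scan progress.
#' @return Object of class `mcrc_matrix`: `params`, `metabolites`,
#'   `coeff_down`, `coeff_up`, `coeff_net`, `baseline`, `failures`.
#' @export
mca_scan <- function(m, params, signature, folds = c(0.5, 1.5),
                     partial = NULL, verbose = FALSE) {
  mets <- if (inherits(signature, "md_signature")) {
    signature$features
  } else {
    as.character(signature)
  }
  missing <- setdiff(mets, m$species$id)
  if (length(missing)) {
    stop("unresolved reference: signature species '", missing[1], "'",
         call. = FALSE)
  }
  baseline <- find_steady_state(m)
  down <- matrix(NA_real_, length(params), length(mets),
                 dimnames = list(params, mets))
  up <- down
  done <- character()
  if (!is.null(partial)) {
    keep <- intersect(partial$params, params)
    down[keep, ] <- partial$coeff_down[keep, mets]
    up[keep, ] <- partial$coeff_up[keep, mets]
    done <- keep
  }
  failures <- list()
  for (p in setdiff(params, done)) {
    if (verbose) message("mca_scan: ", p)
    d <- mcrc(m, p, mets, folds[1], baseline = baseline)
    u <- mcrc(m, p, mets, folds[2], baseline = baseline)
    if (anyNA(d) || anyNA(u)) failures[[p]] <- "non-convergent perturbation"
    down[p, ] <- d
    up[p, ] <- u
  }
  structure(list(params = params, metabolites = mets,
                 coeff_down = down, coeff_up = up,
                 coeff_net = (down + up) / 2,
                 baseline = baseline, failures = failures),
            class = "mcrc_matrix")
}

#' Screen parameters by signature-wide response magnitude
#'
#' Keeps the parameters whose net (mean-over-folds) coefficient has
#' magnitude at least `per_metabolite_min` for *every* signature feature
#' and whose cumulative magnitude (sum of `|net MCRC|` over the features)
#' is at least `cumulative_min`; ranks the kept set by cumulative
#' magnitude, descending.  Parameters with missing entries (failed
#' perturbations) are excluded with a warning.
#'
#' @param mm An `mcrc_matrix` from [mca_scan()].
#' @param per_metabolite_min Per-feature magnitude threshold
#'   (default 0.001).
#' @param cumulative_min Cumulative magnitude threshold (default 0.1).
#' @return data.frame `param`, `cumulative`, `rank` (kept set only).
#' @export
screen_parameters <- function(mm, per_metabolite_min = 0.001,
                              cumulative_min = 0.1) {
  stopifnot(inherits(mm, "mcrc_matrix"))
  net <- abs(mm$coeff_net)
  incomplete <- rownames(net)[apply(net, 1, anyNA)]
  if (length(incomplete)) {
    warning("excluding parameters with missing MCRC entries: ",
            paste(incomplete, collapse = ", "))
  }
  ok <- !apply(net, 1, anyNA)
  keep <- ok & apply(net, 1, function(r) all(r >= per_metabolite_min)) &
    rowSums(net) >= cumulative_min
  kept <- rownames(net)[keep]
  cum <- rowSums(net)[kept]
  ord <- order(cum, decreasing = TRUE)
  data.frame(param = kept[ord], cumulative = unname(cum[ord]),
             rank = seq_along(kept), stringsAsFactors = FALSE)
}

#' Match a perturbation against the signature directions
#'
#' Perturbs `param` by `fold`, re-solves the steady state and compares the
#' sign of the relative concentration change of every signature feature
#' with the expected sign.  Changes below `rel_tol` in magnitude count as
#' "no change" and mismatch any +/- expectation.
#'
#' @param m A [model_spec()].
#' @param param Parameter name(s); vectors are perturbed jointly.
#' @param fold Perturbation fold.
#' @param signature An [md_signature()].
#' @param rel_tol Relative no-change threshold (default 1%).
#' @param baseline Optional precomputed baseline steady state.
#' @return List `match` (logical), `per_feature_signs` (named character),
#'   `mismatches` (character vector of feature ids).
#' @export
match_signature <- function(m, param, fold, signature, rel_tol = 0.01,
                            baseline = NULL) {
  stopifnot(inherits(signature, "md_signature"))
  if (is.null(baseline)) baseline <- find_steady_state(m)
  b <- baseline$concentrations
  ss <- steady_or_null(perturb_parameters(m, param, fold), initial = b)
  if (is.null(ss)) {
    stop("perturbed steady state did not converge for '",
         paste(param, collapse = "+"), "'", call. = FALSE)
  }
  feats <- signature$features
  obs <- change_direction(ss$concentrations[feats], b[feats], rel_tol)
  expd <- ifelse(signature$signs > 0, "+", "-")
  mismatch <- feats[obs != expd]
  list(match = length(mismatch) == 0,
       per_feature_signs = stats::setNames(obs, feats),
       mismatches = mismatch)
}

#' Regulatory-state matrix under matched perturbations
#'
#' For each perturbation (possibly joint parameter sets), trichotomizes
#' the steady-state change of every requested component as `"increased"`,
#' `"decreased"` or `"small"` at a 1% relative-change threshold.
#' Components may be species ids or the derived ratios `atp_adp`,
#' `nadh_nad`, `glycolytic_ratio`, `gabr`, which are recomputed from the
#' perturbed steady state.
#'
#' @param m A [model_spec()].
#' @param matched_params List of parameter names (elements may be
#'   character vectors for joint perturbation).
#' @param components Character vector of species ids / derived ratio
#'   names.
#' @param fold Perturbation fold (default 1.5).
#' @param rel_tol Trichotomy threshold (default 1%).
#' @return Character matrix (perturbations x components) of state labels.
#' @export
regulatory_state_matrix <- function(m, matched_params, components,
                                    fold = 1.5, rel_tol = 0.01) {
  if (!is.list(matched_params)) matched_params <- as.list(matched_params)
  baseline <- find_steady_state(m)
  ratio_names <- c("atp_adp", "nadh_nad", "glycolytic_ratio", "gabr")
  comp_value <- function(ss, comp) {
    if (comp %in% ratio_names) {
      ss$derived_ratios[[comp]]
    } else {
      ss$concentrations[[comp]]
    }
  }
  bad <- setdiff(components, c(ratio_names, m$species$id))
  if (length(bad)) {
    stop("unresolved reference: component '", bad[1], "'", call. = FALSE)
  }
  labs <- vapply(matched_params, paste, character(1), collapse = "+")
  out <- matrix(NA_character_, length(matched_params), length(components),
                dimnames = list(labs, components))
  for (i in seq_along(matched_params)) {
    ss <- steady_or_null(perturb_parameters(m, matched_params[[i]], fold),
                         initial = baseline$concentrations)
    if (is.null(ss)) {
      warning("non-convergent perturbation '", labs[i],
              "'; row left missing")
      next
    }
    for (j in seq_along(components)) {
      b <- comp_value(baseline, components[j])
      v <- comp_value(ss, components[j])
      d <- (v - b) / abs(b)
      out[i, j] <- if (abs(d) < rel_tol) "small" else if (d > 0) {
        "increased"
      } else {
        "decreased"
      }
    }
  }
  out
}

#' Write an MCRC matrix to tidy CSV
#'
#' One row per (param, metabolite) pair with the down-fold, up-fold and
#' net coefficients.
#'
#' @param mm An `mcrc_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mcrc_csv <- function(mm, path) {
  stopifnot(inherits(mm, "mcrc_matrix"))
  grid <- expand.grid(param = mm$params, metabolite = mm$metabolites,
                      stringsAsFactors = FALSE)
  grid$coeff_down <- mm$coeff_down[cbind(grid$param, grid$metabolite)]
  grid$coeff_up <- mm$coeff_up[cbind(grid$param, grid$metabolite)]
  grid$coeff_net <- mm$coeff_net[cbind(grid$param, grid$metabolite)]
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
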