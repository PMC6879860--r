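# End-to-end analysis pipeline: synthetic cohort -> preprocessing ->
# group differences -> correlation maps with fold-change capping -> ACE
# panel -> joint mediation, with tidy CSV outputs and a forest plot of
# the joint-mediated effects.

#' Run the full cohort analysis pipeline
#'
#' Generates (or accepts) a cohort, preprocesses it (log + per-sample
#' median normalization), computes group differences with q-values,
#' Spearman correlation maps for all samples / cases / controls with the
#' between-group fold change capped at `cap`, the balancing-weight ACE
#' panel of the exposure on every metabolite, and the joint-mediator
#' natural-effects panel; writes tidy CSVs (and a forest plot PDF of the
#' indirect effects) under `out_dir`.  All randomness is governed by
#' `seed`, so outputs are reproducible.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param cohort Optional list `(table, truth)` as returned by
#'   [generate_cohort()]; generated from `cfg` when `NULL`.
#' @param cfg A [cohort_config()] used when `cohort` is `NULL`.
#' @param boot Bootstrap resamples for the mediation panel.
#' @param cap Correlation fold-change cap.
#' @param plot Write the forest-plot PDF.
#' @return Invisible list with the computed tables and output paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, cohort = NULL,
                         cfg = cohort_config(), boot = 200, cap = 4,
                         plot = TRUE) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- generate_cohort(cfg)
  }
  tab <- cohort$table
  roles <- cohort_roles(tab)
  pp <- preprocess(tab)
  gd <- group_difference_panel(pp)
  components <- c(roles$exposure, roles$mediators)
  mets <- roles$metabolites
  cm_all <- correlation_map(pp, components, mets, subset = "all")
  cm_case <- correlation_map(pp, components, mets,
                             subset = levels(pp$group)[1])
  cm_ctrl <- correlation_map(pp, components, mets,
                             subset = levels(pp$group)[2])
  fc <- correlation_fold_change(cm_case$rho, cm_ctrl$rho, cap = cap)
  ace <- ace_panel(pp, outcomes = mets, exposure = roles$exposure)
  design <- mediation_design(exposure = roles$exposure,
                             mediators = roles$mediators,
                             outcomes = mets,
                             covariates = roles$covariates)
  med <- joint_mediation(design, pp, boot = boot)
  paths <- list(
    group_differences = file.path(out_dir, "group_differences.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    correlation_fold_change = file.path(out_dir,
                                        "correlation_fold_change.csv"),
    ace = file.path(out_dir, "ace_panel.csv"),
    mediation = file.path(out_dir, "mediation_panel.csv")
  )
  utils::write.csv(gd, paths$group_differences, row.names = FALSE)
  tidy_corr <- function(cm, subset) {
    g <- expand.grid(component = rownames(cm$rho),
                     metabolite = colnames(cm$rho),
                     stringsAsFactors = FALSE)
    g$subset <- subset
    g$rho <- cm$rho[cbind(g$component, g$metabolite)]
    g$p <- cm$p[cbind(g$component, g$metabolite)]
    g$significant <- cm$significant[cbind(g$component, g$metabolite)]
    g
  }
  utils::write.csv(rbind(tidy_corr(cm_all, "all"),
                         tidy_corr(cm_case, "case"),
                         tidy_corr(cm_ctrl, "control")),
                   paths$correlations, row.names = FALSE)
  gfc <- expand.grid(component = rownames(fc$fold),
                     metabolite = colnames(fc$fold),
                     stringsAsFactors = FALSE)
  gfc$fold <- fc$fold[cbind(gfc$component, gfc$metabolite)]
  gfc$sign_flip <- fc$sign_flip[cbind(gfc$component, gfc$metabolite)]
  utils::write.csv(gfc, paths$correlation_fold_change, row.names = FALSE)
  utils::write.csv(ace, paths$ace, row.names = FALSE)
  utils::write.csv(med, paths$mediation, row.names = FALSE)
  if (plot) {
    paths$forest <- file.path(out_dir, "mediation_forest.pdf")
    nie <- med[med$component == "psi_i", ]
    grDevices::pdf(paths$forest, width = 6,
                   height = 2 + 0.18 * nrow(nie))
    op <- graphics::par(mar = c(4, 9, 2, 1))
    yy <- rev(seq_len(nrow(nie)))
    graphics::plot(nie$estimate, yy, xlim = range(c(nie$ci_lo, nie$ci_hi),
                                                  na.rm = TRUE),
                   pch = 16, yaxt = "n", xlab = "joint NIE (psi_i)",
                   ylab = "", main = "Joint-mediated effects")
    graphics::segments(nie$ci_lo, yy, nie$ci_hi, yy)
    graphics::abline(v = 0, lty = 2)
    graphics::axis(2, at = yy, labels = nie$outcome, las = 2,
                   cex.axis = 0.6)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(list(table = tab, preprocessed = pp, group_differences = gd,
                 correlations = list(all = cm_all, case = cm_case,
                                     control = cm_ctrl),
                 fold_change = fc, ace = ace, mediation = med,
                 truth = cohort$truth, paths = paths))
}
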