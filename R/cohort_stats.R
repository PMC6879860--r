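# Cohort statistics: preprocessing (log + median normalization), group
# differences (Mann-Whitney with exact small-sample enumeration, Storey
# q-values, Cohen's d), Spearman correlation maps, and between-group
# correlation fold changes with capping.

#' Construct a cohort feature table
#'
#' A thin wrapper around a data.frame of samples x features with role
#' annotations.  `sample_id` must be unique and `group` two-level (case
#' level first in `levels`).
#'
#' @param data data.frame with `sample_id`, `group` and numeric feature
#'   columns.
#' @param metabolites,mediators,covariates Character vectors of column
#'   names by role.
#' @param exposure Exposure column name (continuous), or `NULL`.
#' @param levels Length-2 group levels, case first (default
#'   `c("PTSD", "control")`).
#' @return Object of class `cohort_table` (a data.frame with attributes
#'   `roles` and `provenance`).
#' @export
cohort_table <- function(data, metabolites = character(),
                         mediators = character(), exposure = NULL,
                         covariates = character(),
                         levels = c("PTSD", "control")) {
  stopifnot(is.data.frame(data), "sample_id" %in% names(data),
            "group" %in% names(data))
  if (anyDuplicated(data$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (!all(data$group %in% levels)) {
    stop("group labels outside {", paste(levels, collapse = ", "), "}",
         call. = FALSE)
  }
  cols <- c(metabolites, mediators, exposure, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("missing feature column '", missing[1], "'", call. = FALSE)
  }
  data$group <- factor(data$group, levels = levels)
  structure(data,
            roles = list(metabolites = metabolites, mediators = mediators,
                         exposure = exposure, covariates = covariates),
            provenance = character(),
            class = c("cohort_table", "data.frame"))
}

#' Feature roles of a cohort table
#'
#' @param t A [cohort_table()].
#' @return Named list `metabolites`, `mediators`, `exposure`,
#'   `covariates`.
#' @export
cohort_roles <- function(t) attr(t, "roles")

#' Log-transform and median-normalize a cohort table
#'
#' Features are natural-log transformed, then median-normalized:
#' by default each sample's log values are centered by that sample's
#' median over the metabolite features (per-sample centering, the common
#' metabolomics batch practice); `method = "per_feature"` centers each
#' feature by its own median instead.  Missing values are preserved;
#' non-positive values raise an error naming the feature and samples.
#' The applied steps are appended to the table's provenance, and the
#' operation is idempotent on already-centered data in the sense that
#' re-centering centered data leaves it unchanged.
#'
#' @param t A [cohort_table()].
#' @param features Columns to transform (default: metabolite role plus
#'   mediators and exposure).
#' @param center_features Columns whose per-sample median defines the
#'   centering offset (default: the metabolite features).
#' @param method `"per_sample"` or `"per_feature"`.
#' @param log_transform Apply the log first (set `FALSE` for data already
#'   on the log scale).
#' @return The preprocessed `cohort_table`.
#' @export
preprocess <- function(t, features = NULL, center_features = NULL,
                       method = c("per_sample", "per_feature"),
                       log_transform = TRUE) {
  method <- match.arg(method)
  roles <- cohort_roles(t)
  if (is.null(features)) {
    features <- unique(c(roles$metabolites, roles$mediators,
                         roles$exposure))
  }
  if (is.null(center_features)) {
    center_features <- if (length(roles$metabolites)) {
      roles$metabolites
    } else {
      features
    }
  }
  x <- as.matrix(as.data.frame(t)[, features, drop = FALSE])
  if (log_transform) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      j <- bad[1, 2]
      rows <- t$sample_id[bad[bad[, 2] == j, 1]]
      stop("non-positive values in feature '", features[j],
           "' for samples: ", paste(rows, collapse = ", "), call. = FALSE)
    }
    x <- log(x)
  }
  if (method == "per_sample") {
    med <- apply(x[, intersect(center_features, features), drop = FALSE],
                 1, stats::median, na.rm = TRUE)
    x <- x - med
  } else {
    x <- sweep(x, 2, apply(x, 2, stats::median, na.rm = TRUE))
  }
  t[, features] <- x
  attr(t, "provenance") <- c(attr(t, "provenance"),
                             paste0(if (log_transform) "log;" else "",
                                    "median_normalized:", method))
  t
}

# Mann-Whitney U statistic (group a vs group b) with average ranks.
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Exact two-sided p by enumerating all group assignments of the pooled
# values (permutation distribution of U, valid under ties).
u_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  u_obs <- u_statistic(a, b)
  mu <- n1 * length(b) / 2
  # two-sided via distance from the null mean (symmetric under exchange)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tie-corrected normal approximation with continuity correction.
u_normal_p <- function(a, b, u) {
  n1 <- length(a)
  n2 <- length(b)
  n <- n1 + n2
  ties <- table(c(a, b))
  correction <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - correction)
  if (sigma2 <= 0) return(1)
  z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-max(z, 0))
}

#' Group difference test for one feature
#'
#' Two-sided Mann-Whitney U test of case vs control values (exact
#' permutation enumeration when the combined sample size is at most
#' `exact_max`, tie-corrected normal approximation otherwise), with
#' Cohen's d from the group means and pooled standard deviation, the
#' direction of the case-minus-control median difference, and the
#' significance class used throughout reporting: `significant` when
#' p < 0.05 (and q < 0.1 once q-values are attached), `trend` when
#' 0.05 < p < 0.1, otherwise `ns`.
#'
#' @param t A preprocessed [cohort_table()].
#' @param feature Feature column name.
#' @param exact_max Combined-n threshold for exact enumeration
#'   (default 20).
#' @return A one-row data.frame (`feature`, `U`, `p`, `q`, `cohen_d`,
#'   `direction`, `significance`); `q` is `NA` until [adjust_fdr()] is
#'   applied across a panel.
#' @export
group_difference <- function(t, feature, exact_max = 20) {
  g <- t$group
  x <- t[[feature]]
  a <- x[g == levels(g)[1] & !is.na(x)]
  b <- x[g == levels(g)[2] & !is.na(x)]
  if (!length(a) || !length(b)) {
    stop("both groups must be nonempty for '", feature, "'", call. = FALSE)
  }
  u <- u_statistic(a, b)
  p <- if (length(a) + length(b) <= exact_max) {
    u_exact_p(a, b)
  } else {
    u_normal_p(a, b, u)
  }
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  d <- if (is.na(sp2) || sp2 == 0) {
    NA_real_
  } else {
    (mean(a) - mean(b)) / sqrt(sp2)
  }
  if (is.na(d)) warning("constant feature '", feature, "': d undefined")
  data.frame(feature = feature, U = u, p = min(p, 1), q = NA_real_,
             cohen_d = d,
             direction = sign(stats::median(a) - stats::median(b)),
             significance = significance_class(p, NA_real_),
             stringsAsFactors = FALSE)
}

significance_class <- function(p, q) {
  ifelse(p < 0.05 & (is.na(q) | q < 0.1), "significant",
         ifelse(p > 0.05 & p < 0.1, "trend", "ns"))
}

#' Group differences for a feature panel, with q-values
#'
#' Runs [group_difference()] per feature and attaches Storey q-values
#' across the panel; the significance class is then finalized against
#' both thresholds (p < 0.05 and q < 0.1).
#'
#' @param t A preprocessed [cohort_table()].
#' @param features Character vector (default: metabolite role).
#' @return data.frame, one row per feature.
#' @export
group_difference_panel <- function(t, features = NULL) {
  if (is.null(features)) features <- cohort_roles(t)$metabolites
  res <- do.call(rbind, lapply(features, function(f) group_difference(t, f)))
  res$q <- adjust_fdr(res$p)
  res$significance <- significance_class(res$p, res$q)
  res
}

#' Storey q-values with smoother pi0 estimate
#'
#' Estimates the null proportion pi0 by the smoother method (natural
#' cubic smoothing spline of `pi0(lambda) = mean(p > lambda)/(1 - lambda)`
#' over `lambda = 0.05, ..., 0.95`, evaluated at the largest lambda) and
#' returns `q_i = min over j: p_j >= p_i of pi0 * m * p_(j) / rank(j)`.
#' When the estimate is degenerate (too few p-values, non-finite, or
#' outside (0, 1]) it falls back to `pi0 = 1`, which reduces exactly to
#' Benjamini-Hochberg.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param pi0 Optional fixed null proportion overriding estimation.
#' @return q-values in the input order; monotone nondecreasing in sorted
#'   p and never smaller than their p times pi0.
#' @export
adjust_fdr <- function(pvals, pi0 = NULL) {
  p <- as.numeric(pvals)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch({
      if (m < 20 || all(pi0_l == 0)) 1 else {
        fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
        stats::predict(fit, x = max(lambda))$y
      }
    }, error = function(e) 1)
    if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- pi0 * p[ord[1]]
  q[ord[1]] <- min(running, 1)
  for (i in seq_len(m - 1)) {
    j <- ord[i + 1]
    running <- min(running, pi0 * m * p[j] / (m - i))
    q[j] <- min(running, 1)
  }
  q
}

spearman_p <- function(rho, n) {
  if (n < 3 || is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Spearman correlation map between two feature sets
#'
#' Pairwise Spearman rank correlations (average ranks for ties,
#' pairwise-complete observations) of `components` against `metabolites`,
#' with t-approximation p-values and a significance mask at `p < alpha`.
#' Entries with fewer than `min_pairs` complete pairs are flagged missing.
#'
#' @param t A [cohort_table()].
#' @param components,metabolites Character vectors of column names.
#' @param subset `"all"`, or a group level to restrict samples.
#' @param alpha Mask threshold (default 0.05).
#' @param min_pairs Minimum complete pairs per entry (default 4).
#' @return List `rho`, `p`, `significant`, `n` (matrices components x
#'   metabolites).
#' @export
correlation_map <- function(t, components, metabolites, subset = "all",
                            alpha = 0.05, min_pairs = 4) {
  d <- as.data.frame(t)
  if (!identical(subset, "all")) {
    d <- d[d$group == subset, , drop = FALSE]
    if (!nrow(d)) stop("empty subset '", subset, "'", call. = FALSE)
  }
  rho <- matrix(NA_real_, length(components), length(metabolites),
                dimnames = list(components, metabolites))
  pm <- rho
  nm <- rho
  for (i in seq_along(components)) {
    for (j in seq_along(metabolites)) {
      x <- d[[components[i]]]
      y <- d[[metabolites[j]]]
      ok <- stats::complete.cases(x, y)
      nm[i, j] <- sum(ok)
      if (sum(ok) < min_pairs) next
      r <- stats::cor(rank(x[ok]), rank(y[ok]))
      rho[i, j] <- r
      pm[i, j] <- spearman_p(r, sum(ok))
    }
  }
  list(rho = rho, p = pm, significant = !is.na(pm) & pm < alpha, n = nm)
}

#' Between-group fold change of correlations
#'
#' Elementwise ratio of case correlations to control correlations.
#' Magnitudes above `cap` are capped at `cap` (keeping the ratio's sign);
#' pairs whose correlations disagree in sign are flagged in `sign_flip`
#' and not ratioed; near-zero control entries are reported as capped and
#' flagged in `unstable`.
#'
#' @param rho_case,rho_control Conformable correlation matrices.
#' @param cap Cap on the fold-change magnitude (default 4).
#' @param zero_tol Threshold below which a control correlation counts as
#'   zero.
#' @return List `fold` (matrix), `sign_flip` (logical matrix), `unstable`
#'   (logical matrix).
#' @export
correlation_fold_change <- function(rho_case, rho_control, cap = 4,
                                    zero_tol = 1e-3) {
  stopifnot(all(dim(rho_case) == dim(rho_control)))
  flip <- !is.na(rho_case) & !is.na(rho_control) &
    (rho_case * rho_control < 0)
  unstable <- !is.na(rho_control) & abs(rho_control) < zero_tol
  fold <- rho_case / rho_control
  fold[unstable] <- cap
  fold[abs(fold) > cap] <- cap * sign(fold[abs(fold) > cap])
  fold[flip] <- NA_real_
  list(fold = fold, sign_flip = flip, unstable = unstable)
}
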