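mk_table <- function(values, group = NULL) {
  n <- nrow(values)
  if (is.null(group)) {
    group <- rep(c("PTSD", "control"), length.out = n)
  }
  d <- data.frame(sample_id = paste0("s", seq_len(n)), group = group,
                  values, stringsAsFactors = FALSE, check.names = FALSE)
  cohort_table(d, metabolites = colnames(values))
}

test_that("preprocess centers each sample by its log-median", {
  v <- data.frame(m1 = exp(1), m2 = exp(2), m3 = exp(3))
  t <- mk_table(rbind(v, v), group = c("PTSD", "control"))
  pp <- preprocess(t)
  expect_equal(unlist(pp[1, c("m1", "m2", "m3")], use.names = FALSE),
               c(-1, 0, 1))
  # an all-equal sample centers to zero
  t2 <- mk_table(data.frame(m1 = c(5, 2), m2 = c(5, 4), m3 = c(5, 8)))
  pp2 <- preprocess(t2)
  expect_equal(unlist(pp2[1, c("m1", "m2", "m3")], use.names = FALSE),
               c(0, 0, 0))
  # provenance records the applied steps
  expect_match(attr(pp, "provenance"), "median_normalized")
})

test_that("preprocess rejects non-positive values naming the offender", {
  t <- mk_table(data.frame(m1 = c(1, -2), m2 = c(1, 1)))
  expect_error(preprocess(t), "m1.*s2")
})

test_that("per-sample centering is idempotent and per-feature mode
           works", {
  set.seed(11)
  t <- mk_table(data.frame(m1 = rlnorm(10), m2 = rlnorm(10),
                           m3 = rlnorm(10)))
  pp <- preprocess(t)
  pp2 <- preprocess(pp, log_transform = FALSE)
  expect_equal(as.data.frame(pp2)[, c("m1", "m2", "m3")],
               as.data.frame(pp)[, c("m1", "m2", "m3")])
  pf <- preprocess(t, method = "per_feature")
  expect_equal(unname(apply(as.data.frame(pf)[, c("m1", "m2", "m3")], 2,
                            stats::median)), c(0, 0, 0))
})

test_that("Mann-Whitney matches the enumeration oracle and closed
           forms", {
  t <- mk_table(data.frame(m = c(1, 2, 3, 4, 5, 6)),
                group = c(rep("PTSD", 3), rep("control", 3)))
  r <- group_difference(t, "m")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)     # 2 / choose(6, 3) extreme assignments
  expect_equal(r$direction, -1)
  # identical groups: p = 1, d = 0
  t2 <- mk_table(data.frame(m = rep(c(1, 2, 3), 2)),
                 group = c(rep("PTSD", 3), rep("control", 3)))
  r2 <- group_difference(t2, "m")
  expect_equal(r2$p, 1)
  expect_equal(r2$cohen_d, 0)
  # pooled-SD closed form: A = (0, 2), B = (1, 3) -> |d| = 1/sqrt(2)
  t3 <- mk_table(data.frame(m = c(0, 2, 1, 3)),
                 group = c("PTSD", "PTSD", "control", "control"))
  expect_equal(abs(group_difference(t3, "m")$cohen_d), 1 / sqrt(2))
  # constant feature flags d as undefined
  t4 <- mk_table(data.frame(m = rep(1, 6)))
  expect_warning(r4 <- group_difference(t4, "m"), "undefined")
  expect_true(is.na(r4$cohen_d))
})

test_that("exact Mann-Whitney agrees with the oracle across group sizes
           up to 8", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    vals <- round(rnorm(n1 + n2), sample(0:1, 1)) # induce ties sometimes
    t <- mk_table(data.frame(m = vals),
                  group = c(rep("PTSD", n1), rep("control", n2)))
    r <- group_difference(t, "m")
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    expect_equal(r$U, oracle_u(a, b))
    expect_equal(r$p, oracle_u_p(a, b), tolerance = 1e-12)
  }
})

test_that("normal approximation is close to the exact p at moderate n", {
  set.seed(5)
  x <- rnorm(18)
  t <- mk_table(data.frame(m = x),
                group = c(rep("PTSD", 9), rep("control", 9)))
  p_exact <- group_difference(t, "m")$p
  p_norm <- group_difference(t, "m", exact_max = 0)$p
  expect_lt(abs(p_exact - p_norm), 0.02)
})

test_that("q-values reduce to Benjamini-Hochberg with pi0 = 1", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_fdr(p, pi0 = 1), rep(0.04, 4))
  expect_equal(adjust_fdr(0.5, pi0 = 1), 0.5)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2)
  pr <- runif(40)
  expect_equal(adjust_fdr(pr, pi0 = 1), oracle_bh(pr), tolerance = 1e-12)
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("q-values are monotone in p and bounded below by pi0 * p", {
  set.seed(13)
  p <- c(runif(30), runif(30, 0, 0.01))
  q <- adjust_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p * 0 & q <= 1))
  expect_true(all(q[o] >= 0.0 * p[o]))
  # small panels fall back to pi0 = 1 (BH)
  expect_equal(adjust_fdr(c(0.2, 0.6)), oracle_bh(c(0.2, 0.6)))
})

test_that("group difference panel attaches q and significance classes", {
  set.seed(31)
  n <- 40
  v <- data.frame(up = c(rlnorm(n / 2, 1), rlnorm(n / 2, 0)),
                  null = rlnorm(n))
  t <- mk_table(v, group = rep(c("PTSD", "control"), each = n / 2))
  pp <- preprocess(t, method = "per_feature")
  res <- group_difference_panel(pp)
  expect_equal(res$feature, c("up", "null"))
  expect_true(all(!is.na(res$q)))
  expect_equal(res$significance[1], "significant")
})

test_that("Spearman maps honor rank identities and flag sparse pairs", {
  t <- mk_table(data.frame(x = c(1, 2, 3, 4), y = c(8, 6, 4, 2),
                           z = c(NA, NA, NA, 4)))
  cm <- correlation_map(t, "x", c("y", "z"))
  expect_equal(unname(cm$rho["x", "y"]), -1)
  expect_true(is.na(cm$rho["x", "z"]))   # < 4 complete pairs
  # invariance to strictly monotone transforms
  set.seed(17)
  a <- rnorm(30)
  b <- a + rnorm(30, 0, 0.5)
  t2 <- mk_table(data.frame(x = a, y = b, y2 = exp(b)))
  cm2 <- correlation_map(t2, "x", c("y", "y2"))
  expect_equal(unname(cm2$rho["x", "y"]), unname(cm2$rho["x", "y2"]))
  expect_error(correlation_map(t2, "x", "y", subset = "PTSD"), NA)
})

test_that("Spearman p-values are near-nominal under independence", {
  set.seed(23)
  hits <- replicate(400, {
    x <- rnorm(60)
    y <- rnorm(60)
    t <- mk_table(data.frame(x = x, y = y))
    correlation_map(t, "x", "y")$p[1, 1] < 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("correlation fold changes ratio, cap, and flag sign flips", {
  case <- matrix(c(0.6, 0.9, -0.3), 1, 3)
  ctrl <- matrix(c(0.2, 0.1, 0.3), 1, 3)
  fc <- correlation_fold_change(case, ctrl, cap = 4)
  expect_equal(fc$fold[1, 1], 3)
  expect_equal(fc$fold[1, 2], 4)           # capped at 4
  expect_true(is.na(fc$fold[1, 3]))        # sign flip: no ratio
  expect_true(fc$sign_flip[1, 3])
  # near-zero control entries are reported as capped and flagged
  fc2 <- correlation_fold_change(matrix(0.5), matrix(1e-6), cap = 4)
  expect_equal(fc2$fold[1, 1], 4)
  expect_true(fc2$unstable[1, 1])
})
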