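chain <- generate_toy_model("linear_chain")

test_that("MCRC matches the linear analytic oracle exactly", {
  # s3* = v_in / k3: response to v_in is +1 at any fold
  expect_equal(unname(mcrc(chain, "v_in", "s3", 0.5)), 1,
               tolerance = 1e-8)
  expect_equal(unname(mcrc(chain, "v_in", "s3", 1.5)), 1,
               tolerance = 1e-8)
  # response to k3 is -1/fold: -2 at 0.5, -2/3 at 1.5, net mean -4/3
  d <- unname(mcrc(chain, "k3", "s3", 0.5))
  u <- unname(mcrc(chain, "k3", "s3", 1.5))
  expect_equal(d, -2, tolerance = 1e-6)
  expect_equal(u, -2 / 3, tolerance = 1e-6)
  expect_equal((d + u) / 2, -4 / 3, tolerance = 1e-6)
  # structural independence: k1 has no path to s3
  expect_equal(unname(mcrc(chain, "k1", "s3", 1.5)), 0, tolerance = 1e-8)
  expect_error(mcrc(chain, "v_in", "s3", 1), "fold")
})

test_that("mca_scan equals independent per-entry mcrc calls", {
  params <- c("v_in", "k1", "k2", "k3")
  mets <- c("s1", "s2", "s3")
  mm <- mca_scan(chain, params, mets)
  base <- find_steady_state(chain)
  for (p in params) {
    expect_equal(mm$coeff_down[p, ], mcrc(chain, p, mets, 0.5, base),
                 tolerance = 1e-12)
    expect_equal(mm$coeff_up[p, ], mcrc(chain, p, mets, 1.5, base),
                 tolerance = 1e-12)
  }
  expect_equal(mm$coeff_net, (mm$coeff_down + mm$coeff_up) / 2)
  # empty parameter list gives an empty matrix, not an error
  empty <- mca_scan(chain, character(), mets)
  expect_equal(nrow(empty$coeff_net), 0)
  # resuming from a partial result reuses entries
  part <- mca_scan(chain, "v_in", mets)
  full <- mca_scan(chain, params, mets, partial = part)
  expect_equal(full$coeff_net, mm$coeff_net)
})

test_that("summation property holds in the infinitesimal limit", {
  # interior metabolite s2 on an unbranched chain: concentration
  # response coefficients over all rate parameters sum to zero
  base <- find_steady_state(chain)
  total <- sum(vapply(c("v_in", "k1", "k2", "k3"), function(p) {
    mean(c(mcrc(chain, p, "s2", 0.99, base),
           mcrc(chain, p, "s2", 1.01, base)))
  }, numeric(1)))
  expect_equal(total, 0, tolerance = 1e-3)
})

test_that("screening applies both thresholds and ranks by magnitude", {
  mets <- paste0("m", 1:12)
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(paste0("p", seq_along(rows)), mets)
    structure(list(params = rownames(m), metabolites = mets,
                   coeff_down = m, coeff_up = m, coeff_net = m,
                   baseline = NULL, failures = list()),
              class = "mcrc_matrix")
  }
  mm <- mk(list(
    rep(0.01, 12),              # passes both (sum 0.12)
    c(0.0005, rep(0.02, 11)),   # fails per-metabolite
    rep(0.0075, 12),            # sum 0.09: fails cumulative
    rep(-0.05, 12),             # passes on absolute values (sum 0.6)
    c(rep(0.001, 11), 0.095)    # per-feature ok, sum 0.106: passes
  ))
  kept <- screen_parameters(mm)
  expect_equal(kept$param, c("p4", "p1", "p5"))
  expect_equal(kept$cumulative, c(0.6, 0.12, 0.106), tolerance = 1e-12)
  expect_equal(kept$rank, 1:3)
  # order independence: permuting rows never changes the kept set
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(5)
    mp <- mk(lapply(perm, function(j) mm$coeff_net[j, ]))
    rownames(mp$coeff_net) <- rownames(mp$coeff_down) <-
      rownames(mp$coeff_up) <- paste0("p", perm)
    mp$params <- paste0("p", perm)
    expect_setequal(screen_parameters(mp)$param, kept$param)
  }
  # missing entries exclude the parameter with a warning
  mm$coeff_net[1, 1] <- NA
  expect_warning(k2 <- screen_parameters(mm), "missing")
  expect_false("p1" %in% k2$param)
})

test_that("signature matching compares directions with a tie rule", {
  sig_up <- signature_spec(c(s3 = 1))
  # raising v_in raises s3: match
  r <- match_signature(chain, "v_in", 1.5, sig_up)
  expect_true(r$match)
  expect_equal(unname(r$per_feature_signs["s3"]), "+")
  # flipped expectation is reported with the feature named
  sig_dn <- signature_spec(c(s3 = -1))
  r2 <- match_signature(chain, "v_in", 1.5, sig_dn)
  expect_false(r2$match)
  expect_equal(r2$mismatches, "s3")
  # a change below rel_tol counts as no-change and mismatches +
  r3 <- match_signature(chain, "k1", 1.5, sig_up)
  expect_false(r3$match)
  expect_equal(unname(r3$per_feature_signs["s3"]), "0")
})

test_that("regulatory state matrix trichotomizes at 1 percent", {
  rs_up <- regulatory_state_matrix(chain, list("v_in"), "s3", fold = 1.05)
  expect_equal(unname(rs_up[1, "s3"]), "increased")
  rs_dn <- regulatory_state_matrix(chain, list("v_in"), "s3", fold = 0.95)
  expect_equal(unname(rs_dn[1, "s3"]), "decreased")
  rs_sm <- regulatory_state_matrix(chain, list("v_in"), "s3",
                                   fold = 1.005)
  expect_equal(unname(rs_sm[1, "s3"]), "small")
  expect_error(regulatory_state_matrix(chain, list("v_in"), "bogus"),
               "bogus")
})

test_that("GR sensitivity parameters control pyruvate and citrate in the
           reference model", {
  m <- reference_model()
  mm <- mca_scan(m, c("n", "nx"), c("pyruvate", "citrate"))
  expect_true(all(abs(mm$coeff_net[, "pyruvate"]) > 0))
  expect_true(all(abs(mm$coeff_net[, "citrate"]) > 0))
  expect_equal(length(mm$failures), 0)
})

test_that("feedback loop toy: higher Hill exponent damps input
           sensitivity", {
  m <- generate_toy_model("feedback_loop")
  sens <- function(n_fb) {
    m$parameters["n_fb"] <- n_fb
    s1 <- find_steady_state(m)$concentrations["c"]
    m2 <- m
    m2$species$initial[m2$species$id == "u"] <- 1.2
    s2 <- find_steady_state(m2)$concentrations["c"]
    (s2 - s1) / s1
  }
  expect_lt(abs(sens(6)), abs(sens(2)))
})
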