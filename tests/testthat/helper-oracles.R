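# Independent oracles used by the test suite.  These deliberately use
# different algorithms from the package implementation.

# Mann-Whitney U via the pairwise-comparison definition (not ranks).
oracle_u <- function(a, b) {
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  sum(cmp)
}

# Exact two-sided permutation p-value for the Mann-Whitney test by full
# enumeration of group assignments of the pooled values.
oracle_u_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  splits <- utils::combn(length(pooled), n1)
  mu <- n1 * length(b) / 2
  u_obs <- oracle_u(a, b)
  us <- apply(splits, 2, function(ix) {
    oracle_u(pooled[ix], pooled[-ix])
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Closed-form Benjamini-Hochberg q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# Tiny model where dC/dt = v_in - k * C, so C* = v_in / k exactly.
oracle_decay_model <- function(v_in = 2, k = 0.5) {
  model_spec(
    species = data.frame(id = "c", compartment = "cell", initial = 1,
                         role = "metabolite", stringsAsFactors = FALSE),
    compartments = data.frame(id = "cell", volume = 1,
                              stringsAsFactors = FALSE),
    reactions = list(
      list(id = "src", vmax = "v_in", law = "saturating",
           substrates = list(), stoich = c(c = 1)),
      list(id = "deg", vmax = "k", law = "mass_action",
           substrates = list("c"), stoich = c(c = -1))
    ),
    parameters = c(v_in = v_in, k = k))
}

# Confounded log-log data-generating process with known slope; the
# covariates load positively on both exposure and outcome, so the
# unweighted slope is upward-biased by about +0.3.
oracle_ace_dgp <- function(n, slope, p_cov = 4) {
  z <- matrix(stats::rnorm(n * p_cov), n, p_cov)
  bz <- rep_len(c(0.4, 0.3, 0.35, 0.25), p_cov)
  e <- as.numeric(z %*% bz) + stats::rnorm(n)
  y <- slope * e + as.numeric(z %*% bz) + stats::rnorm(n)
  list(e = e, y = y, z = as.data.frame(z))
}
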