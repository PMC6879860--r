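test_that("saturation term matches half-saturation algebra and errors", {
  expect_equal(saturation_term(1, 1), 0.5)
  expect_equal(saturation_term(0, 2), 0)
  expect_equal(saturation_term(3, 1), 0.75)
  expect_error(saturation_term(1, 0), "invalid parameter")
  expect_error(saturation_term(1, -2), "invalid parameter")
  expect_error(saturation_term(-1, 1), "invalid input")
})

test_that("saturation term is bounded and monotone", {
  set.seed(1)
  for (i in 1:20) {
    km <- runif(1, 0.1, 5)
    conc <- sort(runif(10, 0, 20))
    v <- saturation_term(conc, km)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("allosteric factors follow the hyperbolic forms", {
  s <- allosteric_spec(activator_conc = 2, inhibitor_conc = 0,
                       k_act = 2, k_inh = 3, k_prod = 1)
  f <- allosteric_factors(s)
  expect_equal(f$f_act, 0.5)           # A = k_act
  expect_equal(f$f_deact, 1)           # no inhibitor
  expect_equal(f$f_pi, 2 / (2 + 3))    # I = 0 -> A/(A + k_inh)
  s2 <- allosteric_spec(activator_conc = 1, inhibitor_conc = 3,
                        k_act = 1, k_inh = 3, k_prod = 2)
  f2 <- allosteric_factors(s2)
  expect_equal(f2$f_deact, 0.5)        # I = k_inh
  expect_equal(f2$f_pi, (1 / 4) * (1 / (1 + 3 / 2)))
  for (v in f2) expect_true(v >= 0 && v <= 1)
  expect_error(allosteric_spec(activator_conc = -1), "invalid input")
  expect_error(allosteric_spec(k_act = 0), "invalid parameter")
})

test_that("sigtrans factor combines edges as Wf(1+sum act)(prod inh)", {
  state <- c(s = 1, i = 2)
  expect_equal(sigtrans_factor(list(), state, weight = 1), 1)
  e_act <- regulator_edge("s", "activate", hill_n = 2, k_half = 1)
  expect_equal(sigtrans_factor(list(e_act), state), 1.5)
  e_inh <- regulator_edge("i", "deactivate", hill_n = 4, k_half = 2)
  expect_equal(sigtrans_factor(list(e_inh), state, weight = 2), 1)
  both <- sigtrans_factor(list(e_act, e_inh), state, weight = 2)
  expect_equal(both, 2 * 1.5 * 0.5)
  # bounded by Wf * (1 + number of unit-weight activators)
  expect_lte(both, 2 * (1 + 1))
  expect_error(sigtrans_factor(list(regulator_edge("ghost", "activate",
                                                   k_half = 1)), state),
               "ghost")
})

test_that("Hill activation with n = 1 equals the saturation term", {
  for (k in c(0.3, 1, 4)) {
    conc <- seq(0, 10, length.out = 25)
    hill <- vapply(conc, function(s) {
      sigtrans_factor(list(regulator_edge("x", "activate", hill_n = 1,
                                          k_half = k)),
                      c(x = s)) - 1
    }, numeric(1))
    expect_equal(hill, saturation_term(conc, k), tolerance = 1e-12)
  }
})

test_that("reaction rate composes the factor blocks", {
  # all substrates saturated, no regulation
  r <- reaction_rate(10, substrates = list(list(conc = 1e9, km = 1),
                                           list(conc = 1e9, km = 2)))
  expect_equal(r, 10, tolerance = 1e-6)
  # any substrate at zero kills the rate
  expect_equal(reaction_rate(10, list(list(conc = 0, km = 1))), 0)
  # one substrate at Km and an allosteric f_deact of 0.5
  al <- allosteric_spec(inhibitor_conc = 1, k_inh = 1)
  r2 <- reaction_rate(10, list(list(conc = 1, km = 1)), allosteric = al,
                      allosteric_use = "f_deact")
  expect_equal(r2, 2.5)
  expect_error(reaction_rate(-1), "invalid parameter")
})

test_that("reaction rate is monotone in substrates and regulators", {
  set.seed(7)
  for (i in 1:15) {
    km <- runif(1, 0.2, 3)
    kact <- runif(1, 0.2, 3)
    kinh <- runif(1, 0.2, 3)
    base <- runif(3, 0.1, 4) # substrate, activator, inhibitor concs
    rate <- function(s, a, ih) {
      reaction_rate(5, list(list(conc = s, km = km)),
                    regulation = list(
                      regulator_edge("a", "activate", hill_n = 2,
                                     k_half = kact),
                      regulator_edge("i", "deactivate", hill_n = 3,
                                     k_half = kinh)),
                    state = c(a = a, i = ih))
    }
    h <- 1e-4
    r0 <- rate(base[1], base[2], base[3])
    expect_gte(rate(base[1] + h, base[2], base[3]), r0)
    expect_gte(rate(base[1], base[2] + h, base[3]), r0)
    expect_lte(rate(base[1], base[2], base[3] + h), r0)
  }
})

test_that("transport rates follow the two carrier laws", {
  p <- transport_spec("passive", epsilon = 0.1)
  expect_equal(transport_rate(p, 5, 3), 0.2)
  expect_equal(transport_rate(p, 2, 2), 0)
  f <- transport_spec("facilitated", t_max = 4, k_blood = 1, k_tissue = 1)
  expect_equal(transport_rate(f, 1, 0), 2)
  expect_error(transport_spec("osmosis"), "configuration error")
  expect_error(transport_spec("passive", epsilon = -1),
               "invalid parameter")
  expect_error(transport_rate(p, -1, 0), "invalid input")
})
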