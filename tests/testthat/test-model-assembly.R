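ref <- reference_model()

test_that("shipped reference model file loads and matches the in-code
           instance", {
  path <- reference_model_path()
  m <- load_model(path)
  expect_s3_class(m, "model_spec")
  expect_equal(nrow(m$species), nrow(ref$species))
  expect_equal(length(m$reactions), length(ref$reactions))
  expect_equal(m$parameters, ref$parameters)
})

test_that("model validation rejects dangling references and empties", {
  sp <- data.frame(id = c("a", "b"), compartment = "cell", initial = 1,
                   role = "metabolite")
  cp <- data.frame(id = "cell", volume = 1)
  expect_error(model_spec(sp[0, ], cp), "empty species")
  expect_error(
    model_spec(sp, cp, reactions = list(
      list(id = "r", vmax = 1, substrates = list("ghost"),
           stoich = c(a = -1)))),
    "ghost")
  expect_error(
    model_spec(sp, cp, reactions = list(
      list(id = "r", vmax = "missing_par", substrates = list(),
           stoich = c(a = 1)))),
    "missing_par")
  expect_error(model_spec(sp, data.frame(id = "cell", volume = 0)),
               "volumes")
  expect_error(model_spec(sp, cp, clamps = "ghost"), "ghost")
})

test_that("assembled RHS applies stoichiometry, volume and clamps", {
  m <- model_spec(
    species = data.frame(id = c("a", "b"), compartment = "cell",
                         initial = c(2, 0), role = "metabolite"),
    compartments = data.frame(id = "cell", volume = 2),
    reactions = list(list(id = "r", vmax = "k", law = "mass_action",
                          substrates = list("a"),
                          stoich = c(a = -1, b = 1))),
    parameters = c(k = 0.5))
  rhs <- assemble_rhs(m)
  d <- rhs(0, c(a = 2, b = 0))
  r <- 0.5 * 2
  expect_equal(unname(d["a"]), -r / 2)
  expect_equal(unname(d["b"]), +r / 2)
  # conservation of the closed pair at arbitrary states
  set.seed(3)
  for (i in 1:10) {
    y <- runif(2, 0, 5)
    expect_equal(sum(rhs(0, stats::setNames(y, c("a", "b")))), 0)
  }
  # clamped species has derivative exactly zero at any state
  m$clamps <- "a"
  rhs_c <- assemble_rhs(m)
  expect_identical(unname(rhs_c(0, c(a = 3, b = 1))["a"]), 0)
})

test_that("glycogen and input clamps hold in the reference model", {
  rhs <- assemble_rhs(ref)
  set.seed(4)
  y <- initial_state(ref)
  y[] <- runif(length(y), 0.1, 3)
  d <- rhs(0, y)
  expect_identical(unname(d[c("glycogen", "stress", "epinephrine")]),
                   c(0, 0, 0))
})

test_that("steady state solver matches the linear closed form", {
  m <- oracle_decay_model(v_in = 2, k = 0.5)
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  expect_equal(unname(ss$concentrations["c"]), 4, tolerance = 1e-7)
  # starting at the steady state converges immediately
  ss2 <- find_steady_state(m, initial = c(c = 4))
  expect_true(ss2$converged)
  expect_lt(ss2$residual_norm, 1e-6)
  # residual is re-checkable from the assembled RHS
  rhs <- assemble_rhs(m)
  expect_lt(max(abs(rhs(0, ss$concentrations))), 1e-6)
  expect_error(find_steady_state(m, initial = c(c = -1)), "negative")
})

test_that("reference model reaches a steady state with sane ratios", {
  ss <- find_steady_state(ref)
  expect_true(ss$converged)
  expect_true(all(ss$concentrations > 0))
  expect_true(all(is.finite(ss$derived_ratios)))
  expect_true(all(ss$derived_ratios > 0))
  rhs <- assemble_rhs(ref)
  free <- setdiff(names(ss$concentrations), ref$clamps)
  expect_lt(max(abs(rhs(0, ss$concentrations)[free])), 1e-6)
})

test_that("simulation matches linear-decay closed form and respects
           overrides", {
  m <- model_spec(
    species = data.frame(id = "c", compartment = "cell", initial = 3,
                         role = "metabolite"),
    compartments = data.frame(id = "cell", volume = 1),
    reactions = list(list(id = "deg", vmax = "k", law = "mass_action",
                          substrates = list("c"), stoich = c(c = -1))),
    parameters = c(k = 0.7))
  tr <- simulate_model(m, t_span = c(0, 5), n_out = 60)
  expect_equal(tr$c, 3 * exp(-0.7 * tr$time), tolerance = 1e-6)
  # a zero-length (empty) perturbation leaves the trajectory unchanged
  tr2 <- simulate_model(m, t_span = c(0, 5), n_out = 60,
                        inputs = list(list(species = "c", value = 9,
                                           from = 2, to = 2)))
  expect_equal(tr2$c[tr2$time %in% tr$time], tr$c, tolerance = 1e-6)
  # clamp contract: clamped species identical at both ends, bit for bit
  m$clamps <- "c"
  tr3 <- simulate_model(m, t_span = c(0, 5), n_out = 20)
  expect_identical(tr3$c[1], tr3$c[nrow(tr3)])
})

test_that("qualitative scenarios reproduce the directional physiology", {
  null <- qualitative_check(ref, "null")
  expect_true(all(null$observed == "0"))
  stress <- qualitative_check(ref, "stress_step")
  expect_equal(stress$observed, "+")
  glu <- qualitative_check(ref, "glucose_load")
  expect_equal(glu$observed, "+")
  cyt <- qualitative_check(ref, "cytokine_challenge")
  expect_equal(cyt$observed, "+")
  expect_error(qualitative_check(ref, "volcano"), "arg")
})

test_that("GR sensitization reproduces the dysfunction signature", {
  rep <- qualitative_check(ref, "gr_sensitization")
  expect_true(attr(rep, "pass"))
  expect_equal(rep$observed[rep$feature %in% c("il6", "tnf")],
               c("+", "+"))
})
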