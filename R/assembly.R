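# Model assembly: compile a declarative model_spec into an ODE
# right-hand side, solve for steady states under clamps, simulate
# trajectories with time-windowed input overrides, and run the shipped
# qualitative scenario checks.

compile_rhs <- function(m) {
  sp <- m$species
  ids <- sp$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  vol <- m$compartments$volume[match(sp$compartment, m$compartments$id)]
  pars <- m$parameters
  clamp_idx <- idx[m$clamps]

  rx_list <- lapply(m$reactions, function(r) {
    law <- r$law %||% "saturating"
    subs <- lapply(r$substrates %||% list(), function(s) {
      if (is.character(s)) {
        list(i = idx[[s]], km = NA_real_)
      } else {
        list(i = idx[[s$species]],
             km = if (law == "saturating") pval(s$km, pars) else NA_real_)
      }
    })
    al <- NULL
    if (!is.null(r$allosteric)) {
      a <- r$allosteric
      al <- list(
        act_i = if (!is.null(a$activator)) idx[[a$activator]] else NA,
        inh_i = if (!is.null(a$inhibitor)) idx[[a$inhibitor]] else NA,
        k_act = if (!is.null(a$k_act)) pval(a$k_act, pars) else NA,
        k_inh = if (!is.null(a$k_inh)) pval(a$k_inh, pars) else NA,
        k_prod = if (!is.null(a$k_prod)) pval(a$k_prod, pars) else NA,
        use = a$use %||% c(if (!is.null(a$activator)) "f_act",
                           if (!is.null(a$inhibitor)) "f_deact")
      )
    }
    regs <- lapply(r$regulators %||% list(), function(e) {
      list(i = idx[[e$species]],
           activate = identical(e$mode, "activate"),
           n = pval(e$n %||% 1, pars),
           k = pval(e$k, pars),
           w = pval(e$weight %||% 1, pars))
    })
    list(vmax = pval(r$vmax, pars),
         mass_action = law == "mass_action",
         subs = subs,
         al = al,
         regs = regs,
         wf = pval(r$weight %||% 1, pars),
         st_i = idx[names(r$stoich)],
         st_c = as.numeric(r$stoich))
  })

  tr_list <- lapply(m$transports, function(tr) {
    passive <- identical(tr$kind, "passive")
    list(passive = passive,
         b = idx[[tr$species_blood]], t = idx[[tr$species_tissue]],
         eps = if (passive) pval(tr$epsilon, pars) else NA,
         tmax = if (!passive) pval(tr$t_max, pars) else NA,
         kb = if (!passive) pval(tr$k_blood, pars) else NA,
         kt = if (!passive) pval(tr$k_tissue, pars) else NA,
         vb = vol[idx[[tr$species_blood]]],
         vt = vol[idx[[tr$species_tissue]]])
  })

  function(t, y) {
    y <- pmax(y, 0)
    dy <- numeric(n)
    for (r in rx_list) {
      rate <- r$vmax
      if (r$mass_action) {
        for (s in r$subs) rate <- rate * y[s$i]
      } else {
        for (s in r$subs) rate <- rate * y[s$i] / (y[s$i] + s$km)
      }
      if (!is.null(r$al)) {
        a <- r$al
        for (u in a$use) {
          rate <- rate * switch(u,
            f_act = y[a$act_i] / (y[a$act_i] + a$k_act),
            f_deact = a$k_inh / (y[a$inh_i] + a$k_inh),
            f_pi = (y[a$act_i] / (y[a$act_i] + a$k_inh)) *
              (1 / (1 + y[a$inh_i] / a$k_prod)))
        }
      }
      if (length(r$regs)) {
        act_sum <- 0
        inh_prod <- 1
        for (e in r$regs) {
          sn <- y[e$i]^e$n
          kn <- e$k^e$n
          if (e$activate) {
            act_sum <- act_sum + e$w * sn / (sn + kn)
          } else {
            inh_prod <- inh_prod * kn / (sn + kn)
          }
        }
        rate <- rate * r$wf * (1 + act_sum) * inh_prod
      } else {
        rate <- rate * r$wf
      }
      dy[r$st_i] <- dy[r$st_i] + r$st_c * rate
    }
    for (tr in tr_list) {
      f <- if (tr$passive) {
        tr$eps * (y[tr$b] - y[tr$t])
      } else {
        tr$tmax * (y[tr$b] / (tr$kb + y[tr$b]) - y[tr$t] / (tr$kt + y[tr$t]))
      }
      dy[tr$b] <- dy[tr$b] - f
      dy[tr$t] <- dy[tr$t] + f
    }
    dy <- dy / vol
    if (length(clamp_idx)) dy[clamp_idx] <- 0
    dy
  }
}

#' Assemble the ODE right-hand side of a model
#'
#' For each species the derivative is
#' `(sum of producing rates - sum of consuming rates +/- transport) / V`;
#' clamped species have derivative exactly 0 at any state.
#'
#' @param m A [model_spec()].
#' @return Function `(t, state) -> named derivative vector`.
#' @export
assemble_rhs <- function(m) {
  stopifnot(inherits(m, "model_spec"))
  f <- compile_rhs(m)
  ids <- m$species$id
  function(t, y) {
    if (!is.null(names(y))) y <- y[ids]
    stats::setNames(f(t, as.numeric(y)), ids)
  }
}

initial_state <- function(m) {
  stats::setNames(as.numeric(m$species$initial), m$species$id)
}

#' Derived regulatory ratios from a model state
#'
#' Computes the four composite readouts used in regulatory-state reporting:
#' energy charge `atp/adp`, redox `nadh/nad`, the glycolytic ratio
#' `(pyruvate + lactate)/citrate`, and the global arginine bioavailability
#' ratio `arginine/(ornithine + citrulline)`.  Ratios whose species are
#' absent from the model are returned as `NA`.
#'
#' @param state Named concentration vector.
#' @return Named numeric vector of the four ratios.
#' @export
derived_ratios <- function(state) {
  g <- function(x) if (x %in% names(state)) state[[x]] else NA_real_
  c(atp_adp = g("atp") / g("adp"),
    nadh_nad = g("nadh") / g("nad"),
    glycolytic_ratio = (g("pyruvate") + g("lactate")) / g("citrate"),
    gabr = g("arginine") / (g("ornithine") + g("citrulline")))
}

#' Find the steady state of a model
#'
#' Integrates the assembled system from `initial` in expanding time chunks
#' and applies a damped-Newton root polish on the unclamped species once
#' the trajectory has settled.  Non-convergence is flagged in the result
#' rather than silently returned.
#'
#' @param m A [model_spec()].
#' @param initial Optional named initial state (defaults to the spec's
#'   initial concentrations).
#' @param t_max Maximum integration horizon.
#' @param tol Steady-state residual tolerance on `max |dM/dt|`.
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `steady_state`: `concentrations`,
#'   `residual_norm`, `converged`, `derived_ratios`.
#' @export
find_steady_state <- function(m, initial = NULL, t_max = 4000, tol = 1e-6,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(m, "model_spec"))
  rhs <- compile_rhs(m)
  ids <- m$species$id
  y <- if (is.null(initial)) initial_state(m) else initial[ids]
  if (any(y < 0)) stop("invalid input: negative initial state",
                       call. = FALSE)
  y <- as.numeric(y)
  free <- setdiff(seq_along(ids), match(m$clamps, ids))
  f0 <- function(y) rhs(0, y)
  resid <- function(y) {
    r <- abs(f0(y)[free])
    if (length(r)) max(r) else 0
  }
  t_now <- 0
  chunk <- 20
  r <- resid(y)
  while (r >= tol && t_now < t_max) {
    t_next <- min(t_now + chunk, t_max)
    tr <- ode_integrate(function(t, y) rhs(t, y), stats::setNames(y, ids),
                        c(t_now, t_next), rtol = rtol, atol = atol)
    y <- pmax(as.numeric(tr[nrow(tr), -1]), 0)
    t_now <- t_next
    chunk <- chunk * 2
    np <- newton_polish(f0, y, free, tol = tol)
    if (np$converged) {
      y <- np$y
      r <- np$residual
      break
    }
    r <- resid(y)
  }
  if (r >= tol) {
    np <- newton_polish(f0, y, free, tol = tol)
    y <- np$y
    r <- np$residual
  }
  conc <- stats::setNames(y, ids)
  structure(list(concentrations = conc, residual_norm = r,
                 converged = r < tol, derived_ratios = derived_ratios(conc)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady_state: residual", format(x$residual_norm, digits = 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Simulate a model trajectory
#'
#' Integrates the model over `t_span`, honouring clamps and
#' time-windowed input overrides.  An override clamps a species to a fixed
#' value over `[from, to]`; the state reverts to free dynamics afterwards.
#'
#' @param m A [model_spec()].
#' @param initial Optional named initial state.
#' @param t_span Numeric `c(t0, t1)`, increasing.
#' @param inputs List of overrides `list(species=, value=, from=, to=)`.
#' @param n_out Number of output points.
#' @param rtol,atol Integrator tolerances.
#' @return data.frame with `time` column and one column per species.
#' @export
simulate_model <- function(m, initial = NULL, t_span = c(0, 100),
                           inputs = list(), n_out = 200,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(m, "model_spec"), length(t_span) == 2,
            t_span[2] > t_span[1])
  ids <- m$species$id
  y <- if (is.null(initial)) initial_state(m) else initial[ids]
  brk <- sort(unique(c(t_span,
                       vapply(inputs, function(i) i$from, numeric(1)),
                       vapply(inputs, function(i) i$to, numeric(1)))))
  brk <- brk[brk >= t_span[1] & brk <= t_span[2]]
  grid <- sort(unique(c(seq(t_span[1], t_span[2], length.out = n_out), brk)))
  rows <- list()
  for (s in seq_len(length(brk) - 1)) {
    a <- brk[s]
    b <- brk[s + 1]
    active <- Filter(function(i) i$from <= a && i$to >= b, inputs)
    mm <- m
    for (i in active) {
      y[i$species] <- i$value
      mm$clamps <- union(mm$clamps, i$species)
    }
    seg_times <- grid[grid >= a & grid <= b]
    if (length(seg_times) < 2) seg_times <- c(a, b)
    rhs <- compile_rhs(mm)
    tr <- ode_integrate(function(t, yy) rhs(t, yy),
                        stats::setNames(as.numeric(y[ids]), ids),
                        seg_times, rtol = rtol, atol = atol)
    y <- stats::setNames(pmax(as.numeric(tr[nrow(tr), -1]), 0), ids)
    rows[[s]] <- if (s == 1) tr else tr[-1, , drop = FALSE]
  }
  as.data.frame(do.call(rbind, rows))
}

change_direction <- function(new, base, rel_tol = 0.01) {
  d <- (new - base) / abs(base)
  ifelse(abs(d) < rel_tol, "0", ifelse(d > 0, "+", "-"))
}

#' Qualitative scenario checks for a model
#'
#' Runs one of the shipped directional validation scenarios against a
#' model instance and reports the observed sign of every assertion:
#' \describe{
#'   \item{null}{no input change; all directions must be "0".}
#'   \item{stress_step}{threefold stress input over a window; cortisol
#'     must rise above baseline during the step.}
#'   \item{glucose_load}{plasma glucose clamped 50% above baseline;
#'     insulin must rise.}
#'   \item{cytokine_challenge}{IL-6 clamped threefold above baseline;
#'     cortisol must rise (cytokine drive on the HPA axis).}
#'   \item{gr_sensitization}{GR sensitivity Hill exponents `n` and `nx`
#'     raised 1.5-fold; IL-6 and TNF must increase and the 12-feature
#'     metabolic-dysfunction signature directions must be reproduced at
#'     the new steady state.}
#' }
#'
#' @param m A [model_spec()] (the shipped reference model for the named
#'   scenarios).
#' @param scenario Scenario name.
#' @param rel_tol No-change threshold on relative change (default 1%).
#' @return data.frame with columns `assertion`, `feature`, `expected`,
#'   `observed`, `pass`; attribute `pass` gives the conjunction.
#' @export
qualitative_check <- function(m, scenario = c("null", "stress_step",
                                              "glucose_load",
                                              "cytokine_challenge",
                                              "gr_sensitization"),
                              rel_tol = 0.01) {
  scenario <- match.arg(scenario)
  base <- find_steady_state(m)
  b <- base$concentrations
  report <- switch(scenario,
    null = {
      feats <- c("cortisol", "insulin", "glucose", "il6", "tnf")
      feats <- intersect(feats, names(b))
      data.frame(assertion = "steady baseline", feature = feats,
                 expected = "0",
                 observed = change_direction(b[feats], b[feats], rel_tol))
    },
    stress_step = {
      tr <- simulate_model(m, initial = b, t_span = c(0, 40),
                           inputs = list(list(species = "stress",
                                              value = 3 * b[["stress"]],
                                              from = 5, to = 25)))
      peak <- max(tr$cortisol[tr$time >= 5 & tr$time <= 25])
      data.frame(assertion = "cortisol rises during stress step",
                 feature = "cortisol", expected = "+",
                 observed = change_direction(peak, b[["cortisol"]], rel_tol))
    },
    glucose_load = {
      tr <- simulate_model(m, initial = b, t_span = c(0, 40),
                           inputs = list(list(species = "glucose",
                                              value = 1.5 * b[["glucose"]],
                                              from = 5, to = 25)))
      peak <- max(tr$insulin[tr$time >= 5 & tr$time <= 25])
      data.frame(assertion = "insulin rises on glucose load",
                 feature = "insulin", expected = "+",
                 observed = change_direction(peak, b[["insulin"]], rel_tol))
    },
    cytokine_challenge = {
      tr <- simulate_model(m, initial = b, t_span = c(0, 40),
                           inputs = list(list(species = "il6",
                                              value = 3 * b[["il6"]],
                                              from = 5, to = 25)))
      peak <- max(tr$cortisol[tr$time >= 5 & tr$time <= 25])
      data.frame(assertion = "cortisol rises on cytokine challenge",
                 feature = "cortisol", expected = "+",
                 observed = change_direction(peak, b[["cortisol"]], rel_tol))
    },
    gr_sensitization = {
      pm <- perturb_parameters(m, c("n", "nx"), 1.5)
      ss <- find_steady_state(pm, initial = b)
      p <- ss$concentrations
      sig <- md_signature()
      feats <- c("il6", "tnf", sig$features)
      expected <- c("+", "+", ifelse(sig$signs > 0, "+", "-"))
      keep <- feats %in% names(p)
      data.frame(assertion = "GR sensitization response",
                 feature = feats[keep], expected = expected[keep],
                 observed = change_direction(p[feats[keep]], b[feats[keep]],
                                             rel_tol))
    })
  report$pass <- report$expected == report$observed
  rownames(report) <- NULL
  attr(report, "pass") <- all(report$pass)
  report
}
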