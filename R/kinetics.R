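#' Michaelis-Menten saturation term
#'
#' Hyperbolic occupancy factor `conc / (conc + km)` used as the substrate
#' factor of every saturating reaction rate.  The factor is 0 at zero
#' concentration, 0.5 at half saturation (`conc == km`) and approaches 1 as
#' the substrate saturates the enzyme.
#'
#' @param conc Substrate concentration (mM), non-negative.  Vectorized.
#' @param km Half-saturation constant (mM), strictly positive.
#' @return Fraction in `[0, 1]`, monotone increasing in `conc`.
#' @examples
#' saturation_term(1, 1)     # 0.5
#' saturation_term(3, 1)     # 0.75
#' @export
saturation_term <- function(conc, km) {
  if (any(!is.finite(km)) || any(km <= 0)) {
    stop("invalid parameter: `km` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("invalid input: `conc` must be non-negative", call. = FALSE)
  }
  conc / (conc + km)
}

#' Allosteric regulation specification
#'
#' Bundles an activator/inhibitor pair acting allosterically on one
#' reaction, with its three constants: `k_act` (activator half-effect),
#' `k_inh` (inhibitor half-effect) and `k_prod` (product-inhibition
#' constant).
#'
#' @param activator_conc,inhibitor_conc Concentrations (>= 0).
#' @param k_act,k_inh,k_prod Positive constants.
#' @return An object of class `allosteric_spec`.
#' @export
allosteric_spec <- function(activator_conc = 0, inhibitor_conc = 0,
                            k_act = 1, k_inh = 1, k_prod = 1) {
  for (k in c(k_act, k_inh, k_prod)) {
    if (!is.finite(k) || k <= 0) {
      stop("invalid parameter: allosteric constants must be positive",
           call. = FALSE)
    }
  }
  if (activator_conc < 0 || inhibitor_conc < 0) {
    stop("invalid input: allosteric concentrations must be non-negative",
         call. = FALSE)
  }
  structure(list(activator_conc = activator_conc,
                 inhibitor_conc = inhibitor_conc,
                 k_act = k_act, k_inh = k_inh, k_prod = k_prod),
            class = "allosteric_spec")
}

#' Allosteric activation, deactivation and product-inhibition factors
#'
#' For activator concentration `A` and inhibitor concentration `I`:
#' `f_act = A/(A + k_act)`, `f_deact = k_inh/(I + k_inh)` and the
#' product-inhibition factor `f_pi = A/(A + k_inh) * 1/(1 + I/k_prod)`.
#' Each factor lies in `[0, 1]`.  The `f_pi` form is read so that it
#' decreases hyperbolically in the inhibiting product `I`.
#'
#' @param spec An [allosteric_spec()].
#' @return Named list with `f_act`, `f_deact`, `f_pi`.
#' @export
allosteric_factors <- function(spec) {
  stopifnot(inherits(spec, "allosteric_spec"))
  A <- spec$activator_conc
  I <- spec$inhibitor_conc
  list(
    f_act   = A / (A + spec$k_act),
    f_deact = spec$k_inh / (I + spec$k_inh),
    f_pi    = (A / (A + spec$k_inh)) * (1 / (1 + I / spec$k_prod))
  )
}

#' Regulatory edge for signaling / transcriptional control
#'
#' One Hill-type regulatory influence of a species on a reaction.
#' Activating edges contribute `S^n / (S^n + K^n)` additively; deactivating
#' edges contribute `K^n / (I^n + K^n)` multiplicatively (see
#' [sigtrans_factor()]).
#'
#' @param regulator_id Species id of the regulator.
#' @param mode `"activate"` or `"deactivate"`.
#' @param layer `"signaling"` or `"transcription"` (metadata only; the two
#'   layers share the same algebra).
#' @param hill_n Cooperativity exponent, real-valued, `>= 1`.
#' @param k_half Half-effect constant, positive.
#' @param weight Optional per-edge scale factor on the activator
#'   contribution (dimensionless, positive).
#' @return Object of class `regulator_edge`.
#' @export
regulator_edge <- function(regulator_id, mode = c("activate", "deactivate"),
                           layer = c("signaling", "transcription"),
                           hill_n = 1, k_half = 1, weight = 1) {
  mode <- match.arg(mode)
  layer <- match.arg(layer)
  if (!is.finite(hill_n) || hill_n < 1) {
    stop("invalid parameter: `hill_n` must be >= 1", call. = FALSE)
  }
  if (!is.finite(k_half) || k_half <= 0) {
    stop("invalid parameter: `k_half` must be positive", call. = FALSE)
  }
  if (!is.finite(weight) || weight <= 0) {
    stop("invalid parameter: `weight` must be positive", call. = FALSE)
  }
  structure(list(regulator_id = regulator_id, mode = mode, layer = layer,
                 hill_n = hill_n, k_half = k_half, weight = weight),
            class = "regulator_edge")
}

hill_act <- function(s, k, n) {
  sn <- s^n
  sn / (sn + k^n)
}

hill_inh <- function(s, k, n) {
  kn <- k^n
  kn / (s^n + kn)
}

#' Signaling/transcription regulation multiplier
#'
#' Combines the Hill terms of all regulatory edges acting on one reaction
#' into a single multiplier
#' `Wf * (1 + sum of activator terms) * (prod of deactivator terms)`.
#' With no edges the multiplier equals `Wf`, so a basal-calibrated rate is
#' unchanged by an empty regulatory context.
#'
#' @param edges List of [regulator_edge()] objects (possibly empty).
#' @param state Named numeric vector of species concentrations; every
#'   referenced regulator must be present.
#' @param weight Reaction-level weighting factor `Wf` (> 0).
#' @return Non-negative multiplier, bounded above by
#'   `Wf * (1 + sum of activator edge weights)`.
#' @export
sigtrans_factor <- function(edges, state, weight = 1) {
  if (!is.finite(weight) || weight < 0) {
    stop("invalid parameter: `weight` must be non-negative", call. = FALSE)
  }
  act_sum <- 0
  inh_prod <- 1
  for (e in edges) {
    if (!e$regulator_id %in% names(state) ||
        is.na(state[[e$regulator_id]])) {
      stop("unresolved regulator: species '", e$regulator_id,
           "' not present in state", call. = FALSE)
    }
    s <- state[[e$regulator_id]]
    s <- max(s, 0)
    if (e$mode == "activate") {
      act_sum <- act_sum + e$weight * hill_act(s, e$k_half, e$hill_n)
    } else {
      inh_prod <- inh_prod * hill_inh(s, e$k_half, e$hill_n)
    }
  }
  weight * (1 + act_sum) * inh_prod
}

#' Saturating reaction rate
#'
#' `rate = vmax * prod(substrate saturation) * allosteric factors *
#' regulation multiplier`.  This is the production/consumption rate form
#' used throughout assembled models; each multiplicative block is optional.
#'
#' @param vmax Maximal rate (>= 0).
#' @param substrates List of `list(conc =, km =)` saturation terms (may be
#'   empty for a constitutive source).
#' @param allosteric Optional [allosteric_spec()]; when given, which of the
#'   three factors apply is chosen by `allosteric_use`.
#' @param allosteric_use Character subset of
#'   `c("f_act", "f_deact", "f_pi")` selecting applied allosteric factors.
#' @param regulation Optional list of [regulator_edge()]s.
#' @param state Named species state, required when `regulation` is given.
#' @param weight Regulatory weighting factor `Wf`.
#' @return Non-negative rate.
#' @export
reaction_rate <- function(vmax, substrates = list(), allosteric = NULL,
                          allosteric_use = c("f_act", "f_deact"),
                          regulation = NULL, state = NULL, weight = 1) {
  if (!is.finite(vmax) || vmax < 0) {
    stop("invalid parameter: `vmax` must be non-negative", call. = FALSE)
  }
  rate <- vmax
  for (s in substrates) {
    rate <- rate * saturation_term(max(s$conc, 0), s$km)
  }
  if (!is.null(allosteric)) {
    f <- allosteric_factors(allosteric)
    for (nm in allosteric_use) rate <- rate * f[[nm]]
  }
  if (!is.null(regulation) && length(regulation)) {
    rate <- rate * sigtrans_factor(regulation, state, weight = weight)
  } else {
    rate <- rate * weight
  }
  rate
}

#' Transport specification
#'
#' @param kind `"passive"` (linear in the blood-tissue gradient) or
#'   `"facilitated"` (carrier-mediated, difference of saturation terms).
#' @param epsilon Partition coefficient (1/time), passive transport.
#' @param t_max Maximal carrier rate, facilitated transport.
#' @param k_blood,k_tissue Half-saturation constants (mM), facilitated.
#' @return Object of class `transport_spec`.
#' @export
transport_spec <- function(kind = c("passive", "facilitated"),
                           epsilon = NULL, t_max = NULL,
                           k_blood = NULL, k_tissue = NULL) {
  if (length(kind) != 1 || !kind %in% c("passive", "facilitated")) {
    stop("configuration error: transport kind must be 'passive' or ",
         "'facilitated'", call. = FALSE)
  }
  if (kind == "passive") {
    if (is.null(epsilon) || !is.finite(epsilon) || epsilon <= 0) {
      stop("invalid parameter: passive transport requires epsilon > 0",
           call. = FALSE)
    }
  } else {
    for (k in list(t_max, k_blood, k_tissue)) {
      if (is.null(k) || !is.finite(k) || k <= 0) {
        stop("invalid parameter: facilitated transport requires positive ",
             "t_max, k_blood, k_tissue", call. = FALSE)
      }
    }
  }
  structure(list(kind = kind, epsilon = epsilon, t_max = t_max,
                 k_blood = k_blood, k_tissue = k_tissue),
            class = "transport_spec")
}

#' Blood-tissue transport rate
#'
#' Passive: `epsilon * (c_blood - c_tissue)`.  Facilitated:
#' `t_max * (c_blood/(k_blood + c_blood) - c_tissue/(k_tissue + c_tissue))`.
#' Positive values move material from blood into tissue.
#'
#' @param spec A [transport_spec()].
#' @param c_blood,c_tissue Concentrations (>= 0).
#' @return Signed rate.
#' @export
transport_rate <- function(spec, c_blood, c_tissue) {
  stopifnot(inherits(spec, "transport_spec"))
  if (c_blood < 0 || c_tissue < 0) {
    stop("invalid input: transport concentrations must be non-negative",
         call. = FALSE)
  }
  if (spec$kind == "passive") {
    spec$epsilon * (c_blood - c_tissue)
  } else {
    spec$t_max * (c_blood / (spec$k_blood + c_blood) -
                    c_tissue / (spec$k_tissue + c_tissue))
  }
}
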