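#' Declarative model specification
#'
#' A `model_spec` is the plain-data description of an ODE network:
#' species with compartments, reactions written in the saturating rate-law
#' grammar (or elementary mass action), blood-tissue transports, a named
#' parameter map, and a set of clamped species that are held constant
#' during integration (e.g. glycogen during control analysis).
#'
#' Reactions reference parameters *by name* wherever a number could be
#' perturbed (vmax, Km, Hill exponents, half-effect constants, weights), so
#' that control analysis can perturb any rate or interaction strength
#' through the parameter map alone.  Numeric literals are also accepted.
#'
#' @param species data.frame with columns `id`, `compartment`, `initial`,
#'   `role` (one of metabolite, signaling, transcription_factor, hormone,
#'   cytokine, input).
#' @param compartments data.frame with columns `id`, `volume`.
#' @param reactions list of reaction descriptors; each a list with fields
#'   `id`, `vmax` (parameter name or number), `law` ("saturating" or
#'   "mass_action"), `substrates` (list of `list(species=, km=)`; for mass
#'   action just species ids), `stoich` (named numeric, negative =
#'   consumed), optional `allosteric`, `regulators`, `weight`.
#' @param transports list of transport bindings: `list(id, species_blood,
#'   species_tissue, kind, epsilon | t_max, k_blood, k_tissue)`.
#' @param parameters named numeric vector/list.
#' @param clamps character vector of species ids held constant.
#' @return Validated object of class `model_spec`.
#' @export
model_spec <- function(species, compartments, reactions = list(),
                       transports = list(), parameters = list(),
                       clamps = character()) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  parameters <- unlist(parameters)
  if (is.null(parameters)) parameters <- numeric()
  m <- structure(list(species = species, compartments = compartments,
                      reactions = reactions, transports = transports,
                      parameters = parameters, clamps = clamps),
                 class = "model_spec")
  validate_model(m)
  m
}

pval <- function(x, pars, ctx = "parameter") {
  if (is.character(x)) {
    if (!x %in% names(pars)) {
      stop("unresolved reference: ", ctx, " '", x,
           "' not found in parameter map", call. = FALSE)
    }
    unname(pars[[x]])
  } else {
    as.numeric(x)
  }
}

#' Validate a model specification
#'
#' Checks referential integrity (species, compartments, parameters),
#' positive volumes, unique ids, and clamp resolvability.  Called by
#' [model_spec()] and [load_model()]; errors name the offending id.
#'
#' @param m A `model_spec`.
#' @return `m`, invisibly.
#' @export
validate_model <- function(m) {
  sp <- m$species
  if (nrow(sp) == 0) stop("validation error: empty species list",
                          call. = FALSE)
  if (anyDuplicated(sp$id)) {
    stop("validation error: duplicate species id '",
         sp$id[duplicated(sp$id)][1], "'", call. = FALSE)
  }
  if (any(!is.finite(m$compartments$volume)) ||
      any(m$compartments$volume <= 0)) {
    stop("validation error: compartment volumes must be positive",
         call. = FALSE)
  }
  bad <- setdiff(sp$compartment, m$compartments$id)
  if (length(bad)) {
    stop("unresolved reference: compartment '", bad[1], "'", call. = FALSE)
  }
  ids <- sp$id
  pars <- m$parameters
  need_par <- function(x, ctx) invisible(pval(x, pars, ctx))
  need_sp <- function(x, ctx) {
    if (!x %in% ids) {
      stop("unresolved reference: ", ctx, " species '", x, "'",
           call. = FALSE)
    }
  }
  for (rx in m$reactions) {
    ctx <- paste0("reaction '", rx$id, "'")
    need_par(rx$vmax, paste0(ctx, " vmax"))
    law <- rx$law %||% "saturating"
    if (!law %in% c("saturating", "mass_action")) {
      stop("validation error: unknown rate law '", law, "' in ", ctx,
           call. = FALSE)
    }
    for (s in rx$substrates) {
      if (is.character(s)) {
        need_sp(s, ctx)
      } else {
        need_sp(s$species, ctx)
        if (law == "saturating") need_par(s$km, paste0(ctx, " km"))
      }
    }
    for (nm in names(rx$stoich)) need_sp(nm, ctx)
    if (!is.null(rx$allosteric)) {
      al <- rx$allosteric
      for (f in c("activator", "inhibitor")) {
        if (!is.null(al[[f]])) need_sp(al[[f]], ctx)
      }
      for (f in c("k_act", "k_inh", "k_prod")) {
        if (!is.null(al[[f]])) need_par(al[[f]], paste0(ctx, " ", f))
      }
    }
    for (e in rx$regulators %||% list()) {
      need_sp(e$species, ctx)
      need_par(e$n %||% 1, paste0(ctx, " hill_n"))
      need_par(e$k, paste0(ctx, " k_half"))
    }
    if (!is.null(rx$weight)) need_par(rx$weight, paste0(ctx, " weight"))
  }
  for (tr in m$transports) {
    ctx <- paste0("transport '", tr$id %||% "?", "'")
    need_sp(tr$species_blood, ctx)
    need_sp(tr$species_tissue, ctx)
    if (identical(tr$kind, "passive")) {
      need_par(tr$epsilon, ctx)
    } else if (identical(tr$kind, "facilitated")) {
      for (f in c("t_max", "k_blood", "k_tissue")) {
        need_par(tr[[f]], paste0(ctx, " ", f))
      }
    } else {
      stop("configuration error: transport kind must be 'passive' or ",
           "'facilitated' in ", ctx, call. = FALSE)
    }
  }
  bad <- setdiff(m$clamps, ids)
  if (length(bad)) {
    stop("unresolved reference: clamp species '", bad[1], "'",
         call. = FALSE)
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a model specification from a JSON file
#'
#' Model documents are plain-text JSON with top-level keys `species`,
#' `compartments`, `reactions`, `transports`, `parameters`, `clamps`.
#' The result is fully resolved and validated; dangling references are
#' rejected with the offending id.
#'
#' @param path Path to the model file.
#' @return A [model_spec()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  as_df <- function(x, cols) {
    do.call(rbind, lapply(x, function(r) {
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
  }
  species <- as_df(doc$species, c("id", "compartment", "initial", "role"))
  compartments <- as_df(doc$compartments, c("id", "volume"))
  rx <- lapply(doc$reactions %||% list(), function(r) {
    r$stoich <- unlist(r$stoich)
    r
  })
  model_spec(species = species, compartments = compartments,
             reactions = rx, transports = doc$transports %||% list(),
             parameters = unlist(doc$parameters),
             clamps = as.character(unlist(doc$clamps %||% list())))
}

#' Write a model specification to JSON
#'
#' Inverse of [load_model()]; round-trips through validation.
#'
#' @param m A `model_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  stopifnot(inherits(m, "model_spec"))
  doc <- list(
    species = lapply(seq_len(nrow(m$species)), function(i) {
      as.list(m$species[i, c("id", "compartment", "initial", "role")])
    }),
    compartments = lapply(seq_len(nrow(m$compartments)), function(i) {
      as.list(m$compartments[i, c("id", "volume")])
    }),
    reactions = lapply(m$reactions, function(r) {
      r$stoich <- as.list(r$stoich)
      r
    }),
    transports = m$transports,
    parameters = as.list(m$parameters),
    clamps = as.list(m$clamps)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", nrow(x$species), "species,",
      length(x$reactions), "reactions,",
      length(x$transports), "transports,",
      length(x$parameters), "parameters,",
      length(x$clamps), "clamped\n")
  invisible(x)
}

#' Perturb model parameters by a fold factor
#'
#' Returns a copy of the model with each named parameter multiplied by
#' `fold`.  This is the elementary move of finite-perturbation control
#' analysis; passing several names perturbs them jointly.
#'
#' @param m A `model_spec`.
#' @param params Character vector of parameter names.
#' @param fold Positive multiplier.
#' @return A perturbed `model_spec`.
#' @export
perturb_parameters <- function(m, params, fold) {
  stopifnot(inherits(m, "model_spec"), fold > 0)
  missing <- setdiff(params, names(m$parameters))
  if (length(missing)) {
    stop("unresolved reference: parameter '", missing[1], "'",
         call. = FALSE)
  }
  m$parameters[params] <- m$parameters[params] * fold
  m
}
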