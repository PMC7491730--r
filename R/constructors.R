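#' Construct a ModelParams object
#'
#' All arguments default to the baseline parameterization (see
#' \linkS4class{ModelParams}).
#'
#' @param r tree growth rate (new trees per tree per year)
#' @param A pest transmission rate (per susceptible-infested contact per year)
#' @param gamma death rate of infested trees (per year)
#' @param K patch carrying capacity (trees)
#' @param U net social cost to transport firewood (utility); the public
#'   outreach lever
#' @param Ce fraction of infested firewood intercepted on every route, in
#'   [0, 1]; the checkpoint lever
#' @param f impact of local infestation on strategy choice (utility per tree)
#' @param s strength of social norms / peer pressure (utility per capita)
#' @param sigma rate of social learning (strategy changes per capita per year)
#' @param d inter-patch transmission rate of infested firewood (logs per year)
#' @param Ia infested population at which within-patch transmission is halved
#'   (trees)
#' @param k steepness of the transmission sigmoid (unitless)
#' @return a validated \linkS4class{ModelParams}
#' @examples
#' modelParams()              # baseline
#' modelParams(U = 2, Ce = 0.3)
#' @export
modelParams <- function(r = 0.02, A = 0.001, gamma = 1.4, K = 5000,
                        U = 0, Ce = 0, f = 0.1, s = 0.1,
                        sigma = 0.1, d = 0.1, Ia = 1, k = 1) {
  new("ModelParams", r = r, A = A, gamma = gamma, K = K, U = U, Ce = Ce,
      f = f, s = s, sigma = sigma, d = d, Ia = Ia, k = k)
}

#' Build ModelParams from a flat configuration mapping
#'
#' Accepts a named list (e.g. parsed from YAML/JSON) using the standard
#' parameter names \code{r, A, gamma, K, U, Ce, f, s, sigma, d, Ia, k}.
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param config named list of parameter values; missing names keep defaults
#' @return a validated \linkS4class{ModelParams}
#' @examples
#' paramsFromConfig(list(gamma = 0.8, Ce = 0.5))
#' @export
paramsFromConfig <- function(config) {
  if (is.null(config) || length(config) == 0) return(modelParams())
  valid <- c("r", "A", "gamma", "K", "U", "Ce", "f", "s", "sigma", "d", "Ia", "k")
  unknown <- setdiff(names(config), valid)
  if (length(unknown) || is.null(names(config)) || any(names(config) == ""))
    stop("unknown parameter name(s): ",
         paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "),
         "; valid names are ", paste(valid, collapse = ", "))
  do.call(modelParams, lapply(config, as.numeric))
}

#' Extract ModelParams as a named list
#' @param params a ModelParams
#' @return named list of the twelve scalars
#' @export
paramsAsList <- function(params) {
  stopifnot(is(params, "ModelParams"))
  stats::setNames(lapply(slotNames(params), function(nm) slot(params, nm)),
                  slotNames(params))
}

#' Modify a ModelParams object
#'
#' Returns a copy of \code{params} with the named parameters replaced.
#'
#' @param params a ModelParams
#' @param ... name = value pairs using the standard parameter names
#' @return a new validated ModelParams
#' @examples
#' updateParams(modelParams(), Ce = 0.5, U = -1)
#' @export
updateParams <- function(params, ...) {
  changes <- list(...)
  cfg <- paramsAsList(params)
  valid <- names(cfg)
  unknown <- setdiff(names(changes), valid)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  cfg[names(changes)] <- changes
  do.call(modelParams, cfg)
}

#' Construct a QuarantinePolicy
#'
#' @param nodes character vector of patch ids to quarantine (empty = none)
#' @param t0 start of the quarantine window (years)
#' @param deltaT duration of the window (years)
#' @return a validated \linkS4class{QuarantinePolicy}
#' @examples
#' quarantinePolicy()                       # no quarantine
#' quarantinePolicy(c("n1", "n7"), t0 = 1, deltaT = 3)
#' @export
quarantinePolicy <- function(nodes = character(), t0 = 0, deltaT = 0) {
  new("QuarantinePolicy", nodes = as.character(nodes), t0 = t0, deltaT = deltaT)
}

#' Construct InitialConditions for the focal-seed scenario
#'
#' @param focalNode id of the patch where the pest is introduced
#' @param focalInfestedFraction fraction of K initially infested there
#'   (default 1: the bulk host population is infested)
#' @param backgroundL initial local-strategist fraction everywhere
#'   (default 0.5, the neutral replicator point at U = 0)
#' @param backgroundB initial infested firewood everywhere (default 0)
#' @return a validated \linkS4class{InitialConditions}
#' @export
initialConditions <- function(focalNode, focalInfestedFraction = 1,
                              backgroundL = 0.5, backgroundB = 0) {
  new("InitialConditions", focalNode = as.character(focalNode),
      focalInfestedFraction = focalInfestedFraction,
      backgroundL = backgroundL, backgroundB = backgroundB)
}

#' Construct a SystemState
#' @param S,I,B,L,T equal-length per-patch vectors (see
#'   \linkS4class{SystemState})
#' @return a validated SystemState
#' @export
systemState <- function(S, I, B, L, T) {
  new("SystemState", S = as.numeric(S), I = as.numeric(I), B = as.numeric(B),
      L = as.numeric(L), T = as.numeric(T))
}

#' Bundle a complete simulation setup
#'
#' @param network a TravelNetwork
#' @param params a ModelParams (default baseline)
#' @param init InitialConditions; default seeds the network's focal node
#'   (or its first node if no focal flag is present) at full infestation
#' @param policy a QuarantinePolicy (default: none)
#' @param tEnd simulation horizon in years (default 20)
#' @param sampleEvery sampling cadence in years (default 0.1)
#' @param rtol,atol solver tolerances (defaults 1e-6, 1e-8)
#' @return a validated \linkS4class{SimulationScenario}
#' @export
simulationScenario <- function(network, params = modelParams(),
                               init = NULL, policy = quarantinePolicy(),
                               tEnd = 20, sampleEvery = 0.1,
                               rtol = 1e-6, atol = 1e-8) {
  if (is.null(init)) {
    meta <- nodeMeta(network)
    focal <- if (nrow(meta) > 0 && any(meta$isFocal))
      meta$id[meta$isFocal][1] else nodeIds(network)[1]
    init <- initialConditions(focal)
  }
  new("SimulationScenario", network = network, params = params, init = init,
      policy = policy, tEnd = tEnd, sampleEvery = sampleEvery,
      rtol = rtol, atol = atol)
}
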