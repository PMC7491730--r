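#' @import methods
NULL

.STOCH_TOL <- 1e-9

#' TravelNetwork: a directed, column-stochastic camper travel network
#'
#' Holds the patch identifiers and the trip-fraction matrix \eqn{P}, where
#' entry \eqn{P[i, j]} is the fraction of annual camper trips originating at
#' patch \eqn{j} that end at patch \eqn{i}. Every column sums to one:
#' each origin's outgoing trips are a probability distribution over
#' destinations. Optional per-node metadata (planar coordinates, population
#' weight, focal flag) supports the synthetic generator and focal-seed
#' scenarios.
#'
#' @slot nodeIds character vector of unique patch identifiers (length N >= 2);
#'   fixes the row/column order of \code{tripFraction}.
#' @slot tripFraction N x N numeric matrix, entries in [0, 1], columns summing
#'   to 1 within 1e-9. Self-loops (diagonal entries) are permitted and count
#'   in the normalization, but the transport dynamics skip them.
#' @slot nodeMeta data.frame with one row per node (columns \code{id},
#'   \code{x}, \code{y}, \code{population}, \code{isFocal}); may have zero
#'   rows when no metadata is available. At most one node may be focal.
#'
#' @seealso [loadTripTable()], [generateSyntheticNetwork()], [kCoreReduce()]
#' @export
setClass("TravelNetwork",
  slots = c(
    nodeIds = "character",
    tripFraction = "matrix",
    nodeMeta = "data.frame"
  )
)

setValidity("TravelNetwork", function(object) {
  msgs <- character()
  n <- length(object@nodeIds)
  P <- object@tripFraction
  if (n < 2) msgs <- c(msgs, "a TravelNetwork needs at least 2 nodes")
  if (anyDuplicated(object@nodeIds)) msgs <- c(msgs, "node ids must be unique")
  if (!is.numeric(P) || nrow(P) != n || ncol(P) != n) {
    msgs <- c(msgs, sprintf("tripFraction must be a %d x %d numeric matrix", n, n))
  } else {
    if (any(!is.finite(P))) msgs <- c(msgs, "tripFraction has non-finite entries")
    else {
      if (min(P) < -.STOCH_TOL || max(P) > 1 + .STOCH_TOL)
        msgs <- c(msgs, "tripFraction entries must lie in [0, 1]")
      cs <- colSums(P)
      if (any(abs(cs - 1) > .STOCH_TOL))
        msgs <- c(msgs, sprintf(
          "tripFraction columns must sum to 1 (worst deviation %.3g)",
          max(abs(cs - 1))))
    }
  }
  if (nrow(object@nodeMeta) > 0) {
    need <- c("id", "population", "isFocal")
    if (!all(need %in% names(object@nodeMeta)))
      msgs <- c(msgs, "nodeMeta must have columns id, population, isFocal")
    else {
      if (!setequal(object@nodeMeta$id, object@nodeIds))
        msgs <- c(msgs, "nodeMeta ids must match nodeIds")
      if (any(object@nodeMeta$population < 0, na.rm = TRUE))
        msgs <- c(msgs, "populations must be nonnegative")
      if (sum(object@nodeMeta$isFocal) > 1)
        msgs <- c(msgs, "at most one node may be flagged focal")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelParams: scalar parameters of the pest/social dynamics
#'
#' The twelve scalar parameters governing per-patch pest dynamics, social
#' learning, and the interception intervention. Defaults are the baseline
#' values used throughout: logistic tree growth rate \code{r} = 0.02/yr,
#' transmission rate \code{A} = 0.001 per susceptible-infested contact per
#' year, infested-tree death rate \code{gamma} = 1.4/yr, carrying capacity
#' \code{K} = 5000 trees, net social cost of transport \code{U} = 0,
#' interception fraction \code{Ce} = 0, infestation impact on strategy
#' \code{f} = 0.1, social-norm strength \code{s} = 0.1, social learning rate
#' \code{sigma} = 0.1/yr, inter-patch firewood transmission rate
#' \code{d} = 0.1 logs/yr, half-saturation infestation \code{Ia} = 1 tree,
#' and sigmoid steepness \code{k} = 1.
#'
#' @seealso [modelParams()], [paramsFromConfig()]
#' @export
setClass("ModelParams",
  slots = c(
    r = "numeric", A = "numeric", gamma = "numeric", K = "numeric",
    U = "numeric", Ce = "numeric", f = "numeric", s = "numeric",
    sigma = "numeric", d = "numeric", Ia = "numeric", k = "numeric"
  ),
  prototype = prototype(
    r = 0.02, A = 0.001, gamma = 1.4, K = 5000,
    U = 0, Ce = 0, f = 0.1, s = 0.1,
    sigma = 0.1, d = 0.1, Ia = 1, k = 1
  )
)

setValidity("ModelParams", function(object) {
  msgs <- character()
  for (nm in slotNames(object)) {
    v <- slot(object, nm)
    if (length(v) != 1 || !is.finite(v))
      msgs <- c(msgs, sprintf("parameter '%s' must be a single finite number", nm))
  }
  if (!length(msgs)) {
    nonneg <- c("r", "A", "gamma", "f", "s", "sigma", "d", "Ia")
    for (nm in nonneg) if (slot(object, nm) < 0)
      msgs <- c(msgs, sprintf("parameter '%s' must be nonnegative", nm))
    if (object@K <= 0) msgs <- c(msgs, "carrying capacity K must be positive")
    if (object@Ce < 0 || object@Ce > 1)
      msgs <- c(msgs, "interception fraction Ce must lie in [0, 1]")
    if (object@k <= 0) msgs <- c(msgs, "sigmoid steepness k must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' SystemState: per-patch state of the coupled system
#'
#' Five equal-length vectors indexed by patch: susceptible trees \code{S},
#' infested trees \code{I}, infested firewood \code{B}, local-strategist
#' fraction \code{L} (in [0, 1]), and the cumulative infestation tracker
#' \code{T} (running integral of new infestations; never decreases).
#'
#' @export
setClass("SystemState",
  slots = c(S = "numeric", I = "numeric", B = "numeric",
            L = "numeric", T = "numeric")
)

setValidity("SystemState", function(object) {
  msgs <- character()
  n <- length(object@S)
  lens <- c(length(object@I), length(object@B), length(object@L), length(object@T))
  if (any(lens != n)) msgs <- c(msgs, "state vectors must have equal length")
  slack <- 1e-6
  if (any(object@S < -slack) || any(object@I < -slack) ||
      any(object@B < -slack) || any(object@T < -slack))
    msgs <- c(msgs, "S, I, B, T must be nonnegative")
  if (any(object@L < -slack) || any(object@L > 1 + slack))
    msgs <- c(msgs, "L must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' QuarantinePolicy: time-windowed closure of a set of patches
#'
#' During the window [t0, t0 + deltaT], patches in \code{nodes} neither
#' import nor export firewood; every transport term with a quarantined
#' endpoint is switched off by an upside-down boxcar gate. An empty node set
#' means no quarantine.
#'
#' @slot nodes character vector of quarantined patch ids (may be empty).
#' @slot t0 quarantine start time (years since simulation start).
#' @slot deltaT quarantine duration (years).
#' @seealso [quarantinePolicy()], [quarantineNodeSelection()]
#' @export
setClass("QuarantinePolicy",
  slots = c(nodes = "character", t0 = "numeric", deltaT = "numeric"),
  prototype = prototype(nodes = character(), t0 = 0, deltaT = 0)
)

setValidity("QuarantinePolicy", function(object) {
  msgs <- character()
  if (length(object@t0) != 1 || object@t0 < 0)
    msgs <- c(msgs, "t0 must be a single nonnegative number")
  if (length(object@deltaT) != 1 || object@deltaT < 0)
    msgs <- c(msgs, "deltaT must be a single nonnegative number")
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "quarantined node ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' InitialConditions: focal-seed starting state specification
#'
#' Describes the introduction scenario: one focal patch (the large-urban-
#' center analogue) starts with a fraction of its carrying capacity
#' infested; all other patches start fully susceptible. The local-strategist
#' fraction starts uniform at \code{backgroundL} (default 0.5, the neutral
#' replicator point when U = 0 and no infestation) and firewood at
#' \code{backgroundB} (default 0).
#'
#' @seealso [initialConditions()], [buildInitialState()]
#' @export
setClass("InitialConditions",
  slots = c(focalNode = "character", focalInfestedFraction = "numeric",
            backgroundL = "numeric", backgroundB = "numeric"),
  prototype = prototype(focalInfestedFraction = 1, backgroundL = 0.5,
                        backgroundB = 0)
)

setValidity("InitialConditions", function(object) {
  msgs <- character()
  if (length(object@focalNode) != 1)
    msgs <- c(msgs, "exactly one focal node must be named")
  if (object@focalInfestedFraction < 0 || object@focalInfestedFraction > 1)
    msgs <- c(msgs, "focalInfestedFraction must lie in [0, 1]")
  if (object@backgroundL < 0 || object@backgroundL > 1)
    msgs <- c(msgs, "backgroundL must lie in [0, 1]")
  if (object@backgroundB < 0)
    msgs <- c(msgs, "backgroundB must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: time-indexed record of a simulation run
#'
#' Stores the sampled per-patch states as time-by-patch matrices (one per
#' state variable) plus the provenance needed to reproduce the run
#' (parameters, policy, initial conditions, solver settings, network
#' fingerprint).
#'
#' @slot times strictly increasing sample times (years).
#' @slot S,I,B,L,T numeric matrices, \code{length(times)} rows by N columns.
#' @slot nodeIds patch identifiers naming the columns.
#' @slot provenance list recording the inputs of the run.
#' @seealso [runSimulation()], [networkAverages()], [infestedPatchCount()]
#' @export
setClass("Trajectory",
  slots = c(times = "numeric", S = "matrix", I = "matrix", B = "matrix",
            L = "matrix", T = "matrix", nodeIds = "character",
            provenance = "list")
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  nt <- length(object@times)
  n <- length(object@nodeIds)
  if (nt < 1) msgs <- c(msgs, "trajectory must contain at least one sample")
  if (nt > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "sample times must be strictly increasing")
  for (nm in c("S", "I", "B", "L", "T")) {
    m <- slot(object, nm)
    if (nrow(m) != nt || ncol(m) != n)
      msgs <- c(msgs, sprintf("%s matrix must be %d x %d", nm, nt, n))
  }
  slack <- 1e-6
  if (!length(msgs)) {
    if (min(object@S, object@I, object@B, object@T) < -slack)
      msgs <- c(msgs, "stored states must be nonnegative")
    if (min(object@L) < -slack || max(object@L) > 1 + slack)
      msgs <- c(msgs, "stored L must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' SweepResult: metric surface over a 2-D parameter grid
#'
#' @slot axis1Name,axis2Name swept quantity names.
#' @slot axis1Values,axis2Values grid values (axis1 indexes rows).
#' @slot metricName name of the summary statistic evaluated per cell.
#' @slot values numeric matrix, length(axis1Values) x length(axis2Values).
#' @slot provenance list (scenario settings, evaluation horizon, policy).
#' @seealso [parameterSweep2d()], [quarantineSweep()]
#' @export
setClass("SweepResult",
  slots = c(axis1Name = "character", axis1Values = "numeric",
            axis2Name = "character", axis2Values = "numeric",
            metricName = "character", values = "matrix",
            provenance = "list")
)

setValidity("SweepResult", function(object) {
  msgs <- character()
  if (nrow(object@values) != length(object@axis1Values) ||
      ncol(object@values) != length(object@axis2Values))
    msgs <- c(msgs, "values matrix dimensions must match axis lengths")
  if (length(msgs)) msgs else TRUE
})

#' SimulationScenario: a complete, reusable simulation setup
#'
#' Bundles a network, parameters, initial conditions, quarantine policy and
#' solver settings so that sweep operations can vary one or two quantities
#' while holding everything else fixed.
#'
#' @seealso [simulationScenario()], [parameterSweep2d()]
#' @export
setClass("SimulationScenario",
  slots = c(network = "TravelNetwork", params = "ModelParams",
            init = "InitialConditions", policy = "QuarantinePolicy",
            tEnd = "numeric", sampleEvery = "numeric",
            rtol = "numeric", atol = "numeric")
)

setValidity("SimulationScenario", function(object) {
  msgs <- character()
  if (object@tEnd <= 0) msgs <- c(msgs, "tEnd must be positive")
  if (object@sampleEvery <= 0) msgs <- c(msgs, "sampleEvery must be positive")
  if (!object@init@focalNode %in% object@network@nodeIds)
    msgs <- c(msgs, sprintf("focal node '%s' is not in the network",
                            object@init@focalNode))
  bad <- setdiff(object@policy@nodes, object@network@nodeIds)
  if (length(bad))
    msgs <- c(msgs, sprintf("quarantined nodes not in network: %s",
                            paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})
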