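#' Number of patches in an object
#' @param x a TravelNetwork, SystemState or Trajectory
#' @return integer patch count
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' Patch identifiers
#' @param x a TravelNetwork or Trajectory
#' @return character vector of node ids, in matrix order
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Trip-fraction matrix accessor
#' @param x a TravelNetwork
#' @return the column-stochastic N x N matrix P (P[i, j] = fraction of trips
#'   from j that go to i), with node ids as dimnames
#' @export
setGeneric("tripFraction", function(x) standardGeneric("tripFraction"))

#' Node metadata accessor
#' @param x a TravelNetwork
#' @return data.frame of per-node records (possibly zero rows)
#' @export
setGeneric("nodeMeta", function(x) standardGeneric("nodeMeta"))

#' Sample times of a trajectory
#' @param x a Trajectory
#' @return numeric vector of sample times in years
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' Per-patch state matrix of a trajectory
#' @param x a Trajectory
#' @param variable one of "S", "I", "B", "L", "T"
#' @return time-by-patch numeric matrix
#' @export
setGeneric("stateMatrix", function(x, variable) standardGeneric("stateMatrix"))

#' @describeIn nPatches patch count of a network
#' @export
setMethod("nPatches", "TravelNetwork", function(x) length(x@nodeIds))

#' @describeIn nPatches patch count of a state
#' @export
setMethod("nPatches", "SystemState", function(x) length(x@S))

#' @describeIn nPatches patch count of a trajectory
#' @export
setMethod("nPatches", "Trajectory", function(x) length(x@nodeIds))

#' @describeIn nodeIds node ids of a network
#' @export
setMethod("nodeIds", "TravelNetwork", function(x) x@nodeIds)

#' @describeIn nodeIds node ids of a trajectory
#' @export
setMethod("nodeIds", "Trajectory", function(x) x@nodeIds)

#' @describeIn tripFraction matrix of a network
#' @export
setMethod("tripFraction", "TravelNetwork", function(x) {
  P <- x@tripFraction
  dimnames(P) <- list(x@nodeIds, x@nodeIds)
  P
})

#' @describeIn nodeMeta metadata of a network
#' @export
setMethod("nodeMeta", "TravelNetwork", function(x) x@nodeMeta)

#' @describeIn sampleTimes times of a trajectory
#' @export
setMethod("sampleTimes", "Trajectory", function(x) x@times)

#' @describeIn stateMatrix state matrix of a trajectory
#' @export
setMethod("stateMatrix", "Trajectory", function(x, variable) {
  variable <- match.arg(variable, c("S", "I", "B", "L", "T"))
  m <- slot(x, variable)
  dimnames(m) <- list(NULL, x@nodeIds)
  m
})

setMethod("show", "TravelNetwork", function(object) {
  n <- length(object@nodeIds)
  P <- object@tripFraction
  nEdges <- sum(P > 0) - sum(diag(P) > 0)
  cat(sprintf("TravelNetwork with %d patches, %d directed edges\n", n, nEdges))
  if (nrow(object@nodeMeta) > 0 && any(object@nodeMeta$isFocal)) {
    cat(sprintf("  focal node: %s\n",
                object@nodeMeta$id[object@nodeMeta$isFocal][1]))
  }
  cat(sprintf("  column-stochastic trip fractions; max off-diagonal P = %.4g\n",
              maxOffDiagonal(P)))
  invisible(object)
})

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams:\n")
  for (nm in slotNames(object))
    cat(sprintf("  %-6s %g\n", nm, slot(object, nm)))
  invisible(object)
})

setMethod("show", "QuarantinePolicy", function(object) {
  if (length(object@nodes) == 0) {
    cat("QuarantinePolicy: no quarantine\n")
  } else {
    cat(sprintf("QuarantinePolicy: %d patches closed over [%g, %g] years\n",
                length(object@nodes), object@t0, object@t0 + object@deltaT))
  }
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d patches sampled at %d times over [%g, %g] years\n",
              length(object@nodeIds), length(object@times),
              min(object@times), max(object@times)))
  fin <- networkAverages(object)
  last <- fin[nrow(fin), ]
  cat(sprintf("  final network averages: S=%.1f I=%.3g B=%.3g L=%.3f T=%.1f\n",
              last$S, last$I, last$B, last$L, last$T))
  invisible(object)
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %s over %s (%d) x %s (%d)\n",
              object@metricName,
              object@axis1Name, length(object@axis1Values),
              object@axis2Name, length(object@axis2Values)))
  cat(sprintf("  metric range: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf("SimulationScenario: %d patches, t in [0, %g] years, seed node '%s'\n",
              nPatches(object@network), object@tEnd, object@init@focalNode))
  invisible(object)
})
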