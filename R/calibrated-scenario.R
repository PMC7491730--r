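#' Calibrated synthetic focal-seed scenario
#'
#' Builds the standard study setup at a configurable size: a synthetic
#' gravity-model travel network, the focal (largest-urban-center analogue)
#' patch seeded at full infestation, and baseline parameters with the
#' transmission rates calibrated so that the uncontrolled invasion infests
#' the whole network and kills at least 95% of the tree population within
#' 10 to 15 years (d = 0.2 logs/yr, A = 0.0012 at the default 100-node
#' size; all other parameters at their baseline values).
#'
#' @param nNodes network size (default 100)
#' @param seed RNG seed for the synthetic network
#' @param params parameters (default: baseline with d = 0.2, A = 0.0012)
#' @param tEnd horizon in years (default 20)
#' @param sampleEvery sampling cadence (default 0.1 years)
#' @param ... further arguments to [generateSyntheticNetwork()]
#' @return a \linkS4class{SimulationScenario}
#' @examples
#' sc <- calibratedScenario(seed = 1)
#' traj <- runScenario(sc)
#' tail(networkAverages(traj))
#' @export
calibratedScenario <- function(nNodes = 100, seed,
                               params = modelParams(d = 0.2, A = 0.0012),
                               tEnd = 20, sampleEvery = 0.1, ...) {
  net <- generateSyntheticNetwork(nNodes, seed = seed, ...)
  simulationScenario(net, params = params, tEnd = tEnd,
                     sampleEvery = sampleEvery)
}
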