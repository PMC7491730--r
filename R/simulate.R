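## Time integration of the coupled system, focal-seed initial conditions,
## and summary time series.

#' Build the focal-seed initial state
#'
#' All patches start at carrying capacity \code{K} fully susceptible,
#' except the focal patch, where a fraction of \code{K} is infested
#' (\code{I = focalInfestedFraction * K}, \code{S = K - I}). Firewood
#' starts at \code{backgroundB} and the local-strategist fraction at
#' \code{backgroundL} everywhere. The cumulative tracker starts at
#' \code{T = I(0)} so that seeded infestations are counted.
#'
#' @param network a TravelNetwork
#' @param init an \linkS4class{InitialConditions}
#' @param params a ModelParams (supplies K)
#' @return a \linkS4class{SystemState}
#' @examples
#' net <- generateSyntheticNetwork(10, seed = 1)
#' buildInitialState(net, initialConditions(nodeIds(net)[3]))
#' @export
buildInitialState <- function(network, init, params = modelParams()) {
  ids <- nodeIds(network)
  if (!init@focalNode %in% ids)
    stop(sprintf("focal node '%s' is not in the network", init@focalNode))
  n <- length(ids)
  I <- numeric(n)
  I[ids == init@focalNode] <- init@focalInfestedFraction * params@K
  systemState(S = params@K - I, I = I,
              B = rep(init@backgroundB, n),
              L = rep(init@backgroundL, n),
              T = I)
}

packState <- function(state) c(state@S, state@I, state@B, state@L, state@T)

unpackState <- function(y, n) {
  list(S = y[seq_len(n)], I = y[n + seq_len(n)], B = y[2 * n + seq_len(n)],
       L = y[3 * n + seq_len(n)], T = y[4 * n + seq_len(n)])
}

networkFingerprint <- function(network) {
  P <- network@tripFraction
  sprintf("N=%d;sumP=%.12g;maxP=%.12g", nrow(P), sum(P), maxOffDiagonal(P))
}

#' Integrate the coupled system over time
#'
#' Adaptive integration (lsoda) of the coupled pest/social dynamics. When a
#' quarantine policy is active the integration is segmented at \code{t0}
#' and \code{t0 + deltaT} so the discontinuous boxcar gate never crosses a
#' solver step; the gate is constant within each segment. The local-
#' strategist fraction is clamped to [0, 1] and tiny negative undershoots
#' (above -1e-6) in the other components are clamped to zero at sampling;
#' larger undershoots abort the run.
#'
#' @param network a TravelNetwork
#' @param params a ModelParams (default baseline)
#' @param policy a QuarantinePolicy (default: none)
#' @param init an InitialConditions (default seeds the focal or first node),
#'   or a \linkS4class{SystemState} giving the full starting state directly
#' @param tEnd horizon in years (default 20)
#' @param sampleEvery sampling cadence in years (default 0.1)
#' @param rtol,atol solver tolerances (defaults 1e-6, 1e-8)
#' @return a \linkS4class{Trajectory}
#' @examples
#' net <- generateSyntheticNetwork(20, seed = 1)
#' traj <- runSimulation(net, tEnd = 5)
#' head(networkAverages(traj))
#' @export
runSimulation <- function(network, params = modelParams(),
                          policy = quarantinePolicy(), init = NULL,
                          tEnd = 20, sampleEvery = 0.1,
                          rtol = 1e-6, atol = 1e-8) {
  if (tEnd <= 0) stop("tEnd must be positive")
  if (sampleEvery <= 0) stop("sampleEvery must be positive")
  if (is.null(init)) {
    meta <- nodeMeta(network)
    focal <- if (nrow(meta) > 0 && any(meta$isFocal))
      meta$id[meta$isFocal][1] else nodeIds(network)[1]
    init <- initialConditions(focal)
  }
  bad <- setdiff(policy@nodes, nodeIds(network))
  if (length(bad))
    stop("quarantined nodes not in network: ", paste(bad, collapse = ", "))

  n <- nPatches(network)
  if (is(init, "SystemState")) {
    if (length(init@S) != n)
      stop(sprintf("initial state has %d patches but network has %d",
                   length(init@S), n))
    state0 <- init
    init <- NULL
  } else {
    state0 <- buildInitialState(network, init, params)
  }
  ctx <- rhsContext(params, network, policy)

  sampleTimes <- seq(0, tEnd, by = sampleEvery)
  if (sampleTimes[length(sampleTimes)] < tEnd)
    sampleTimes <- c(sampleTimes, tEnd)

  # segment boundaries where the quarantine gate switches
  cuts <- numeric()
  if (length(policy@nodes) && policy@deltaT > 0) {
    cuts <- c(policy@t0, policy@t0 + policy@deltaT)
    cuts <- cuts[cuts > 0 & cuts < tEnd]
  }
  bounds <- sort(unique(c(0, cuts, tEnd)))

  deriv <- function(t, y, parms) {
    st <- unpackState(y, n)
    d <- rhsEval(st, ctx, parms$gateOn)
    list(c(d$dS, d$dI, d$dB, d$dL, d$dT))
  }

  y <- packState(state0)
  rows <- matrix(NA_real_, length(sampleTimes), 5 * n)
  rows[1, ] <- y
  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    mid <- (a + b) / 2
    gateOn <- if (length(policy@nodes))
      boxcarOffWindow(mid - policy@t0, policy@deltaT) else 1
    inside <- sampleTimes[sampleTimes > a & sampleTimes < b]
    segTimes <- sort(unique(c(a, inside, b)))
    sol <- deSolve::ode(y = y, times = segTimes, func = deriv,
                        parms = list(gateOn = gateOn), method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE solver failed near t = %.4g years",
                   sol[nrow(sol), 1]))
    soly <- sol[, -1, drop = FALSE]
    keep <- match(round(segTimes, 12), round(sampleTimes, 12))
    ok <- !is.na(keep)
    rows[keep[ok], ] <- soly[ok, , drop = FALSE]
    y <- soly[nrow(soly), ]
  }

  worst <- min(rows)
  if (worst < -1e-6)
    stop(sprintf("state went negative beyond tolerance (min = %.3g)", worst))
  rows[rows < 0] <- 0
  Lcols <- 3 * n + seq_len(n)
  rows[, Lcols][rows[, Lcols] > 1] <- 1

  new("Trajectory",
      times = sampleTimes,
      S = rows[, seq_len(n), drop = FALSE],
      I = rows[, n + seq_len(n), drop = FALSE],
      B = rows[, 2 * n + seq_len(n), drop = FALSE],
      L = rows[, Lcols, drop = FALSE],
      T = rows[, 4 * n + seq_len(n), drop = FALSE],
      nodeIds = nodeIds(network),
      provenance = list(
        params = paramsAsList(params),
        policy = list(nodes = policy@nodes, t0 = policy@t0,
                      deltaT = policy@deltaT),
        init = if (is.null(init)) list(kind = "explicit state") else
          list(focalNode = init@focalNode,
               focalInfestedFraction = init@focalInfestedFraction,
               backgroundL = init@backgroundL,
               backgroundB = init@backgroundB),
        solver = list(method = "lsoda", rtol = rtol, atol = atol,
                      tEnd = tEnd, sampleEvery = sampleEvery),
        network = networkFingerprint(network)
      ))
}

#' Run a bundled scenario
#'
#' Convenience wrapper: integrates the scenario's network, parameters,
#' policy and initial conditions with its solver settings.
#'
#' @param scenario a \linkS4class{SimulationScenario}
#' @param params optional ModelParams overriding the scenario's
#' @param policy optional QuarantinePolicy overriding the scenario's
#' @return a \linkS4class{Trajectory}
#' @export
runScenario <- function(scenario, params = NULL, policy = NULL) {
  runSimulation(scenario@network,
                params = if (is.null(params)) scenario@params else params,
                policy = if (is.null(policy)) scenario@policy else policy,
                init = scenario@init, tEnd = scenario@tEnd,
                sampleEvery = scenario@sampleEvery,
                rtol = scenario@rtol, atol = scenario@atol)
}

#' Network-average time series
#'
#' Unweighted patch means of each state variable at each sample time:
#' \eqn{I(t) = (1/N) \sum_i I_i(t)} and likewise for S, B, L, T.
#'
#' @param trajectory a Trajectory
#' @return data.frame with columns time, S, I, B, L, T
#' @export
networkAverages <- function(trajectory) {
  data.frame(time = trajectory@times,
             S = rowMeans(trajectory@S),
             I = rowMeans(trajectory@I),
             B = rowMeans(trajectory@B),
             L = rowMeans(trajectory@L),
             T = rowMeans(trajectory@T))
}

#' Count of infested patches over time
#'
#' @param trajectory a Trajectory
#' @param threshold patch counts as infested when I_i >= threshold
#'   (default 1 tree)
#' @return data.frame with columns time, count
#' @export
infestedPatchCount <- function(trajectory, threshold = 1) {
  if (threshold < 0) stop("threshold must be nonnegative")
  data.frame(time = trajectory@times,
             count = rowSums(trajectory@I >= threshold))
}

#' Export a trajectory as long-format CSV
#'
#' One row per (time, patch) pair with columns
#' \code{time, patch_id, S, I, B, L, T}.
#'
#' @param trajectory a Trajectory
#' @param file output path
#' @return invisibly, the exported data.frame
#' @seealso [readTrajectoryCSV()]
#' @export
writeTrajectoryCSV <- function(trajectory, file) {
  nt <- length(trajectory@times)
  n <- length(trajectory@nodeIds)
  df <- data.frame(
    time = rep(trajectory@times, each = n),
    patch_id = rep(trajectory@nodeIds, times = nt),
    S = as.vector(t(trajectory@S)),
    I = as.vector(t(trajectory@I)),
    B = as.vector(t(trajectory@B)),
    L = as.vector(t(trajectory@L)),
    T = as.vector(t(trajectory@T)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a long-format trajectory CSV back into a Trajectory
#'
#' Inverse of [writeTrajectoryCSV()]. Provenance is not stored in the CSV,
#' so the returned object records only the source file.
#'
#' @param file path written by [writeTrajectoryCSV()]
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectoryCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  times <- sort(unique(df$time))
  ids <- unique(df$patch_id[df$time == times[1]])
  grab <- function(v) {
    m <- matrix(df[[v]], nrow = length(times), ncol = length(ids), byrow = TRUE)
    m
  }
  df <- df[order(df$time, match(df$patch_id, ids)), , drop = FALSE]
  new("Trajectory", times = times,
      S = grab("S"), I = grab("I"), B = grab("B"), L = grab("L"),
      T = grab("T"), nodeIds = as.character(ids),
      provenance = list(source = file))
}

#' Write a compact JSON summary of a trajectory
#'
#' Stores the network-average time series and the run provenance; round-
#' trips through [jsonlite::fromJSON()].
#'
#' @param trajectory a Trajectory
#' @param file output path
#' @return invisibly, the summary list
#' @export
writeTrajectorySummaryJSON <- function(trajectory, file) {
  summary <- list(averages = networkAverages(trajectory),
                  nPatches = length(trajectory@nodeIds),
                  provenance = trajectory@provenance)
  jsonlite::write_json(summary, file, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
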