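## Assessment statistics and sweep experiments: cumulative-infestation
## summaries, the marginal-benefit-of-outreach slope, 2-D parameter sweeps,
## quarantine sweeps, and the halving-interception search.

#' Mean cumulative infested population at a horizon
#'
#' The damage metric: \eqn{(1/N) \sum_i T_i(\bar t)}, the per-patch average
#' of the cumulative infestation tracker, linearly interpolated between
#' sample times if the horizon falls between samples.
#'
#' @param trajectory a Trajectory
#' @param tBar evaluation horizon (years), inside the trajectory span
#' @return mean cumulative infested trees per patch
#' @export
meanCumulativeInfestation <- function(trajectory, tBar) {
  times <- trajectory@times
  if (tBar < min(times) || tBar > max(times))
    stop(sprintf("tBar = %g is outside the trajectory span [%g, %g]",
                 tBar, min(times), max(times)))
  Tbar <- rowMeans(trajectory@T)
  stats::approx(times, Tbar, xout = tBar)$y
}

#' Least-squares slope of metric values over a grid
#'
#' Ordinary least squares fit of \code{values ~ grid}; the slope is the
#' first-order sensitivity of the metric to the swept quantity.
#'
#' @param grid numeric vector (>= 2 distinct values)
#' @param values metric values, same length
#' @return the fitted slope
#' @export
fitMarginalSlope <- function(grid, values) {
  if (length(grid) < 2 || length(unique(grid)) < 2)
    stop("grid must contain at least 2 distinct values")
  if (length(values) != length(grid))
    stop("grid and values must have equal length")
  unname(stats::coef(stats::lm(values ~ grid))[2])
}

#' Marginal benefit of raising the social cost of transport
#'
#' Runs the full simulation for each value of the net transport cost
#' \code{U} on a grid (default 11 evenly spaced points on [-5, 5]),
#' computes the mean cumulative infestation at the horizon, and fits a
#' linear function of U. A negative slope means raising U (more outreach)
#' reduces total infestation; a positive slope means it is neutral or
#' detrimental.
#'
#' @param scenario a \linkS4class{SimulationScenario}
#' @param UGrid grid of U values (default \code{seq(-5, 5, length.out = 11)})
#' @param tBar evaluation horizon (years)
#' @return list with \code{slope} (trees per utility unit), \code{U} and
#'   \code{metric} (the per-U metric values)
#' @export
marginalBenefitSlope <- function(scenario, UGrid = seq(-5, 5, length.out = 11),
                                 tBar = scenario@tEnd) {
  if (length(UGrid) < 2 || length(unique(UGrid)) < 2)
    stop("UGrid must contain at least 2 distinct values")
  metric <- vapply(UGrid, function(u) {
    traj <- runScenario(scenario, params = updateParams(scenario@params, U = u))
    meanCumulativeInfestation(traj, tBar)
  }, numeric(1))
  list(slope = fitMarginalSlope(UGrid, metric), U = UGrid, metric = metric)
}

sweepCache <- function() new.env(parent = emptyenv())

cacheKey <- function(...) {
  paste(vapply(list(...), function(x)
    paste(format(x, digits = 17), collapse = ","), character(1)),
    collapse = "|")
}

evalMetricCell <- function(scenario, params, tBar, metric, UGrid, cache) {
  key <- cacheKey(unlist(paramsAsList(params)), tBar, metric)
  if (!is.null(cache[[key]])) return(cache[[key]])
  sc <- scenario
  sc@params <- params
  value <- if (metric == "cumulative") {
    meanCumulativeInfestation(runScenario(sc), tBar)
  } else {
    marginalBenefitSlope(sc, UGrid = UGrid, tBar = tBar)$slope
  }
  cache[[key]] <- value
  value
}

#' Two-dimensional parameter sweep
#'
#' Evaluates a summary metric over every cell of a 2-D parameter grid,
#' holding everything else in the scenario fixed. Cells are independent:
#' the result is identical regardless of evaluation order, and repeated
#' parameter combinations are served from a cache rather than re-simulated.
#' The special axis name \code{"tBar"} sweeps the evaluation horizon
#' instead of a dynamics parameter.
#'
#' @param scenario a SimulationScenario
#' @param axis1Name,axis2Name parameter names (any of r, A, gamma, K, U,
#'   Ce, f, s, sigma, d, Ia, k, or "tBar")
#' @param axis1Values,axis2Values nonempty numeric grids (axis1 = rows)
#' @param metric "cumulative" (mean cumulative infestation at tBar) or
#'   "slope" (marginal-benefit-of-U slope at tBar)
#' @param tBar evaluation horizon used when it is not itself an axis
#' @param UGrid U grid used by the "slope" metric
#' @return a \linkS4class{SweepResult}
#' @export
parameterSweep2d <- function(scenario, axis1Name, axis1Values,
                             axis2Name, axis2Values,
                             metric = c("cumulative", "slope"),
                             tBar = scenario@tEnd,
                             UGrid = seq(-5, 5, length.out = 11)) {
  metric <- match.arg(metric)
  valid <- c(slotNames("ModelParams"), "tBar")
  for (nm in c(axis1Name, axis2Name))
    if (!nm %in% valid)
      stop(sprintf("invalid parameter name '%s'; valid names: %s",
                   nm, paste(valid, collapse = ", ")))
  if (length(axis1Values) == 0 || length(axis2Values) == 0)
    stop("axis grids must be nonempty")
  if (metric == "slope" && "U" %in% c(axis1Name, axis2Name))
    stop("U cannot be a sweep axis for the slope metric")
  cache <- sweepCache()
  vals <- matrix(NA_real_, length(axis1Values), length(axis2Values))
  for (i in seq_along(axis1Values)) {
    for (j in seq_along(axis2Values)) {
      p <- scenario@params
      tb <- tBar
      for (ax in list(c(axis1Name, axis1Values[i]),
                      c(axis2Name, axis2Values[j]))) {
        if (ax[1] == "tBar") tb <- as.numeric(ax[2])
        else p <- do.call(updateParams, c(list(p),
                          stats::setNames(list(as.numeric(ax[2])), ax[1])))
      }
      vals[i, j] <- evalMetricCell(scenario, p, tb, metric, UGrid, cache)
    }
  }
  new("SweepResult", axis1Name = axis1Name, axis1Values = axis1Values,
      axis2Name = axis2Name, axis2Values = axis2Values,
      metricName = if (metric == "cumulative")
        "mean cumulative infestation" else "marginal-benefit slope",
      values = vals,
      provenance = list(tBar = tBar, metric = metric,
                        network = networkFingerprint(scenario@network),
                        params = paramsAsList(scenario@params)))
}

#' Smallest interception fraction that halves total infestation
#'
#' Bisection search on the interception fraction \code{Ce} in [0, 1] for
#' the smallest value at which the mean cumulative infestation at the
#' horizon drops to half its uncontrolled (Ce = 0) value. Requires the
#' metric to be nonincreasing in Ce (guarded: a bracketing failure raises
#' an error). If even complete interception cannot halve the metric, 1 is
#' returned with \code{attainable = FALSE}.
#'
#' @param scenario a SimulationScenario
#' @param tBar evaluation horizon (years)
#' @param tol bisection tolerance on Ce (default 0.005)
#' @param metricFn optional function(Ce) -> metric, replacing the built-in
#'   simulation metric (used for testing and for externally cached sweeps)
#' @return list with \code{Ce}, \code{attainable}, \code{baseline} (the
#'   Ce = 0 metric) and \code{atCe} (the metric at the returned Ce)
#' @export
halvingInterceptionFraction <- function(scenario, tBar = 5, tol = 0.005,
                                        metricFn = NULL) {
  if (is.null(metricFn)) {
    metricFn <- function(ce) {
      meanCumulativeInfestation(
        runScenario(scenario, params = updateParams(scenario@params, Ce = ce)),
        tBar)
    }
  }
  m0 <- metricFn(0)
  if (m0 <= 0) stop("metric at Ce = 0 must be positive")
  target <- m0 / 2
  m1 <- metricFn(1)
  if (m1 > m0 + 1e-9 * max(1, m0))
    stop("metric is not nonincreasing in Ce; bracketing failed")
  if (m1 > target) {
    return(list(Ce = 1, attainable = FALSE, baseline = m0, atCe = m1))
  }
  lo <- 0; hi <- 1
  mhi <- m1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    mm <- metricFn(mid)
    if (mm > m0 + 1e-9 * max(1, m0))
      stop("metric is not nonincreasing in Ce; bracketing failed")
    if (mm <= target) { hi <- mid; mhi <- mm } else lo <- mid
  }
  list(Ce = hi, attainable = TRUE, baseline = m0, atCe = mhi)
}

#' Quarantine sweep over set size and window length
#'
#' For every combination of quarantine size |V| (nodes chosen by weighted
#' betweenness centrality via [quarantineNodeSelection()]) and window
#' length, runs the simulation with the quarantine starting at \code{t0}
#' and evaluates the mean cumulative infestation at each horizon. Returns
#' one \linkS4class{SweepResult} per horizon.
#'
#' @param scenario a SimulationScenario
#' @param VSizes integer vector of quarantine set sizes (rows)
#' @param deltaTValues numeric vector of window lengths in years (columns)
#' @param t0 quarantine start time (years, default 1)
#' @param tBarList evaluation horizons (default c(5, 10, 15) years)
#' @return named list of SweepResult objects, one per horizon
#' @export
quarantineSweep <- function(scenario, VSizes, deltaTValues, t0 = 1,
                            tBarList = c(5, 10, 15)) {
  n <- nPatches(scenario@network)
  if (any(VSizes < 0) || any(VSizes > n))
    stop(sprintf("quarantine sizes must lie in [0, %d]", n))
  if (t0 < 0) stop("t0 must be nonnegative")
  if (max(tBarList) > scenario@tEnd)
    stop("every horizon must lie within the scenario's tEnd")
  ranked <- quarantineNodeSelection(scenario@network, max(VSizes))
  metric <- array(NA_real_,
                  c(length(VSizes), length(deltaTValues), length(tBarList)))
  for (i in seq_along(VSizes)) {
    V <- ranked[seq_len(VSizes[i])]
    for (j in seq_along(deltaTValues)) {
      pol <- if (VSizes[i] == 0 || deltaTValues[j] == 0) quarantinePolicy()
        else quarantinePolicy(V, t0 = t0, deltaT = deltaTValues[j])
      traj <- runScenario(scenario, policy = pol)
      for (h in seq_along(tBarList))
        metric[i, j, h] <- meanCumulativeInfestation(traj, tBarList[h])
    }
  }
  out <- lapply(seq_along(tBarList), function(h) {
    new("SweepResult",
        axis1Name = "quarantine size |V|", axis1Values = as.numeric(VSizes),
        axis2Name = "quarantine length deltaT",
        axis2Values = as.numeric(deltaTValues),
        metricName = sprintf("mean cumulative infestation at %g years",
                             tBarList[h]),
        values = metric[, , h, drop = TRUE] |>
          matrix(length(VSizes), length(deltaTValues)),
        provenance = list(t0 = t0, tBar = tBarList[h],
                          network = networkFingerprint(scenario@network),
                          params = paramsAsList(scenario@params)))
  })
  names(out) <- sprintf("t%g", tBarList)
  out
}

#' Export a sweep result as CSV matrix plus JSON provenance
#'
#' @param sweep a SweepResult
#' @param csvFile output path for the metric matrix (axis1 values as the
#'   first column, axis2 values as the header)
#' @param jsonFile optional output path for provenance
#' @return invisibly, the sweep
#' @export
writeSweepResult <- function(sweep, csvFile, jsonFile = NULL) {
  df <- data.frame(axis1 = sweep@axis1Values, sweep@values)
  names(df) <- c(sweep@axis1Name, format(sweep@axis2Values, trim = TRUE))
  utils::write.csv(df, csvFile, row.names = FALSE)
  if (!is.null(jsonFile)) {
    jsonlite::write_json(
      c(list(axis1Name = sweep@axis1Name, axis2Name = sweep@axis2Name,
             metricName = sweep@metricName), sweep@provenance),
      jsonFile, auto_unbox = TRUE, digits = NA)
  }
  invisible(sweep)
}
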