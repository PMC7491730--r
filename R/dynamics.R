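## Right-hand side of the coupled pest/social metapopulation system.
##
## Per patch i (N patches, column-stochastic trip fractions P[i, j] =
## fraction of trips from j to i):
##
##   dS_i/dt = r S_i (1 - (S_i + I_i)/K) - A S_i (I_i + B_i) theta_k(I_i - Ia)
##   dI_i/dt = -gamma I_i + A S_i (I_i + B_i) theta_k(I_i - Ia) - export_i
##   dB_i/dt = -gamma B_i + import_i
##   dL_i/dt = sigma L_i (1 - L_i) (U + s(2 L_i - 1) + f I_i)
##   dT_i/dt = A S_i (I_i + B_i) theta_k(I_i - Ia)
##
##   export_i = d (1-Ce) (1-L_i) I_i * sum_{j != i} gate[j,i] P[j,i]
##   import_i = d (1-Ce) * sum_{j != i} gate[i,j] P[i,j] (1-L_j) I_j
##
## gate[i,j] is 1 normally; if either endpoint is quarantined it is the
## upside-down boxcar H_c(t - t0, deltaT), 0 inside the window, 1 outside.

#' Transmission sigmoid
#'
#' The logistic sigmoid \eqn{\theta_k(x) = 1 / (1 + e^{-kx})} used to make
#' within-patch transmission density-dependent: evaluated at
#' \eqn{I_i - I_a}, it halves the transmission rate when the infested
#' population equals \code{Ia} and saturates to one above it.
#'
#' @param x numeric vector
#' @param k steepness (> 0)
#' @return values in (0, 1), strictly increasing in x, 0.5 at x = 0
#' @examples
#' sigmoidTheta(0, 1)      # 0.5
#' sigmoidTheta(log(9), 1) # 0.9
#' @export
sigmoidTheta <- function(x, k = 1) {
  if (k <= 0) stop("k must be positive")
  1 / (1 + exp(-k * x))
}

#' Upside-down boxcar switch
#'
#' The quarantine gate \eqn{H_c(x, \Delta t)}: 1 for x < 0, 0 for
#' \eqn{0 \le x \le \Delta t}, 1 for \eqn{x > \Delta t}. Applied with
#' \code{x = t - t0} it switches transport off exactly inside the
#' quarantine window.
#'
#' @param x numeric vector (time since the window start)
#' @param deltaT window length (>= 0)
#' @return 0 inside the window, 1 outside
#' @examples
#' boxcarOffWindow(c(-0.1, 1, 2.5), deltaT = 2) # 1 0 1
#' @export
boxcarOffWindow <- function(x, deltaT) {
  if (deltaT < 0) stop("deltaT must be nonnegative")
  ifelse(x >= 0 & x <= deltaT, 0, 1)
}

#' Utility difference driving social learning
#'
#' Returns the payoff advantage of the local-purchase strategy over the
#' transport strategy, \eqn{P_l - P_t = U + s(2L_i - 1) + f I_i}: the net
#' social cost of transport, plus conformity pressure towards the local
#' majority, plus aversion driven by visible local infestation. This is the
#' bracketed term of the replicator equation for \code{L}.
#'
#' @param L local-strategist fraction(s), in [0, 1]
#' @param I infested tree population(s), >= 0
#' @param params a \linkS4class{ModelParams} (uses U, s, f)
#' @return numeric utility difference(s)
#' @examples
#' utilityDifference(0.5, 0, modelParams())          # 0 at the neutral point
#' utilityDifference(0.25, 0, modelParams(U = 0.05)) # interior root
#' @export
utilityDifference <- function(L, I, params = modelParams()) {
  params@U + params@s * (2 * L - 1) + params@f * I
}

## Precompute the time-independent pieces of the RHS for one solver segment.
## `gateOn` = the boxcar value for quarantined-endpoint terms on this
## segment (constant between segment boundaries).
rhsContext <- function(params, network, policy = quarantinePolicy()) {
  P <- network@tripFraction
  diag(P) <- 0 # transport sums skip j = i even when self-loops are stored
  n <- nrow(P)
  inV <- network@nodeIds %in% policy@nodes
  gated <- outer(inV, inV, "|") # TRUE where either endpoint is quarantined
  list(P = P, n = n, gated = gated, anyGate = any(gated),
       exportWeight = colSums(P), # sum_j P[j,i] over j != i
       params = params, policy = policy)
}

rhsEval <- function(state, ctx, gateOn) {
  p <- ctx$params
  S <- state$S; I <- state$I; B <- state$B; L <- state$L
  theta <- 1 / (1 + exp(-p@k * (I - p@Ia)))
  infest <- p@A * S * (I + B) * theta
  outflow <- (1 - p@Ce) * (1 - L) * I # per-source transportable wood
  if (ctx$anyGate && gateOn == 0) {
    Peff <- ctx$P
    Peff[ctx$gated] <- 0
    import <- p@d * as.vector(Peff %*% outflow)
    export <- p@d * colSums(Peff) * outflow
  } else {
    import <- p@d * as.vector(ctx$P %*% outflow)
    export <- p@d * ctx$exportWeight * outflow
  }
  list(
    dS = unname(p@r * S * (1 - (S + I) / p@K) - infest),
    dI = unname(-p@gamma * I + infest - export),
    dB = unname(-p@gamma * B + import),
    dL = unname(p@sigma * L * (1 - L) * (p@U + p@s * (2 * L - 1) + p@f * I)),
    dT = unname(infest)
  )
}

#' Evaluate the coupled right-hand side at one state
#'
#' Computes the instantaneous derivatives of all five per-patch state
#' variables, including firewood import/export between patches, checkpoint
#' interception (the \code{(1 - Ce)} factor on every route), and the
#' quarantine gate: any transport term whose source or destination patch is
#' quarantined is multiplied by the boxcar switch, which is zero for
#' \code{t} inside \code{[t0, t0 + deltaT]}.
#'
#' @param t time (years); only the quarantine gate depends on it
#' @param state a \linkS4class{SystemState} (or named list with S, I, B, L, T)
#' @param params a ModelParams
#' @param network a TravelNetwork whose size matches the state
#' @param policy a QuarantinePolicy (default: none)
#' @return named list of derivative vectors dS, dI, dB, dL, dT
#' @examples
#' net <- generateSyntheticNetwork(5, seed = 1)
#' st <- buildInitialState(net, initialConditions(nodeIds(net)[1]))
#' coupledRHS(0, st, modelParams(), net)
#' @export
coupledRHS <- function(t, state, params, network, policy = quarantinePolicy()) {
  if (is(state, "SystemState"))
    state <- list(S = state@S, I = state@I, B = state@B,
                  L = state@L, T = state@T)
  n <- nPatches(network)
  if (length(state$S) != n)
    stop(sprintf("state has %d patches but network has %d",
                 length(state$S), n))
  ctx <- rhsContext(params, network, policy)
  gateOn <- if (length(policy@nodes))
    boxcarOffWindow(t - policy@t0, policy@deltaT) else 1
  rhsEval(state, ctx, gateOn)
}
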