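# Independent oracles and fixture builders shared across the test files.
# Both oracles are deliberately naive (scalar loops, no linear algebra,
# no igraph) so they cannot share a defect with the implementation paths
# they check.

# Naive double-loop evaluation of the coupled right-hand side.
naiveRHS <- function(t, state, params, network, policy = quarantinePolicy()) {
  P <- tripFraction(network)
  ids <- nodeIds(network)
  n <- length(ids)
  S <- state@S; I <- state@I; B <- state@B; L <- state@L
  p <- paramsAsList(params)
  inV <- ids %in% policy@nodes
  h <- if (length(policy@nodes)) {
    x <- t - policy@t0
    if (x >= 0 && x <= policy@deltaT) 0 else 1
  } else 1
  dS <- dI <- dB <- dL <- dT <- numeric(n)
  for (i in seq_len(n)) {
    theta <- 1 / (1 + exp(-p$k * (I[i] - p$Ia)))
    infest <- p$A * S[i] * (I[i] + B[i]) * theta
    imp <- 0
    exp_ <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      gIn <- if (inV[i] || inV[j]) h else 1   # term j -> i
      imp <- imp + gIn * P[i, j] * (1 - p$Ce) * (1 - L[j]) * I[j]
      gOut <- if (inV[j] || inV[i]) h else 1  # term i -> j
      exp_ <- exp_ + gOut * P[j, i] * (1 - p$Ce) * (1 - L[i]) * I[i]
    }
    dS[i] <- p$r * S[i] * (1 - (S[i] + I[i]) / p$K) - infest
    dI[i] <- -p$gamma * I[i] + infest - p$d * exp_
    dB[i] <- -p$gamma * B[i] + p$d * imp
    dL[i] <- p$sigma * L[i] * (1 - L[i]) *
      (p$U + p$s * (2 * L[i] - 1) + p$f * I[i])
    dT[i] <- infest
  }
  list(dS = dS, dI = dI, dB = dB, dL = dL, dT = dT)
}

# Brute-force shortest-path betweenness on the trip-fraction weight
# transform w = max(P) + 1 - P, endpoints excluded. Floyd-Warshall with
# shortest-path counting; independent of igraph's Brandes algorithm.
bruteBetweenness <- function(network, tol = 1e-10) {
  P <- tripFraction(network)
  n <- nrow(P)
  off <- P; diag(off) <- -Inf
  wmax <- max(off)
  dist <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i != j && P[i, j] > 0) {   # edge j -> i
      dist[j, i] <- wmax + 1 - P[i, j]
      cnt[j, i] <- 1
    }
  }
  for (k in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || k == s || k == t) next
    alt <- dist[s, k] + dist[k, t]
    if (!is.finite(alt)) next
    if (alt < dist[s, t] - tol) {
      dist[s, t] <- alt
      cnt[s, t] <- cnt[s, k] * cnt[k, t]
    } else if (abs(alt - dist[s, t]) <= tol) {
      cnt[s, t] <- cnt[s, t] + cnt[s, k] * cnt[k, t]
    }
  }
  g <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v) next
    if (cnt[s, t] == 0) next
    thru <- if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
                abs(dist[s, v] + dist[v, t] - dist[s, t]) <= tol)
      cnt[s, v] * cnt[v, t] else 0
    g[v] <- g[v] + thru / cnt[s, t]
  }
  stats::setNames(g, nodeIds(network))
}

# Random sparse column-stochastic network on n nodes (every node keeps at
# least one outgoing edge).
randomNetwork <- function(n, seed, density = 0.4) {
  set.seed(seed)
  counts <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dests <- setdiff(seq_len(n), j)
    m <- max(1, rbinom(1, length(dests), density))
    pick <- sample(dests, m)
    counts[pick, j] <- runif(m, 0.1, 10)
  }
  ids <- sprintf("v%02d", seq_len(n))
  dimnames(counts) <- list(ids, ids)
  norm <- normalizeTripFractions(counts, "error")
  new("TravelNetwork", nodeIds = ids, tripFraction = norm$P,
      nodeMeta = data.frame(id = character(), x = numeric(), y = numeric(),
                            population = numeric(), isFocal = logical()))
}

# Random admissible system state for n patches.
randomState <- function(n, K = 5000) {
  systemState(S = runif(n, 0, K), I = runif(n, 0, K), B = runif(n, 0, 50),
              L = runif(n), T = runif(n, 0, K))
}

# Network built from an explicit edge data.frame (origin, destination, trips).
networkFromEdges <- function(edges, ...) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(edges, f, row.names = FALSE, quote = FALSE)
  loadTripTable(f, ...)
}
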