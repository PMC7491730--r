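## Travel-network construction, normalization, reduction, synthesis and
## quarantine-node ranking.

maxOffDiagonal <- function(P) {
  off <- P
  diag(off) <- -Inf
  max(off)
}

emptyNodeMeta <- function() {
  data.frame(id = character(), x = numeric(), y = numeric(),
             population = numeric(), isFocal = logical(),
             stringsAsFactors = FALSE)
}

newTravelNetwork <- function(nodeIds, tripFraction, nodeMeta = emptyNodeMeta()) {
  dimnames(tripFraction) <- list(nodeIds, nodeIds)
  new("TravelNetwork", nodeIds = as.character(nodeIds),
      tripFraction = tripFraction, nodeMeta = nodeMeta)
}

#' Column-normalize a trip-count matrix
#'
#' Converts raw trip counts into trip fractions: each column (one origin
#' patch) is divided by its total so columns sum to one. Columns with zero
#' total — origins with no recorded outgoing trips — are handled per
#' \code{zeroColumnPolicy}: \code{"drop"} removes those nodes from the
#' network, \code{"selfloop"} gives them a self-loop of weight one, and
#' \code{"error"} aborts.
#'
#' @param counts square numeric matrix of nonnegative trip counts;
#'   counts[i, j] = trips from origin j to destination i. Dimnames, if
#'   present, are preserved.
#' @param zeroColumnPolicy one of "drop", "selfloop", "error"
#' @return list with \code{P} (the column-stochastic matrix) and
#'   \code{keep} (logical vector over the original columns; all TRUE unless
#'   policy "drop" removed zero-trip nodes)
#' @examples
#' normalizeTripFractions(matrix(c(0, 9, 1, 0), 2, 2,
#'                               dimnames = list(c("a","b"), c("a","b"))))
#' @export
normalizeTripFractions <- function(counts,
                                   zeroColumnPolicy = c("drop", "selfloop", "error")) {
  zeroColumnPolicy <- match.arg(zeroColumnPolicy)
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop("counts must be a square matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("trip counts must be finite and nonnegative")
  tot <- colSums(counts)
  keep <- rep(TRUE, ncol(counts))
  if (any(tot == 0)) {
    if (zeroColumnPolicy == "error") {
      stop("column(s) with zero outgoing trips: ",
           paste(which(tot == 0), collapse = ", "))
    } else if (zeroColumnPolicy == "selfloop") {
      for (j in which(tot == 0)) counts[j, j] <- 1
      tot <- colSums(counts)
    } else {
      keep <- tot > 0
      counts <- counts[keep, keep, drop = FALSE]
      tot <- colSums(counts)
      if (any(tot == 0)) # dropping destinations can empty further columns
        return(normalizeTripFractions(counts, "drop") |>
                 (\(r) { keep[keep] <- r$keep; list(P = r$P, keep = keep) })())
    }
  }
  P <- sweep(counts, 2, tot, "/")
  list(P = P, keep = keep)
}

#' Read a travel network from CSV edge-list (and optional node table)
#'
#' The edge list must have header \code{origin,destination,trips}; the
#' optional node table has header \code{id,x,y,population,is_focal}. Trip
#' counts are converted to column-stochastic fractions via
#' [normalizeTripFractions()]. Duplicate (origin, destination) pairs are
#' summed with a warning; negative trip counts and malformed rows are
#' errors. Node-table ids must be a superset of the edge-list ids; node-only
#' ids become isolated nodes handled by the zero-trip policy.
#'
#' @param edgeFile path to the edge-list CSV
#' @param nodeFile optional path to the node-table CSV
#' @param zeroOutPolicy policy for nodes with no outgoing trips:
#'   "drop" (default), "selfloop" or "error"
#' @return a \linkS4class{TravelNetwork}
#' @seealso [writeTravelNetwork()] for the round-trip inverse
#' @export
loadTripTable <- function(edgeFile, nodeFile = NULL,
                          zeroOutPolicy = c("drop", "selfloop", "error")) {
  zeroOutPolicy <- match.arg(zeroOutPolicy)
  edges <- utils::read.csv(edgeFile, stringsAsFactors = FALSE)
  need <- c("origin", "destination", "trips")
  if (!all(need %in% names(edges)))
    stop("edge list must have columns origin, destination, trips")
  if (nrow(edges) == 0) stop("edge list is empty")
  trips <- suppressWarnings(as.numeric(edges$trips))
  bad <- which(!is.finite(trips))
  if (length(bad))
    stop(sprintf("malformed trips value at edge-list row %d: '%s'",
                 bad[1], edges$trips[bad[1]]))
  neg <- which(trips < 0)
  if (length(neg))
    stop(sprintf("negative trip count at edge-list row %d", neg[1]))
  edges$trips <- trips
  edges$origin <- as.character(edges$origin)
  edges$destination <- as.character(edges$destination)

  dup <- duplicated(edges[c("origin", "destination")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (origin, destination) pair(s) summed",
                    sum(dup)))
    edges <- stats::aggregate(trips ~ origin + destination, data = edges, FUN = sum)
  }

  meta <- emptyNodeMeta()
  edgeIds <- sort(unique(c(edges$origin, edges$destination)))
  if (!is.null(nodeFile)) {
    nt <- utils::read.csv(nodeFile, stringsAsFactors = FALSE)
    if (!"id" %in% names(nt)) stop("node table must have an 'id' column")
    nt$id <- as.character(nt$id)
    missing <- setdiff(edgeIds, nt$id)
    if (length(missing))
      stop("edge-list ids missing from node table: ",
           paste(missing, collapse = ", "))
    ids <- sort(nt$id)
    meta <- data.frame(
      id = nt$id,
      x = if ("x" %in% names(nt)) as.numeric(nt$x) else NA_real_,
      y = if ("y" %in% names(nt)) as.numeric(nt$y) else NA_real_,
      population = if ("population" %in% names(nt)) as.numeric(nt$population) else 0,
      isFocal = if ("is_focal" %in% names(nt))
        as.logical(nt$is_focal) else FALSE,
      stringsAsFactors = FALSE
    )
    meta <- meta[order(meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  } else {
    ids <- edgeIds
  }

  n <- length(ids)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  counts[cbind(match(edges$destination, ids), match(edges$origin, ids))] <-
    edges$trips
  norm <- normalizeTripFractions(counts, zeroOutPolicy)
  ids <- ids[norm$keep]
  if (length(ids) < 2)
    stop("fewer than 2 nodes remain after applying the zero-trip policy")
  if (nrow(meta) > 0) {
    meta <- meta[meta$id %in% ids, , drop = FALSE]
    rownames(meta) <- NULL
  }
  newTravelNetwork(ids, norm$P, meta)
}

#' Write a travel network as a round-trippable CSV pair
#'
#' Writes the trip-fraction matrix as an edge list (fractions in the
#' \code{trips} column) and, if metadata are present, a node table. Reading
#' the pair back with [loadTripTable()] reproduces the network: column
#' normalization is idempotent on an already-stochastic matrix.
#'
#' @param network a TravelNetwork
#' @param edgeFile output path for the edge-list CSV
#' @param nodeFile optional output path for the node-table CSV
#' @return invisibly, the network
#' @export
writeTravelNetwork <- function(network, edgeFile, nodeFile = NULL) {
  P <- network@tripFraction
  ids <- network@nodeIds
  nz <- which(P > 0, arr.ind = TRUE)
  edges <- data.frame(origin = ids[nz[, 2]], destination = ids[nz[, 1]],
                      trips = P[nz], stringsAsFactors = FALSE)
  edges <- edges[order(edges$origin, edges$destination), , drop = FALSE]
  utils::write.csv(edges, edgeFile, row.names = FALSE, quote = FALSE)
  if (!is.null(nodeFile) && nrow(network@nodeMeta) > 0) {
    meta <- network@nodeMeta
    out <- data.frame(id = meta$id, x = meta$x, y = meta$y,
                      population = meta$population,
                      is_focal = meta$isFocal, stringsAsFactors = FALSE)
    utils::write.csv(out, nodeFile, row.names = FALSE, quote = FALSE)
  }
  invisible(network)
}

asIgraph <- function(network, weighted = FALSE) {
  P <- network@tripFraction
  diag(P) <- 0 # transport dynamics and path analysis skip self-loops
  nz <- which(P > 0, arr.ind = TRUE)
  ids <- network@nodeIds
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[nz[, 2]], to = ids[nz[, 1]],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (weighted) {
    # higher trip fraction => shorter path distance
    igraph::E(g)$weight <- maxOffDiagonal(network@tripFraction) + 1 - P[nz]
  }
  g
}

#' Reduce a network to its largest k-core
#'
#' Returns the maximal subgraph in which every node has degree at least
#' \code{k}, with degree computed on the undirected support of the graph
#' (an edge in either direction counts once). If the k-core is
#' disconnected, the largest (weakly) connected component is kept. Trip
#' fractions are re-normalized per column on the surviving subgraph.
#'
#' @param network a TravelNetwork
#' @param k minimum degree (>= 1)
#' @return the reduced \linkS4class{TravelNetwork}
#' @examples
#' net <- generateSyntheticNetwork(30, seed = 1)
#' kCoreReduce(net, 5)
#' @export
kCoreReduce <- function(network, k) {
  if (k < 1) stop("k must be >= 1")
  g <- asIgraph(network)
  gu <- igraph::as_undirected(g, mode = "collapse")
  core <- igraph::coreness(gu)
  keepIds <- names(core)[core >= k]
  if (length(keepIds) == 0)
    stop(sprintf("the %d-core of this network is empty", k))
  sub <- igraph::induced_subgraph(gu, keepIds)
  comp <- igraph::components(sub)
  largest <- which.max(comp$csize)
  keepIds <- names(comp$membership)[comp$membership == largest]
  keep <- network@nodeIds %in% keepIds
  if (sum(keep) < 2)
    stop(sprintf("the %d-core of this network is empty", k))
  ids <- network@nodeIds[keep]
  counts <- network@tripFraction[keep, keep, drop = FALSE]
  norm <- normalizeTripFractions(counts, "drop")
  ids <- ids[norm$keep]
  if (length(ids) < 2)
    stop(sprintf("the %d-core of this network is empty", k))
  meta <- network@nodeMeta
  if (nrow(meta) > 0) {
    meta <- meta[meta$id %in% ids, , drop = FALSE]
    rownames(meta) <- NULL
  }
  newTravelNetwork(ids, norm$P, meta)
}

#' Select quarantine nodes by weighted betweenness centrality
#'
#' Ranks patches by shortest-path betweenness centrality on the directed
#' weighted graph where the distance of edge (j -> i) is
#' \code{max(P) + 1 - P[i, j]} (max over off-diagonal entries, computed once
#' per network), so that more-travelled routes are shorter. Endpoints are
#' excluded from path counts. Ties are broken by ascending node id.
#'
#' @param network a TravelNetwork
#' @param nNodes how many top-ranked nodes to return (0 <= nNodes <= N)
#' @return character vector of node ids, highest betweenness first
#' @examples
#' net <- generateSyntheticNetwork(30, seed = 1)
#' quarantineNodeSelection(net, 5)
#' @export
quarantineNodeSelection <- function(network, nNodes) {
  n <- nPatches(network)
  if (nNodes < 0 || nNodes > n)
    stop(sprintf("nNodes must lie in [0, %d]", n))
  if (nNodes == 0) return(character())
  g <- asIgraph(network, weighted = TRUE)
  btw <- igraph::betweenness(g, directed = TRUE, weights = igraph::E(g)$weight)
  btw <- btw[network@nodeIds]
  ord <- order(-btw, network@nodeIds)
  network@nodeIds[ord][seq_len(nNodes)]
}

#' Generate a synthetic camper-travel network
#'
#' Emulates the shape of a reservation-derived travel network at a
#' configurable size: nodes scattered uniformly in the unit square,
#' heavy-tailed (log-normal) population weights, one dominant high-population
#' focal node (a large-urban-center analogue), and gravity-model trip counts
#' \eqn{trips(i \leftarrow j) \propto pop_i \, pop_j / dist(i,j)^{\alpha}}
#' (zero on the diagonal), column-normalized to trip fractions. The same
#' seed always yields a bit-identical network.
#'
#' @param nNodes number of patches (>= 2)
#' @param seed integer RNG seed (required; the generator is a pure function
#'   of its arguments)
#' @param gravityExponent distance-decay exponent \eqn{\alpha} (default 2,
#'   the classical gravity-model deterrence)
#' @param populationSpread sdlog of the log-normal population distribution
#'   (default 1, giving heavy-tailed trip counts)
#' @param focalBoost multiplier applied to the largest node's population,
#'   which is flagged focal (default 30, roughly a metropolis-to-largest-
#'   town population ratio)
#' @param destinationsPerOrigin number of strongest destinations kept per
#'   origin before normalization (default 10). Reservation-derived travel
#'   networks are sparse — each origin books trips to a limited set of
#'   destinations — and shortest-path betweenness is degenerate on a
#'   complete graph, so the raw gravity weights are thinned to each
#'   origin's strongest routes. Use \code{nNodes - 1} for a complete
#'   network.
#' @return a \linkS4class{TravelNetwork} with full node metadata
#' @examples
#' net <- generateSyntheticNetwork(100, seed = 42)
#' net
#' @export
generateSyntheticNetwork <- function(nNodes, seed, gravityExponent = 2,
                                     populationSpread = 1, focalBoost = 30,
                                     destinationsPerOrigin = 10) {
  if (nNodes < 2) stop("nNodes must be >= 2")
  if (missing(seed)) stop("an explicit integer seed is required")
  rng <- local({
    # isolate the generator from the session RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    list(x = stats::runif(nNodes), y = stats::runif(nNodes),
         pop = stats::rlnorm(nNodes, meanlog = 0, sdlog = populationSpread))
  })
  ids <- sprintf("n%0*d", nchar(nNodes), seq_len(nNodes))
  pop <- rng$pop
  focal <- which.max(pop)
  pop[focal] <- pop[focal] * focalBoost
  dx <- outer(rng$x, rng$x, "-")
  dy <- outer(rng$y, rng$y, "-")
  dist <- sqrt(dx^2 + dy^2)
  diag(dist) <- 1 # unused: diagonal trips are zeroed below
  w <- outer(pop, pop) / dist^gravityExponent
  diag(w) <- 0
  m <- min(max(1, destinationsPerOrigin), nNodes - 1)
  if (m < nNodes - 1) {
    # keep each origin's m strongest destinations and each destination's m
    # strongest inbound routes, so every patch both sends and receives
    # (mirroring a minimum-degree core of reservation data)
    mask <- matrix(FALSE, nNodes, nNodes)
    for (j in seq_len(nNodes)) {
      mask[order(w[, j], decreasing = TRUE)[seq_len(m)], j] <- TRUE
      mask[j, order(w[j, ], decreasing = TRUE)[seq_len(m)]] <- TRUE
    }
    w[!mask] <- 0
  }
  norm <- normalizeTripFractions(w, "error")
  meta <- data.frame(id = ids, x = rng$x, y = rng$y, population = pop,
                     isFocal = seq_len(nNodes) == focal,
                     stringsAsFactors = FALSE)
  newTravelNetwork(ids, norm$P, meta)
}
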