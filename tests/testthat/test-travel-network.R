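test_that("trip counts normalize to column-stochastic fractions", {
  m <- matrix(c(2, 2, 9, 1), 2, 2)
  norm <- normalizeTripFractions(m, "error")
  expect_equal(norm$P[, 1], c(0.5, 0.5))
  expect_equal(norm$P[, 2], c(0.9, 0.1))

  expect_equal(normalizeTripFractions(diag(3), "error")$P, diag(3))

  expect_error(normalizeTripFractions(matrix(c(1, 0, 0, 0), 2, 2), "error"),
               "zero outgoing")
  expect_error(normalizeTripFractions(matrix(-1, 2, 2)), "nonnegative")

  # self-loop policy fills zero columns on the diagonal
  m0 <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(normalizeTripFractions(m0, "selfloop")$P,
               matrix(c(0, 1, 0, 1), 2, 2))
  # drop policy removes dead columns; here node 1's only destination is the
  # dropped node, so the removal cascades and empties the network
  drop <- normalizeTripFractions(m0, "drop")
  expect_equal(drop$keep, c(FALSE, FALSE))
  # a node with no outgoing trips is dropped, the connected pair survives
  m3 <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  drop3 <- normalizeTripFractions(m3, "drop")
  expect_equal(drop3$keep, c(TRUE, TRUE, FALSE))
  expect_equal(colSums(drop3$P), c(1, 1))
})

test_that("edge-list loading builds validated networks", {
  net <- networkFromEdges(data.frame(origin = c("a", "b"),
                                     destination = c("b", "a"),
                                     trips = c(10, 10)))
  P <- tripFraction(net)
  expect_equal(P["b", "a"], 1)
  expect_equal(P["a", "b"], 1)

  net3 <- networkFromEdges(data.frame(origin = c("a", "a"),
                                      destination = c("b", "c"),
                                      trips = c(3, 1)),
                           zeroOutPolicy = "selfloop")
  P3 <- tripFraction(net3)
  expect_equal(unname(P3[, "a"]), c(0, 0.75, 0.25))
  expect_equal(P3["b", "b"], 1)
  expect_equal(P3["c", "c"], 1)

  expect_error(networkFromEdges(data.frame(origin = "a", destination = "b",
                                           trips = -1)),
               "negative")
  expect_error(networkFromEdges(data.frame(origin = "a", destination = "b",
                                           trips = "ten")),
               "malformed")
  expect_warning(
    net <- networkFromEdges(data.frame(origin = c("a", "a", "b"),
                                       destination = c("b", "b", "a"),
                                       trips = c(1, 2, 5))),
    "duplicate")
  expect_equal(tripFraction(net)["b", "a"], 1) # 1+2 summed then normalized
})

test_that("node table must cover the edge list and carries metadata", {
  ef <- tempfile(fileext = ".csv"); nf <- tempfile(fileext = ".csv")
  on.exit(unlink(c(ef, nf)))
  write.csv(data.frame(origin = c("a", "b"), destination = c("b", "a"),
                       trips = c(1, 1)), ef, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 1),
                       population = c(10, 20), is_focal = c(FALSE, TRUE)),
            nf, row.names = FALSE, quote = FALSE)
  net <- loadTripTable(ef, nf)
  expect_equal(nodeMeta(net)$population, c(10, 20))
  expect_true(nodeMeta(net)$isFocal[2])

  write.csv(data.frame(id = "a", population = 1, is_focal = FALSE), nf,
            row.names = FALSE, quote = FALSE)
  expect_error(loadTripTable(ef, nf), "missing from node table")
})

test_that("k-core reduction keeps the maximal high-degree subgraph", {
  # complete graph on 12 nodes is its own 10-core
  ids <- sprintf("k%02d", 1:12)
  pairs <- expand.grid(origin = ids, destination = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin != pairs$destination, ]
  net <- networkFromEdges(data.frame(pairs, trips = 1))
  expect_equal(sort(nodeIds(kCoreReduce(net, 10))), sort(ids))

  # star on 20 nodes: every leaf has degree 1, so the 2-core is empty
  star <- networkFromEdges(data.frame(
    origin = c(rep("hub", 19), sprintf("s%02d", 1:19)),
    destination = c(sprintf("s%02d", 1:19), rep("hub", 19)),
    trips = 1))
  expect_error(kCoreReduce(star, 2), "empty")

  # path a-b-c-d: all degrees >= 1, unchanged at k = 1
  path <- networkFromEdges(data.frame(
    origin = c("a", "b", "b", "c", "c", "d"),
    destination = c("b", "a", "c", "b", "d", "c"),
    trips = 1))
  expect_setequal(nodeIds(kCoreReduce(path, 1)), c("a", "b", "c", "d"))
})

test_that("k-core reduction is idempotent and preserves stochasticity", {
  for (seed in 1:5) {
    net <- randomNetwork(15, seed = seed, density = 0.35)
    red <- tryCatch(kCoreReduce(net, 3), error = function(e) NULL)
    if (is.null(red)) next
    expect_true(all(abs(colSums(tripFraction(red)) - 1) < 1e-9))
    again <- kCoreReduce(red, 3)
    expect_equal(sort(nodeIds(again)), sort(nodeIds(red)))
  }
})

test_that("quarantine node ranking follows weighted betweenness", {
  # star with uniform fractions: every shortest path crosses the hub
  star <- networkFromEdges(data.frame(
    origin = c(rep("hub", 5), sprintf("s%d", 1:5)),
    destination = c(sprintf("s%d", 1:5), rep("hub", 5)),
    trips = 1))
  expect_equal(quarantineNodeSelection(star, 1), "hub")

  # path a-b-c-d-e with uniform weights: the middle node is on the most paths
  path <- networkFromEdges(data.frame(
    origin = c("a", "b", "b", "c", "c", "d", "d", "e"),
    destination = c("b", "a", "c", "b", "d", "c", "e", "d"),
    trips = 1))
  expect_equal(quarantineNodeSelection(path, 1), "c")

  expect_identical(quarantineNodeSelection(path, 0), character())
  expect_error(quarantineNodeSelection(path, 6), "nNodes")
})

test_that("betweenness ranking matches the brute-force oracle", {
  # smaller-scale spot check; the full 100-instance sweep is in acceptance
  for (seed in 1:20) {
    n <- sample(4:10, 1)
    net <- randomNetwork(n, seed = 1000 + seed)
    g <- bruteBetweenness(net)
    ranking <- quarantineNodeSelection(net, n)
    oracleOrder <- nodeIds(net)[order(-g, nodeIds(net))]
    expect_equal(g[ranking], g[oracleOrder], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("synthetic networks are deterministic and well-formed", {
  a <- generateSyntheticNetwork(50, seed = 1)
  b <- generateSyntheticNetwork(50, seed = 1)
  expect_identical(tripFraction(a), tripFraction(b))
  expect_identical(nodeMeta(a), nodeMeta(b))
  expect_false(identical(tripFraction(a),
                         tripFraction(generateSyntheticNetwork(50, seed = 2))))

  expect_true(all(abs(colSums(tripFraction(a)) - 1) < 1e-9))
  expect_true(all(diag(tripFraction(a)) == 0))
  expect_equal(sum(nodeMeta(a)$isFocal), 1)
  expect_error(generateSyntheticNetwork(1, seed = 1), "nNodes")
})

test_that("gravity limit cases behave analytically", {
  # no distance decay + equal populations => uniform columns at 1/(n-1)
  net <- generateSyntheticNetwork(10, seed = 3, gravityExponent = 0,
                                  populationSpread = 0, focalBoost = 1)
  P <- tripFraction(net)
  offdiag <- P[row(P) != col(P)]
  expect_equal(offdiag, rep(1 / 9, 90), tolerance = 1e-12)

  # a strongly boosted focal node dominates incoming trip fractions
  net <- generateSyntheticNetwork(40, seed = 4, focalBoost = 100)
  P <- tripFraction(net)
  focal <- nodeMeta(net)$id[nodeMeta(net)$isFocal]
  expect_equal(names(which.max(rowSums(P))), focal)
})

test_that("networks round-trip through the CSV pair", {
  net <- generateSyntheticNetwork(20, seed = 9)
  ef <- tempfile(fileext = ".csv"); nf <- tempfile(fileext = ".csv")
  on.exit(unlink(c(ef, nf)))
  writeTravelNetwork(net, ef, nf)
  back <- loadTripTable(ef, nf)
  expect_equal(nodeIds(back), nodeIds(net))
  expect_equal(tripFraction(back), tripFraction(net), tolerance = 1e-12)
  expect_equal(nodeMeta(back)$population, nodeMeta(net)$population,
               tolerance = 1e-12)
  expect_equal(nodeMeta(back)$isFocal, nodeMeta(net)$isFocal)
})

test_that("column stochasticity survives every transformation", {
  net <- generateSyntheticNetwork(30, seed = 11)
  checks <- list(
    loaded = {
      ef <- tempfile(fileext = ".csv")
      writeTravelNetwork(net, ef)
      out <- loadTripTable(ef); unlink(ef); out
    },
    reduced = kCoreReduce(net, 3)
  )
  for (nm in names(checks))
    expect_true(all(abs(colSums(tripFraction(checks[[nm]])) - 1) < 1e-9),
                label = nm)
})
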