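twoPatchNet <- function() {
  networkFromEdges(data.frame(origin = c("a", "b"), destination = c("b", "a"),
                              trips = 1))
}

test_that("focal-seed initial states are constructed as specified", {
  net <- generateSyntheticNetwork(10, seed = 1)
  focal <- nodeIds(net)[4]
  st <- buildInitialState(net, initialConditions(focal), modelParams())
  i <- which(nodeIds(net) == focal)
  expect_equal(st@I[i], 5000)
  expect_equal(st@S[i], 0)
  expect_equal(st@S[-i], rep(5000, 9))
  expect_equal(st@T, st@I) # seeded infestations are counted
  expect_equal(st@L, rep(0.5, 10))

  st0 <- buildInitialState(net, initialConditions(focal,
                                                  focalInfestedFraction = 0))
  expect_equal(st0@I, rep(0, 10))
  expect_equal(st0@S, rep(5000, 10))

  stL <- buildInitialState(net, initialConditions(focal, backgroundL = 0.9))
  expect_equal(stL@L, rep(0.9, 10))

  expect_error(buildInitialState(net, initialConditions("nope")), "not in")
})

test_that("uncoupled infested patches decay in closed form", {
  net <- twoPatchNet()
  st <- systemState(S = c(0, 0), I = c(100, 100), B = c(0, 0),
                    L = c(0.5, 0.5), T = c(100, 100))
  traj <- runSimulation(net, modelParams(A = 0, d = 0), init = st,
                        tEnd = 5, sampleEvery = 0.5)
  I5 <- stateMatrix(traj, "I")[nrow(traj@I), ]
  expect_equal(unname(I5), rep(100 * exp(-1.4 * 5), 2), tolerance = 1e-5)
})

test_that("d = 0 decouples patches into independent single-patch runs", {
  net <- generateSyntheticNetwork(5, seed = 2)
  p <- modelParams(d = 0)
  traj <- runSimulation(net, p, tEnd = 20, sampleEvery = 0.5,
                        rtol = 1e-10, atol = 1e-11)
  meta <- nodeMeta(net)
  focalIdx <- which(nodeIds(net) == meta$id[meta$isFocal])

  # reference: same per-patch dynamics on an unrelated 2-patch network
  ref <- twoPatchNet()
  seeded <- runSimulation(ref, p,
    init = systemState(S = c(0, 5000), I = c(5000, 0), B = c(0, 0),
                       L = c(0.5, 0.5), T = c(5000, 0)),
    tEnd = 20, sampleEvery = 0.5, rtol = 1e-10, atol = 1e-11)
  for (v in c("S", "I", "B", "L", "T")) {
    got <- stateMatrix(traj, v)
    want <- stateMatrix(seeded, v)
    expect_lt(max(abs(got[, focalIdx] - want[, 1])), 1e-6)
    for (j in setdiff(seq_len(5), focalIdx))
      expect_lt(max(abs(got[, j] - want[, 2])), 1e-6)
  }
})

test_that("trajectories sample on the requested cadence and keep invariants", {
  sc <- calibratedScenario(nNodes = 30, seed = 3, tEnd = 10)
  traj <- runScenario(sc)
  expect_equal(traj@times, seq(0, 10, by = 0.1))
  expect_true(validObject(traj))
  # cumulative infestation is nondecreasing everywhere
  expect_true(all(diff(stateMatrix(traj, "T")) > -1e-8))
  # determinism for fixed inputs
  traj2 <- runScenario(sc)
  expect_identical(traj@I, traj2@I)
})

test_that("halving solver tolerances barely moves the endpoint", {
  net <- generateSyntheticNetwork(30, seed = 3)
  p <- modelParams(d = 0.2)
  a <- networkAverages(runSimulation(net, p, tEnd = 10))
  b <- networkAverages(runSimulation(net, p, tEnd = 10,
                                     rtol = 5e-7, atol = 5e-9))
  iEnd <- nrow(a)
  expect_lt(abs(a$T[iEnd] - b$T[iEnd]) / b$T[iEnd], 1e-3)
})

test_that("network averages and infested-patch counts summarize correctly", {
  net <- twoPatchNet()
  st <- systemState(S = c(0, 5000), I = c(5000, 0), B = c(0, 0),
                    L = c(0.5, 0.5), T = c(5000, 0))
  traj <- runSimulation(net, modelParams(d = 0), init = st, tEnd = 2,
                        sampleEvery = 0.5)
  av <- networkAverages(traj)
  expect_equal(av$I, rowMeans(stateMatrix(traj, "I")))
  expect_equal(av$I[1], 2500) # mean of (5000, 0)

  counts <- infestedPatchCount(traj)
  expect_equal(counts$count[1], 1) # the seeded patch only
  expect_equal(infestedPatchCount(traj, threshold = 0)$count,
               rep(2, nrow(counts)))
  none <- runSimulation(net, modelParams(d = 0),
                        init = systemState(S = c(5000, 5000), I = c(0, 0),
                                           B = c(0, 0), L = c(0.5, 0.5),
                                           T = c(0, 0)),
                        tEnd = 2, sampleEvery = 0.5)
  expect_equal(infestedPatchCount(none)$count, rep(0, 5))
})

test_that("simulation inputs are validated", {
  net <- twoPatchNet()
  expect_error(runSimulation(net, tEnd = 0), "tEnd")
  expect_error(runSimulation(net, sampleEvery = 0), "sampleEvery")
  expect_error(runSimulation(net, policy = quarantinePolicy("zz", 0, 1)),
               "not in network")
  expect_error(runSimulation(net, init = randomState(3)), "patches")
})

test_that("trajectories round-trip through long CSV and JSON summary", {
  sc <- calibratedScenario(nNodes = 10, seed = 5, tEnd = 2)
  traj <- runScenario(sc)
  f <- tempfile(fileext = ".csv")
  j <- tempfile(fileext = ".json")
  on.exit(unlink(c(f, j)))
  writeTrajectoryCSV(traj, f)
  back <- readTrajectoryCSV(f)
  expect_equal(back@times, traj@times)
  expect_equal(nodeIds(back), nodeIds(traj))
  for (v in c("S", "I", "B", "L", "T"))
    expect_equal(stateMatrix(back, v), stateMatrix(traj, v),
                 tolerance = 1e-12)

  writeTrajectorySummaryJSON(traj, j)
  s <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(s$nPatches, 10)
  expect_equal(s$averages$I, networkAverages(traj)$I, tolerance = 1e-9)
  expect_equal(s$provenance$params$gamma, 1.4)
})
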