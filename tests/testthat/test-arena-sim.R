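test_that("trajectory respects the apparatus: rotation, wall, determinism", {
  cfg <- SimConfig(duration = 60, seed = 7)
  tr <- simulateTrajectory(cfg)
  # 1 rpm: one full revolution after 60 s
  expect_equal(tr@theta[length(tr@theta)], 6 * (60 - 1 / 30), tolerance = 1e-9)
  expect_lte(max(sqrt(tr@x^2 + tr@y^2)), cfg@arenaRadius + 1e-9)
  # signed rotation: opposite sign reverses theta
  trNeg <- simulateTrajectory(SimConfig(duration = 60, seed = 7,
                                        rotationRpm = -1))
  expect_equal(trNeg@theta, -tr@theta)
  # fixed seed is bit-identical
  tr2 <- simulateTrajectory(SimConfig(duration = 60, seed = 7))
  expect_identical(tr@x, tr2@x)
  expect_identical(tr@y, tr2@y)
})

test_that("degenerate noise freezes the animal and distance is zero", {
  tr <- simulateTrajectory(SimConfig(duration = 20, seed = 3, ouSigma = 0))
  expect_equal(pathLength(tr, minStep = 0), 0)
})

test_that("sector repulsion depresses occupancy inside the avoided zone", {
  zone <- SectorSpec("room", 0, 60)
  free <- simulateTrajectory(SimConfig(duration = 600, seed = 5,
                                       avoidanceGain = 0,
                                       avoidanceZone = zone))
  avoid <- simulateTrajectory(SimConfig(duration = 600, seed = 5,
                                        avoidanceGain = 4,
                                        avoidanceZone = zone))
  expect_lt(sectorOccupancy(avoid, zone), sectorOccupancy(free, zone))
})

test_that("latent state reproduces dwell statistics and mode semantics", {
  tr <- simulateTrajectory(SimConfig(duration = 2000, seed = 9))
  # none: constant room
  expect_identical(unique(latentState(tr, StateProcess("none"))), 1L)
  # dwell: empirical mean dwell within 10% of nominal
  st <- latentState(tr, StateProcess("dwell", meanDwell = 2), seed = 9)
  runs <- rle(st)
  expect_equal(mean(runs$lengths) / 30, 2, tolerance = 0.1)
  # room-time fraction equals the dwell-mode parameter
  for (p in c(0.3, 0.7)) {
    stp <- latentState(tr, StateProcess("dwell", meanDwell = 2,
                                        pRoomNear = p), seed = 9)
    expect_lt(abs(mean(stp) - p), 0.05)
  }
})

test_that("proximity mode recovers its conditional room probabilities", {
  zone <- SectorSpec("room", 0, 60)
  # slow lap: the animal changes halves only a handful of times over the
  # session, so the half at each dwell renewal is the half of almost every
  # sample in the dwell and the conditional frequencies are identifiable
  tr <- circleSeries(radius = 25, lapTime = 400, laps = 5)
  st <- latentState(tr, StateProcess("proximity", meanDwell = 1,
                                     pRoomNear = 0.9, pRoomFar = 0.1,
                                     zone = zone), seed = 15)
  ang <- atan2(tr@y, tr@x) * 180 / pi
  nearHalf <- abs(((ang - zone@center + 180) %% 360) - 180) <= 90
  expect_lt(abs(mean(st[nearHalf]) - 0.9), 0.05)
  expect_lt(abs(mean(st[!nearHalf]) - 0.1), 0.05)
})

test_that("a clamped rat at the field centre spikes at the Poisson rate", {
  s <- stationarySeries(x = 5, y = 5, duration = 10)
  cell <- CellSpec("room", c(5, 5), sigma = 10, peak = 10, baseline = 0)
  tr <- simulateEnsemble(s, list(cell), seed = 42)[[1]]
  expect_lt(abs(length(spikeTimes(tr)) - 100), 3 * sqrt(100))
  expect_true(all(diff(spikeTimes(tr)) > 0))
})

test_that("cells silenced by frame disagreement with zero baseline are mute", {
  s <- stationarySeries(x = 5, y = 5, duration = 10)
  cell <- CellSpec("room", c(5, 5), sigma = 10, peak = 10, baseline = 0)
  stateArena <- rep(0L, length(s@t))
  tr <- simulateEnsemble(s, list(cell), state = stateArena, seed = 42)[[1]]
  expect_equal(length(spikeTimes(tr)), 0)
})

test_that("empirical rate map of a simulated cell recovers its field", {
  cfg <- SimConfig(duration = 1200, seed = 17)
  tr <- simulateTrajectory(cfg)
  cell <- CellSpec("room", c(15, -10), sigma = 10, peak = 12, baseline = 0.2)
  spk <- simulateEnsemble(tr, list(cell), seed = 17)[[1]]
  m <- rateMap(spk, tr, "room")
  peakBin <- which(m@rate == max(m@rate, na.rm = TRUE), arr.ind = TRUE)[1, ]
  peakPos <- c(m@mids[peakBin[1]], m@mids[peakBin[2]])
  expect_lt(sqrt(sum((peakPos - cell@center)^2)), cell@sigma)
})

test_that("ensemble generation is reproducible and spikes stay in-session", {
  tr <- simulateTrajectory(SimConfig(duration = 60, seed = 23))
  cells <- ringCells("room", n = 3)
  a <- simulateEnsemble(tr, cells, seed = 23)
  b <- simulateEnsemble(tr, cells, seed = 23)
  for (j in seq_along(cells)) {
    expect_identical(spikeTimes(a[[j]]), spikeTimes(b[[j]]))
    expect_true(all(spikeTimes(a[[j]]) >= tr@t[1]))
    expect_true(all(spikeTimes(a[[j]]) <= tr@t[length(tr@t)] + 1 / 30))
  }
})
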