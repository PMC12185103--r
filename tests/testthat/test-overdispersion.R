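test_that("rate maps estimate homogeneous firing and mask unvisited bins", {
  tr <- simulateTrajectory(SimConfig(duration = 1200, seed = 19))
  # peak = baseline: homogeneous 2 Hz Poisson regardless of position
  cell <- CellSpec("room", c(0, 0), sigma = 10, peak = 2, baseline = 2)
  spk <- simulateEnsemble(tr, list(cell), seed = 19)[[1]]
  m <- rateMap(spk, tr, "room")
  visited <- !is.na(m@rate) & m@occupancy > 2
  expect_gt(sum(visited), 50)
  expect_equal(mean(m@rate[visited]), 2, tolerance = 0.15)
  # masked bins answer NA, never zero
  expect_true(is.na(rateAt(m, 40.9, 40.9)))
  expect_true(all(is.na(rateAt(m, c(100, -100), c(0, 0)))))
})

test_that("unsmoothed single-bin firing gives count over occupancy", {
  s <- stationarySeries(x = 10, y = 0, duration = 10)
  spk <- SpikeTrain("u", seq(0.5, 9.5, by = 0.5))
  m <- rateMap(spk, s, "room", smoothingSigma = 0, minOccupancy = 0.1)
  expect_equal(rateAt(m, 10, 0), length(spikeTimes(spk)) / 10)
})

test_that("expected counts integrate the map along the actual path", {
  flat <- constantBinnedMap(2)
  xy <- list(x = rep(5, 150), y = rep(-3, 150))
  expect_equal(expectedCount(flat, xy$x, xy$y, 1 / 30), 10)
  # half the time at 4 Hz, half at 0 Hz -> 10 spikes expected over 5 s
  half <- constantBinnedMap(4)
  half@rate[half@mids > 0, ] <- 0
  x2 <- c(rep(-5, 75), rep(5, 75))
  expect_equal(expectedCount(half, x2, rep(0, 150), 1 / 30), 10)
  # masked sample poisons the episode
  masked <- constantBinnedMap(2)
  masked@rate[1, 1] <- NA
  expect_true(is.na(expectedCount(masked, c(5, masked@mids[1]),
                                  c(5, masked@mids[1]), 1 / 30)))
})

test_that("episode z follows the standardized-deviation formula exactly", {
  s <- stationarySeries(x = 5, y = 5, duration = 50)
  cell <- GaussianRateField("room", c(5, 5), 10, peak = 1.8, baseline = 0)
  # 9 spikes inside one 5 s episode against exp = 1.8 * 5 = 9
  spk <- SpikeTrain("u", seq(10.2, 14.8, length.out = 9))
  ez <- episodeZs(spk, s, cell)
  expect_equal(nrow(ez), 10)
  expect_equal(ez$exp, rep(9, 10), tolerance = 1e-9)
  expect_equal(ez$obs[3], 9)
  expect_equal(ez$z, (ez$obs - ez$exp) / sqrt(ez$exp), tolerance = 1e-12)
  # direct formula case: obs 9, exp 4 -> z = 2.5
  expect_equal((9 - 4) / sqrt(4), 2.5)
})

test_that("the retention rule admits only high-expectation episodes", {
  tr <- simulateTrajectory(SimConfig(duration = 600, seed = 21))
  cell <- CellSpec("room", c(10, 0), sigma = 10, peak = 8, baseline = 0.5)
  spk <- simulateEnsemble(tr, list(cell), seed = 21)[[1]]
  ez <- episodeZs(spk, tr, trueRateField(cell))
  meanCount <- length(spikeTimes(spk)) / sessionLength(tr) * 5
  expect_true(all(ez$exp[ez$retained] > meanCount))
  expect_true(all(ez$exp[ez$retained] > 0))
  expect_true(any(ez$retained))
  expect_true(all(ez$reason[!ez$retained] != "ok"))
})

test_that("overdispersion variance behaves on constructed and null samples", {
  expect_equal(overdispersionVariance(c(-1, 1))$variance, 2)
  expect_equal(overdispersionVariance(rep(0.3, 10))$variance, 0)
  set.seed(12)
  ov <- overdispersionVariance(rnorm(1e4))
  expect_equal(ov$variance, 1, tolerance = 0.03)
  expect_equal(ov$n, 1e4)
})

test_that("variance ratio test matches its F construction", {
  a <- c(-sqrt(2), sqrt(2), -sqrt(2), sqrt(2))   # var 8/3
  b <- a / sqrt(2)                               # var 4/3
  vr <- varianceRatioTest(a, b)
  expect_equal(vr$F, 2)
  expect_equal(vr$dfA, 3)
  same <- varianceRatioTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 1)
  expect_equal(same$p, 1)
})

test_that("gain modulation inflates z variance above the Poisson floor", {
  tr <- simulateTrajectory(SimConfig(duration = 900, seed = 25))
  cells <- ringCells("room", n = 10, peak = 8, sigma = 10, baseline = 0.5)
  run <- function(gain) {
    trains <- simulateEnsemble(tr, cells, NULL, gain, seed = 25)
    zs <- unlist(lapply(seq_along(cells), function(j) {
      ez <- episodeZs(trains[[j]], tr, trueRateField(cells[[j]]))
      ez$z[ez$retained]
    }))
    stats::var(zs)
  }
  vNull <- run(GainProcess(1))
  vMod <- run(GainProcess(c(0.5, 1.5)))
  expect_lt(abs(vNull - 1), 0.25)
  expect_gt(vMod, vNull + 0.3)
})

test_that("preferred frame follows the coherent map", {
  tr <- simulateTrajectory(SimConfig(duration = 900, seed = 27))
  roomCell <- CellSpec("room", c(15, 0), sigma = 9, peak = 12, baseline = 0.2)
  arenaCell <- CellSpec("arena", c(0, 15), sigma = 9, peak = 12,
                        baseline = 0.2)
  spkR <- simulateEnsemble(tr, list(roomCell), seed = 27)[[1]]
  stArena <- rep(0L, length(tr@t))
  spkA <- simulateEnsemble(tr, list(arenaCell), state = stArena,
                           seed = 27)[[1]]
  expect_equal(preferredFrame(spkR, tr), "room")
  expect_equal(preferredFrame(spkA, tr), "arena")
})
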