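test_that("discretisation yields the right window count and spike counts", {
  s <- stationarySeries(duration = 600)
  silent <- SpikeTrain("s", numeric(0))
  d <- discretize(silent, s)
  expect_equal(nrow(d), 4511)            # floor(600 / 0.133)
  expect_true(all(d$i == 0))
  # one spike per window at the window rate
  dt <- 0.133
  times <- (seq_len(100) - 0.5) * dt
  one <- discretize(SpikeTrain("o", times), stationarySeries(duration = 14))
  expect_true(all(one$i[seq_len(100)] == 1))
  # counts conserve total spikes inside the covered span
  set.seed(13)
  tr <- simulateTrajectory(SimConfig(duration = 120, seed = 13))
  spk <- simulateEnsemble(tr, ringCells("room", 1), seed = 13)[[1]]
  d2 <- discretize(spk, tr)
  nWin <- nrow(d2)
  inSpan <- sum(spikeTimes(spk) < tr@t[1] + nWin * 0.133)
  expect_equal(sum(d2$i), inSpan)
})

test_that("empirical distributions normalise and match hand-built histograms", {
  # single location, always one spike
  d1 <- toyDisc(nA = 15, nB = 0, iA = 1L)
  f1 <- estimateDistributions(d1, "room")
  expect_equal(unname(f1@pCond[1, "1"]), 1)
  expect_equal(unname(f1@pMarg[f1@levels == 1]), 1)
  # two equally occupied locations, firing only at A
  d2 <- toyDisc(nA = 12, nB = 12, iA = 1L, iB = 0L)
  f2 <- estimateDistributions(d2, "room")
  expect_equal(unname(f2@pCond[1, "1"]), 1)
  expect_equal(unname(f2@pCond[2, "0"]), 1)
  expect_equal(unname(f2@pMarg[f2@levels == 1]), 0.5)
  # conditional rows sum to one on simulated data
  tr <- simulateTrajectory(SimConfig(duration = 300, seed = 29))
  spk <- simulateEnsemble(tr, ringCells("room", 1), seed = 29)[[1]]
  fr <- estimateDistributions(discretize(spk, tr), "room")
  rows <- rowSums(fr@pCond[fr@validBin, , drop = FALSE])
  expect_equal(rows, rep(1, sum(fr@validBin)), ignore_attr = TRUE)
  expect_equal(sum(fr@pMarg), 1)
})

test_that("ipos matches the information formula and its zero condition", {
  d2 <- toyDisc(nA = 12, nB = 12, iA = 1L, iB = 0L)
  f2 <- estimateDistributions(d2, "room")
  # informative query: p(1|A) = 1 against p(1) = 0.5
  expect_equal(ipos(f2, 1, 1), 1.0)
  # conditional equal to marginal carries no information
  dEq <- toyDisc(nA = 12, nB = 12, iA = 1L, iB = 1L)
  fEq <- estimateDistributions(dEq, "room")
  expect_equal(ipos(fEq, 1, 1), 0)
  # direct evaluation: p_cond 0.5, p_marg 0.25 -> 0.5
  expect_equal(abs(0.5 * log2(0.5 / 0.25)), 0.5)
  expect_error(ipos(f2, 1, 99), "not retained")
})

test_that("ipos is non-negative across simulated sessions", {
  tr <- simulateTrajectory(SimConfig(duration = 600, seed = 33))
  spk <- simulateEnsemble(tr, ringCells("room", 1, peak = 20), seed = 33)[[1]]
  ct <- cellDeltaIpos(spk, tr, includeZero = TRUE)
  expect_true(all(ct$I_room >= 0, na.rm = TRUE))
  expect_true(all(ct$I_arena >= 0, na.rm = TRUE))
})

test_that("ensemble preference averages cells and flags ties", {
  base <- data.frame(window = 1:50, t_center = (1:50 - 0.5) * 0.133,
                     i = 1L, I_room = 0.3, I_arena = 0.1, dI = 0.2)
  ens <- deltaIposEnsemble(list(base))
  expect_equal(sfepRoom(ens), 1.0)
  # opposite constant cells cancel: every window ties, proportion undefined
  neg <- base; neg$dI <- -0.2
  tied <- deltaIposEnsemble(list(base, neg))
  expect_true(is.na(sfepRoom(tied)))
  expect_equal(tied@nTies, 50L)
  expect_error(deltaIposEnsemble(list()), "no cells")
})

test_that("ensemble outputs are invariant to cell order", {
  tr <- simulateTrajectory(SimConfig(duration = 400, seed = 35))
  st <- latentState(tr, StateProcess("dwell", meanDwell = 2), seed = 35)
  trains <- simulateEnsemble(tr, c(ringCells("room", 4),
                                   ringCells("arena", 4, offset = 0.5)),
                             st, seed = 35)
  tabs <- lapply(trains, cellDeltaIpos, series = tr)
  e1 <- deltaIposEnsemble(tabs)
  e2 <- deltaIposEnsemble(rev(tabs))
  expect_equal(e1@deltaI, e2@deltaI)
  expect_equal(sfepRoom(e1), sfepRoom(e2))
})

test_that("runs test reproduces closed-form z and its type-I rate", {
  alt <- rep(c(1, -1), 10)
  rt <- runsTest(alt, threshold = 0)
  expect_equal(rt$runs, 20)
  expect_equal(rt$z, (20 - 11) / sqrt(4.7368), tolerance = 1e-4)
  blocks <- c(rep(1, 10), rep(-1, 10))
  expect_equal(runsTest(blocks, threshold = 0)$z, -(20 - 11) / sqrt(4.7368),
               tolerance = 1e-4)
  expect_error(runsTest(rep(1, 10), threshold = 0), "each side")
  # iid series: about 5% false positives
  set.seed(14)
  fp <- mean(replicate(500, abs(runsTest(rnorm(100))$z) > 1.96))
  expect_lt(abs(fp - 0.05), 0.03)
})

test_that("preference maps localise room preference and mask sparse bins", {
  tr <- simulateTrajectory(SimConfig(duration = 600, seed = 37))
  nWin <- floor(sessionLength(tr) / 0.133)
  ens <- new("EnsemblePreference",
    t = tr@t[1] + 0.133 * (seq_len(nWin) - 0.5),
    deltaI = rep(0.2, nWin), sfepRoom = 1, runsZ = 0, runsP = 1,
    nCells = 1L, nTies = 0L
  )
  pm <- preferenceMap(ens, tr)
  expect_true(all(pm@pRoom[!is.na(pm@pRoom)] == 1))
  expect_true(all(pm@count[is.na(pm@pRoom)] < pm@minSamples))
  # near/far summary of a uniform map returns the uniform value
  pmU <- pm
  pmU@pRoom[!is.na(pmU@pRoom)] <- 0.6
  part <- nearFarPartition(tr)
  nf <- nearFarSummary(pmU, part)
  expect_equal(nf$pNear, 0.6)
  expect_equal(nf$pFar, 0.6)
  expect_error(nearFarSummary(pmU, list(near = SectorSpec("room", 0, 360),
                                        far = NULL)), "far sector")
})

test_that("sfep bias test wraps a one-sample t-test against 0.5", {
  ht <- sfepBiasTest(c(0.62, 0.58, 0.65, 0.6))
  expect_equal(ht$null.value[["mean"]], 0.5)
  expect_lt(ht$p.value, 0.05)
})
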