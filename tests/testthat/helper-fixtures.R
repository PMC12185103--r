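# Programmatic fixtures shared across the suite. Everything is generated in
# code so tests carry no data files.

# trajectory moving at constant angular speed on a circle of given radius
circleSeries <- function(radius = 30, lapTime = 10, fs = 30, laps = 1,
                         theta = 0) {
  n <- round(lapTime * fs * laps)
  t <- (seq_len(n) - 1) / fs
  a <- 2 * pi * t / lapTime
  PositionSeries(t, radius * cos(a), radius * sin(a), theta)
}

# straight walk from p0 to p1 at constant speed
lineSeries <- function(p0, p1, duration = 10, fs = 30, arenaRadius = 60) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  f <- t / max(t)
  PositionSeries(t, p0[1] + f * (p1[1] - p0[1]),
                 p0[2] + f * (p1[2] - p0[2]), 0, arenaRadius = arenaRadius)
}

# motionless animal
stationarySeries <- function(x = 10, y = 0, duration = 10, fs = 30) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  PositionSeries(t, rep(x, n), rep(y, n), 0)
}

# trajectory visiting a prescribed sequence of polar angles (radius fixed)
angleSeries <- function(angles, radius = 30, fs = 30) {
  n <- length(angles)
  t <- (seq_len(n) - 1) / fs
  PositionSeries(t, radius * cos(pi / 180 * angles),
                 radius * sin(pi / 180 * angles), 0)
}

# ring of place cells covering the arena, frame-locked
ringCells <- function(frame, n = 10, peak = 30, sigma = 10,
                      baseline = 0.05, offset = 0) {
  lapply(seq_len(n), function(j) {
    a <- 2 * pi * (j + offset) / n
    r <- c(12, 18, 24)[j %% 3 + 1]
    CellSpec(frame, c(r * cos(a), r * sin(a)), sigma = sigma, peak = peak,
             baseline = baseline)
  })
}

# minimal discretize()-shaped table for distribution tests: windows at two
# spatial bins with prescribed activity levels
toyDisc <- function(binA = 1L, binB = 2L, nA = 12L, nB = 12L,
                    iA = 1L, iB = 0L) {
  n <- nA + nB
  out <- data.frame(
    window = seq_len(n), t_center = (seq_len(n) - 0.5) * 0.133,
    i = c(rep(iA, nA), rep(iB, nB)),
    x_room = 0, y_room = 0, x_arena = 0, y_arena = 0,
    roomBin = c(rep(binA, nA), rep(binB, nB)),
    arenaBin = c(rep(binA, nA), rep(binB, nB))
  )
  attr(out, "nGrid") <- 2L
  attr(out, "dt") <- 0.133
  out
}

# hand-built constant-rate binned map spanning the default 41 cm arena
constantBinnedMap <- function(rateHz, frame = "room", binCm = 2.5, R = 41) {
  nb <- ceiling(2 * R / binCm)
  mids <- -R + binCm * (seq_len(nb) - 0.5)
  new("BinnedRateMap",
    frame = frame, mids = mids,
    rate = matrix(rateHz, nb, nb), occupancy = matrix(1, nb, nb),
    binCm = binCm, smoothingSigma = 0, minOccupancy = 0
  )
}
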