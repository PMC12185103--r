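# Synthetic rotating-arena sessions. The generator is an explicit stand-in:
# the analyses below are defined for real recordings; these processes give
# them a known ground truth (frame-locked Gaussian tuning, latent frame
# switching, per-pass gain modulation) to be recovered.

#' Simulation configuration
#'
#' Apparatus and locomotion parameters of a synthetic session: an 82 cm
#' diameter arena rotating at 1 rpm, tracked at 30 Hz, with the rat's path
#' modelled as an Ornstein-Uhlenbeck velocity process reflected at the wall.
#'
#' @slot arenaRadius cm (default 41).
#' @slot rotationRpm signed rotation rate, revolutions per minute (default 1;
#'   the sign encodes direction, which the task apparatus leaves free).
#' @slot fs sampling rate, Hz (default 30).
#' @slot duration session length, s.
#' @slot ouTau velocity relaxation time, s.
#' @slot ouSigma stationary per-axis speed scale, cm/s.
#' @slot avoidanceGain dimensionless repulsion strength from a stationary
#'   room-frame sector (0 = free foraging).
#' @slot avoidanceZone [SectorSpec-class] repelled from when avoidanceGain > 0.
#' @slot seed master seed; substreams for trajectory, state, gain and each
#'   cell are derived from it so components are individually reproducible.
#' @export
setClass("SimConfig",
  representation(
    arenaRadius = "numeric", rotationRpm = "numeric", fs = "numeric",
    duration = "numeric", ouTau = "numeric", ouSigma = "numeric",
    avoidanceGain = "numeric", avoidanceZone = "SectorSpec", seed = "numeric"
  ),
  prototype(
    arenaRadius = 41, rotationRpm = 1, fs = 30, duration = 600,
    ouTau = 1, ouSigma = 8, avoidanceGain = 0,
    avoidanceZone = new("SectorSpec", frame = "room", center = 0, width = 60),
    seed = 1
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@fs <= 0) msgs <- c(msgs, "fs must be positive")
  if (object@duration <= 0) msgs <- c(msgs, "duration must be positive")
  if (object@arenaRadius <= 0) msgs <- c(msgs, "arenaRadius must be positive")
  if (object@ouTau <= 0) msgs <- c(msgs, "ouTau must be positive")
  if (object@ouSigma < 0) msgs <- c(msgs, "ouSigma must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimConfig
#' @param duration session length, s.
#' @param seed master seed (integer < 2^31).
#' @param arenaRadius,rotationRpm,fs,ouTau,ouSigma,avoidanceGain,avoidanceZone
#'   see [SimConfig-class].
#' @return A [SimConfig-class].
#' @export
SimConfig <- function(duration = 600, seed = 1, arenaRadius = 41,
                      rotationRpm = 1, fs = 30, ouTau = 1, ouSigma = 8,
                      avoidanceGain = 0,
                      avoidanceZone = SectorSpec("room", 0, 60)) {
  new("SimConfig",
    arenaRadius = arenaRadius, rotationRpm = rotationRpm, fs = fs,
    duration = duration, ouTau = ouTau, ouSigma = ouSigma,
    avoidanceGain = avoidanceGain, avoidanceZone = avoidanceZone, seed = seed
  )
}

#' Place-cell tuning specification
#'
#' Gaussian spatial tuning anchored to one spatial frame.
#'
#' @slot frame "room" or "arena".
#' @slot center field centre, cm, in that frame.
#' @slot sigma field width, cm.
#' @slot peak,baseline spikes/s, peak >= baseline >= 0.
#' @export
setClass("CellSpec",
  representation(
    frame = "character", center = "numeric", sigma = "numeric",
    peak = "numeric", baseline = "numeric"
  ),
  prototype(frame = "room", sigma = 10, peak = 10, baseline = 0.1)
)

setValidity("CellSpec", function(object) {
  msgs <- character()
  if (!(object@frame %in% c("room", "arena"))) {
    msgs <- c(msgs, "frame must be 'room' or 'arena'")
  }
  if (length(object@center) != 2) msgs <- c(msgs, "center must be length 2")
  if (object@sigma <= 0) msgs <- c(msgs, "sigma must be positive")
  if (object@baseline < 0 || object@peak < object@baseline) {
    msgs <- c(msgs, "need peak >= baseline >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CellSpec
#' @param frame "room" or "arena".
#' @param center field centre, cm (length-2).
#' @param sigma field width, cm.
#' @param peak,baseline firing rates, spikes/s.
#' @return A [CellSpec-class].
#' @export
CellSpec <- function(frame = "room", center = c(0, 0), sigma = 10,
                     peak = 10, baseline = 0.1) {
  new("CellSpec",
    frame = frame, center = as.numeric(center), sigma = sigma,
    peak = peak, baseline = baseline
  )
}

#' The generative rate field of a CellSpec
#' @param cell a [CellSpec-class].
#' @return the matching [GaussianRateField-class] (the ground-truth rate map).
#' @export
trueRateField <- function(cell) {
  stopifnot(is(cell, "CellSpec"))
  GaussianRateField(cell@frame, cell@center, cell@sigma, cell@peak,
                    cell@baseline)
}

#' Latent spatial-frame state process specification
#'
#' The ensemble-level state alternating between the room and arena frames on
#' a seconds timescale. In `dwell` mode the state strictly alternates, with
#' exponential dwell durations whose means are 2 p `meanDwell` (room) and
#' 2 (1 - p) `meanDwell` (arena) with p = `pRoomNear`, so the overall mean
#' dwell is `meanDwell` and the long-run room-time fraction is exactly p.
#' In `proximity` mode dwells renew on an exponential clock of mean
#' `meanDwell` and each renewal draws room with probability `pRoomNear` when
#' the animal is within 90 degrees of the zone centre, `pRoomFar` otherwise.
#' Mode `none` pins the state to room throughout.
#'
#' @slot mode "none", "dwell" or "proximity".
#' @slot meanDwell mean dwell time, s.
#' @slot pRoomNear room-time fraction (dwell mode) / near-half renewal
#'   probability of the room state (proximity mode).
#' @slot pRoomFar far-half renewal probability (proximity mode).
#' @slot zone room-frame [SectorSpec-class] defining proximity.
#' @export
setClass("StateProcess",
  representation(
    mode = "character", meanDwell = "numeric",
    pRoomNear = "numeric", pRoomFar = "numeric", zone = "SectorSpec"
  ),
  prototype(
    mode = "none", meanDwell = 5, pRoomNear = 0.5, pRoomFar = 0.5,
    zone = new("SectorSpec", frame = "room", center = 0, width = 60)
  )
)

setValidity("StateProcess", function(object) {
  msgs <- character()
  if (!(object@mode %in% c("none", "dwell", "proximity"))) {
    msgs <- c(msgs, "mode must be none, dwell or proximity")
  }
  if (object@meanDwell <= 0) msgs <- c(msgs, "meanDwell must be positive")
  for (p in c(object@pRoomNear, object@pRoomFar)) {
    if (p < 0 || p > 1) msgs <- c(msgs, "probabilities must be in [0,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StateProcess
#' @param mode "none", "dwell" or "proximity".
#' @param meanDwell mean dwell time, s.
#' @param pRoomNear,pRoomFar renewal probabilities of the room state.
#' @param zone room-frame zone for proximity mode.
#' @return A [StateProcess-class].
#' @export
StateProcess <- function(mode = "none", meanDwell = 5, pRoomNear = 0.5,
                         pRoomFar = 0.5, zone = SectorSpec("room", 0, 60)) {
  new("StateProcess",
    mode = mode, meanDwell = meanDwell, pRoomNear = pRoomNear,
    pRoomFar = pRoomFar, zone = zone
  )
}

#' Per-pass gain modulation specification
#'
#' Multiplicative gain held constant over consecutive `passLength`-second
#' segments and redrawn independently per segment — a minimal stand-in for
#' the slow extra-positional modulation that overdispersion detects. Gains
#' `{1}` reduce to a pure inhomogeneous-Poisson cell.
#'
#' @slot gains non-negative multipliers.
#' @slot probs sampling probabilities (sum to 1).
#' @slot passLength segment length, s (default 5, the overdispersion episode).
#' @export
setClass("GainProcess",
  representation(gains = "numeric", probs = "numeric", passLength = "numeric"),
  prototype(gains = 1, probs = 1, passLength = 5)
)

setValidity("GainProcess", function(object) {
  msgs <- character()
  if (length(object@gains) != length(object@probs)) {
    msgs <- c(msgs, "gains and probs must have equal length")
  }
  if (any(object@gains < 0)) msgs <- c(msgs, "gains must be non-negative")
  if (abs(sum(object@probs) - 1) > 1e-8) {
    msgs <- c(msgs, "probs must sum to 1")
  }
  if (object@passLength <= 0) msgs <- c(msgs, "passLength must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GainProcess
#' @param gains multipliers.
#' @param probs sampling probabilities (default uniform).
#' @param passLength segment length, s.
#' @return A [GainProcess-class].
#' @export
GainProcess <- function(gains = 1, probs = rep(1 / length(gains),
                                               length(gains)),
                        passLength = 5) {
  new("GainProcess", gains = as.numeric(gains), probs = as.numeric(probs),
      passLength = passLength)
}

# Derive an independent substream seed from the master seed. Exact in double
# arithmetic and bounded below 2^31 - 1.
childSeed <- function(seed, k) {
  ((seed %% 65011) * 33013 + k * 9973 + 17) %% 2147483647
}

#' Simulate a foraging trajectory on the rotating arena
#'
#' Ornstein-Uhlenbeck velocity random walk (exact discretisation per sample
#' step), specular reflection of position and velocity at the wall, and, for
#' `avoidanceGain > 0`, a tangential repulsion from the configured room-frame
#' sector that depresses occupancy inside it. The arena rotation angle is
#' `theta(t) = 6 * rotationRpm * t` degrees.
#'
#' @param cfg a [SimConfig-class].
#' @return A [PositionSeries-class].
#' @export
simulateTrajectory <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(childSeed(cfg@seed, 1))
  dt <- 1 / cfg@fs
  n <- round(cfg@duration * cfg@fs)
  t <- (seq_len(n) - 1) * dt
  R <- cfg@arenaRadius
  a <- exp(-dt / cfg@ouTau)
  sdInc <- cfg@ouSigma * sqrt(1 - a^2)
  x <- numeric(n); y <- numeric(n)
  # start mid-radius so degenerate (sigma = 0) runs are not at the origin
  x[1] <- R / 2; y[1] <- 0
  vx <- 0; vy <- 0
  noise <- matrix(stats::rnorm(2 * n, sd = sdInc), ncol = 2)
  zc <- cfg@avoidanceZone@center
  zw <- cfg@avoidanceZone@width
  for (i in seq_len(n - 1L)) {
    vx <- a * vx + noise[i, 1]
    vy <- a * vy + noise[i, 2]
    if (cfg@avoidanceGain > 0) {
      ang <- atan2(y[i], x[i]) * 180 / pi
      d <- ((ang - zc + 180) %% 360) - 180  # signed offset from zone centre
      reach <- zw / 2 + 45
      if (abs(d) < reach) {
        # tangential push away from the zone centre, fading with offset
        f <- cfg@avoidanceGain * cfg@ouSigma / cfg@ouTau *
          (1 - abs(d) / reach)
        s <- if (d >= 0) 1 else -1
        aa <- atan2(y[i], x[i])
        vx <- vx + s * f * (-sin(aa)) * dt
        vy <- vy + s * f * cos(aa) * dt
      }
    }
    xn <- x[i] + vx * dt
    yn <- y[i] + vy * dt
    r <- sqrt(xn^2 + yn^2)
    if (r > R) {
      # specular bounce: fold the overshoot back inside, reflect the
      # radial velocity component
      xn <- xn * (2 * R - r) / r
      yn <- yn * (2 * R - r) / r
      nx <- x[i]; ny <- y[i]
      nr <- sqrt(nx^2 + ny^2)
      if (nr > 0) {
        nx <- nx / nr; ny <- ny / nr
        vr <- vx * nx + vy * ny
        vx <- vx - 2 * vr * nx
        vy <- vy - 2 * vr * ny
      } else {
        vx <- -vx; vy <- -vy
      }
    }
    x[i + 1L] <- xn
    y[i + 1L] <- yn
  }
  PositionSeries(t, x, y, 6 * cfg@rotationRpm * t, arenaRadius = R)
}

#' Simulate the latent spatial-frame state
#'
#' @param series the session [PositionSeries-class] (proximity mode reads
#'   the room-frame position at each renewal).
#' @param sp a [StateProcess-class].
#' @param seed substream seed.
#' @return integer vector per sample: 1 = room state, 0 = arena state.
#' @export
latentState <- function(series, sp, seed = 1) {
  stopifnot(is(series, "PositionSeries"), is(sp, "StateProcess"))
  validObject(sp)
  n <- length(series@t)
  if (sp@mode == "none") return(rep(1L, n))
  set.seed(childSeed(seed, 2))
  state <- integer(n)
  dt <- 1 / samplingRate(series)
  if (sp@mode == "dwell") {
    p <- sp@pRoomNear
    if (p <= 0) return(rep(0L, n))
    if (p >= 1) return(rep(1L, n))
    meanRoom <- 2 * p * sp@meanDwell
    meanArena <- 2 * (1 - p) * sp@meanDwell
    s <- if (stats::runif(1) < p) 1L else 0L
    i <- 1L
    while (i <= n) {
      m <- if (s == 1L) meanRoom else meanArena
      len <- max(1L, round(stats::rexp(1, 1 / m) / dt))
      j <- min(n, i + len - 1L)
      state[i:j] <- s
      s <- 1L - s
      i <- j + 1L
    }
  } else {
    i <- 1L
    while (i <= n) {
      ang <- atan2(series@y[i], series@x[i]) * 180 / pi
      d <- abs(((ang - sp@zone@center + 180) %% 360) - 180)
      p <- if (d <= 90) sp@pRoomNear else sp@pRoomFar
      s <- if (stats::runif(1) < p) 1L else 0L
      len <- max(1L, round(stats::rexp(1, 1 / sp@meanDwell) / dt))
      j <- min(n, i + len - 1L)
      state[i:j] <- s
      i <- j + 1L
    }
  }
  state
}

# per-sample rate of one cell given trajectory, state and gain
cellRate <- function(cell, series, arenaXY, state, gain) {
  if (cell@frame == "room") {
    px <- series@x; py <- series@y
  } else {
    px <- arenaXY$x; py <- arenaXY$y
  }
  d2 <- (px - cell@center[1])^2 + (py - cell@center[2])^2
  rate <- cell@baseline +
    (cell@peak - cell@baseline) * exp(-d2 / (2 * cell@sigma^2))
  # state disagreement suppresses tuning to baseline (keeps p(i) estimable)
  agree <- if (cell@frame == "room") state == 1L else state == 0L
  rate[!agree] <- cell@baseline
  rate * gain
}

#' Simulate an ensemble of place cells
#'
#' Per sample, each cell's rate is baseline + (peak - baseline)
#' exp(-d^2 / 2 sigma^2) with d measured in the cell's own frame, suppressed
#' to baseline whenever the latent state disagrees with that frame, and
#' multiplied by the current per-pass gain. Spikes are Poisson counts per
#' 1/fs bin with times jittered uniformly within the bin, so the generator
#' is an exact inhomogeneous-Poisson oracle at bin resolution.
#'
#' @param series the session [PositionSeries-class].
#' @param cells list of [CellSpec-class].
#' @param state integer room/arena state per sample (NULL = all room).
#' @param gain a [GainProcess-class] (default: constant gain 1).
#' @param seed master seed; each cell gets its own substream.
#' @return list of [SpikeTrain-class], one per cell, unit ids "u001", ...
#' @export
simulateEnsemble <- function(series, cells, state = NULL,
                             gain = GainProcess(), seed = 1) {
  stopifnot(is(series, "PositionSeries"), length(cells) > 0)
  lapply(cells, function(cl) stopifnot(is(cl, "CellSpec")))
  validObject(gain)
  n <- length(series@t)
  if (is.null(state)) state <- rep(1L, n)
  stopifnot(length(state) == n)
  dt <- 1 / samplingRate(series)
  arenaXY <- arenaCoordinates(series)
  # per-pass gain: one draw per passLength segment
  set.seed(childSeed(seed, 3))
  nSeg <- ceiling(n * dt / gain@passLength)
  segGain <- sample(gain@gains, nSeg, replace = TRUE, prob = gain@probs)
  segIdx <- pmin(nSeg, floor((series@t - series@t[1]) / gain@passLength) + 1L)
  g <- segGain[segIdx]
  trains <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    set.seed(childSeed(seed, 100 + j))
    rate <- cellRate(cells[[j]], series, arenaXY, state, g)
    counts <- stats::rpois(n, rate * dt)
    which0 <- which(counts > 0L)
    times <- rep(series@t[which0], counts[which0]) +
      stats::runif(sum(counts)) * dt
    trains[[j]] <- SpikeTrain(sprintf("u%03d", j), times,
      waveformUs = 320, regionTag = "hippocampus")
  }
  trains
}
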