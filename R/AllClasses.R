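#' @import methods
NULL

#' PositionSeries: a tracked trajectory in the room frame plus arena rotation
#'
#' Holds a uniformly sampled position time series: timestamps (s), room-frame
#' coordinates (cm, origin at the arena centre) and the accumulated arena
#' rotation angle (degrees, counterclockwise positive, not wrapped so the
#' rotation count is recoverable).
#'
#' @slot t numeric, timestamps in seconds, strictly increasing, uniform step.
#' @slot x,y numeric, room-frame coordinates in cm.
#' @slot theta numeric, accumulated arena rotation angle in degrees.
#' @slot arenaRadius single numeric, arena radius in cm (default 41).
#'
#' @export
setClass("PositionSeries",
  representation(
    t = "numeric", x = "numeric", y = "numeric", theta = "numeric",
    arenaRadius = "numeric"
  ),
  prototype(arenaRadius = 41)
)

setValidity("PositionSeries", function(object) {
  msgs <- character()
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@theta) != n) {
    msgs <- c(msgs, "t, x, y, theta must have equal length")
  }
  if (n >= 2) {
    dt <- diff(object@t)
    if (any(dt <= 0)) msgs <- c(msgs, "t must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      msgs <- c(msgs, "t must lie on a uniform grid")
    }
  }
  if (length(object@arenaRadius) != 1 || object@arenaRadius <= 0) {
    msgs <- c(msgs, "arenaRadius must be a single positive number")
  }
  if (n > 0 && length(object@x) == n && length(object@y) == n) {
    r <- sqrt(object@x^2 + object@y^2)
    # 5 cm tracking slack over the wall before we call the file corrupt
    if (any(is.finite(r) & (r > object@arenaRadius + 5))) {
      msgs <- c(msgs, sprintf(
        "positions exceed arena radius %.1f cm (+5 cm tolerance)",
        object@arenaRadius
      ))
    }
    if (any(!is.finite(object@x)) || any(!is.finite(object@y)) ||
        any(!is.finite(object@theta)) || any(!is.finite(object@t))) {
      msgs <- c(msgs, "coordinates, theta and t must be finite")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PositionSeries
#'
#' @param t timestamps (s), uniform grid.
#' @param x,y room-frame coordinates (cm).
#' @param theta accumulated arena rotation (degrees); scalar is recycled.
#' @param arenaRadius arena radius in cm.
#' @return A [PositionSeries-class] object.
#' @export
PositionSeries <- function(t, x, y, theta = 0, arenaRadius = 41) {
  if (length(theta) == 1) theta <- rep(theta, length(t))
  new("PositionSeries",
    t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
    theta = as.numeric(theta), arenaRadius = arenaRadius
  )
}

#' @describeIn PositionSeries number of samples
#' @param x a PositionSeries
#' @export
setMethod("length", "PositionSeries", function(x) length(x@t))

setMethod("show", "PositionSeries", function(object) {
  n <- length(object@t)
  cat(sprintf(
    "PositionSeries: %d samples, %.1f s, fs ~ %.1f Hz, arena radius %.1f cm\n",
    n, if (n) diff(range(object@t)) else 0,
    if (n > 1) 1 / stats::median(diff(object@t)) else NA_real_,
    object@arenaRadius
  ))
  if (n) {
    cat(sprintf(
      "  theta: %.1f .. %.1f deg (%.2f revolutions)\n",
      object@theta[1], object@theta[n],
      (object@theta[n] - object@theta[1]) / 360
    ))
  }
})

#' Sampling rate of a PositionSeries
#' @param series a [PositionSeries-class].
#' @return sampling rate in Hz.
#' @export
samplingRate <- function(series) {
  stopifnot(is(series, "PositionSeries"), length(series@t) >= 2)
  1 / stats::median(diff(series@t))
}

#' Session length of a PositionSeries
#' @param series a [PositionSeries-class].
#' @return duration in seconds (last minus first timestamp plus one step).
#' @export
sessionLength <- function(series) {
  stopifnot(is(series, "PositionSeries"))
  n <- length(series@t)
  if (n < 2) return(0)
  dt <- stats::median(diff(series@t))
  series@t[n] - series@t[1] + dt
}

#' SectorSpec: an angular sector of the arena in a named spatial frame
#'
#' Sectors define the shock zone (60 degrees, room frame), the least-visited
#' seed sector (20 degrees) and the near/far partition. Membership is
#' half-open on the leading edge: a point at polar angle a is inside iff
#' a lies in \[center - width/2, center + width/2) modulo 360.
#'
#' @slot frame "room" or "arena".
#' @slot center sector centre angle, degrees.
#' @slot width angular width, degrees, in (0, 360].
#' @export
setClass("SectorSpec",
  representation(frame = "character", center = "numeric", width = "numeric")
)

setValidity("SectorSpec", function(object) {
  msgs <- character()
  if (!(object@frame %in% c("room", "arena"))) {
    msgs <- c(msgs, "frame must be 'room' or 'arena'")
  }
  if (length(object@width) != 1 || !is.finite(object@width) ||
      object@width <= 0 || object@width > 360) {
    msgs <- c(msgs, "width must be in (0, 360]")
  }
  if (length(object@center) != 1 || !is.finite(object@center)) {
    msgs <- c(msgs, "center must be a finite scalar")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SectorSpec
#' @param frame "room" or "arena".
#' @param center centre angle in degrees.
#' @param width angular width in degrees (shock zone: 60; seed sector: 20).
#' @return A [SectorSpec-class] object.
#' @export
SectorSpec <- function(frame = "room", center = 0, width = 60) {
  new("SectorSpec", frame = frame, center = as.numeric(center),
      width = as.numeric(width))
}

setMethod("show", "SectorSpec", function(object) {
  cat(sprintf(
    "SectorSpec: %s frame, center %.1f deg, width %.1f deg\n",
    object@frame, object@center, object@width
  ))
})

#' SpikeTrain: sorted spike times for one unit
#'
#' @slot unitId character identifier.
#' @slot times numeric spike times in seconds, strictly increasing.
#' @slot waveformUs waveform duration in microseconds (NA if unknown).
#' @slot regionTag "hippocampus", "thalamus" or "unknown".
#' @export
setClass("SpikeTrain",
  representation(
    unitId = "character", times = "numeric",
    waveformUs = "numeric", regionTag = "character"
  ),
  prototype(waveformUs = NA_real_, regionTag = "unknown")
)

setValidity("SpikeTrain", function(object) {
  msgs <- character()
  if (length(object@times) >= 2 && any(diff(object@times) <= 0)) {
    msgs <- c(msgs, "spike times must be strictly increasing")
  }
  if (!(object@regionTag %in% c("hippocampus", "thalamus", "unknown"))) {
    msgs <- c(msgs, "regionTag must be hippocampus, thalamus or unknown")
  }
  if (!is.na(object@waveformUs) && object@waveformUs < 0) {
    msgs <- c(msgs, "waveformUs must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpikeTrain
#' @param unitId unit identifier.
#' @param times spike times in seconds (sorted internally; exact duplicates
#'   are offset is an error — deduplicate upstream).
#' @param waveformUs waveform duration, microseconds.
#' @param regionTag recording region tag.
#' @return A [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(unitId, times, waveformUs = NA_real_,
                       regionTag = "unknown") {
  new("SpikeTrain",
    unitId = as.character(unitId), times = sort(as.numeric(times)),
    waveformUs = as.numeric(waveformUs), regionTag = regionTag
  )
}

#' @describeIn SpikeTrain number of spikes
#' @param x a SpikeTrain
#' @export
setMethod("length", "SpikeTrain", function(x) length(x@times))

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf(
    "SpikeTrain '%s': %d spikes%s, region %s\n",
    object@unitId, length(object@times),
    if (is.na(object@waveformUs)) "" else
      sprintf(", waveform %.0f us", object@waveformUs),
    object@regionTag
  ))
})

#' Spike times accessor
#' @param train a [SpikeTrain-class].
#' @return numeric vector of spike times (s).
#' @export
spikeTimes <- function(train) {
  stopifnot(is(train, "SpikeTrain"))
  train@times
}

# ---- rate sources -----------------------------------------------------------

#' Virtual parent of rate-map representations
#'
#' Anything that can answer [rateAt()] queries: an estimated, binned map
#' ([BinnedRateMap-class]) or an analytic generative field
#' ([GaussianRateField-class]).
#' @export
setClass("RateSource", representation("VIRTUAL", frame = "character"))

#' BinnedRateMap: an occupancy-normalised, smoothed firing-rate map
#'
#' Spikes and occupancy are binned on a square grid clipped to the arena disk
#' in the chosen frame, smoothed with a shared Gaussian kernel, and divided.
#' Bins whose raw occupancy is below `minOccupancy` are masked: queries there
#' return NA, never 0.
#'
#' @slot frame "room" or "arena".
#' @slot mids bin centre coordinates (shared by x and y), cm.
#' @slot rate matrix of firing rates, spikes/s; NA where masked.
#' @slot occupancy matrix of raw occupancy, seconds.
#' @slot binCm bin size, cm.
#' @slot smoothingSigma smoothing kernel sigma, bins.
#' @slot minOccupancy occupancy mask threshold, seconds.
#' @export
setClass("BinnedRateMap",
  contains = "RateSource",
  representation(
    mids = "numeric", rate = "matrix", occupancy = "matrix",
    binCm = "numeric", smoothingSigma = "numeric", minOccupancy = "numeric"
  )
)

setValidity("BinnedRateMap", function(object) {
  msgs <- character()
  if (!all(dim(object@rate) == dim(object@occupancy))) {
    msgs <- c(msgs, "rate and occupancy must have identical dimensions")
  }
  if (any(object@rate < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "rates must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BinnedRateMap", function(object) {
  cat(sprintf(
    "BinnedRateMap (%s frame): %dx%d bins of %.1f cm, %d masked, peak %.2f Hz\n",
    object@frame, nrow(object@rate), ncol(object@rate), object@binCm,
    sum(is.na(object@rate)), suppressWarnings(max(object@rate, na.rm = TRUE))
  ))
})

#' GaussianRateField: an analytic place-field rate function
#'
#' The generative tuning model of the simulator expressed as a rate source:
#' rate(x) = baseline + (peak - baseline) exp(-d^2 / (2 sigma^2)) with d the
#' distance to the field centre measured in the cell's frame. Used as the
#' ground-truth expectation when calibrating overdispersion against the
#' inhomogeneous-Poisson model.
#'
#' @slot center field centre (cm, length 2) in `frame`.
#' @slot sigma field width, cm.
#' @slot peak,baseline firing rates, spikes/s.
#' @export
setClass("GaussianRateField",
  contains = "RateSource",
  representation(
    center = "numeric", sigma = "numeric",
    peak = "numeric", baseline = "numeric"
  )
)

setValidity("GaussianRateField", function(object) {
  msgs <- character()
  if (length(object@center) != 2) msgs <- c(msgs, "center must be length 2")
  if (object@sigma <= 0) msgs <- c(msgs, "sigma must be positive")
  if (object@baseline < 0 || object@peak < object@baseline) {
    msgs <- c(msgs, "need peak >= baseline >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GaussianRateField
#' @param frame "room" or "arena" — the frame in which tuning is anchored.
#' @param center field centre, cm (length-2).
#' @param sigma field width, cm.
#' @param peak,baseline peak and baseline rates, spikes/s.
#' @return A [GaussianRateField-class].
#' @export
GaussianRateField <- function(frame, center, sigma, peak, baseline = 0) {
  new("GaussianRateField",
    frame = frame, center = as.numeric(center), sigma = sigma,
    peak = peak, baseline = baseline
  )
}

setMethod("show", "GaussianRateField", function(object) {
  cat(sprintf(
    "GaussianRateField (%s frame): center (%.1f, %.1f) cm, sigma %.1f cm, %.1f->%.1f Hz\n",
    object@frame, object@center[1], object@center[2], object@sigma,
    object@baseline, object@peak
  ))
})

# ---- frame distributions and ensemble preference ----------------------------

#' FrameDistributions: empirical p(i | x) and p(i) for one frame
#'
#' Joint histogram of discretised activity levels i (spike counts per
#' time window) against spatial bins in one frame, with the conditional
#' rows normalised per visited bin and the marginal over all retained
#' windows. Bins with fewer than `minSamples` windows are dropped from the
#' estimate and from any information series built on it.
#'
#' @slot frame "room" or "arena".
#' @slot levels integer activity levels (top level pools the capped tail).
#' @slot pCond matrix bins x levels, rows sum to 1 for retained bins.
#' @slot pMarg numeric, marginal activity distribution, sums to 1.
#' @slot binCount windows per spatial bin.
#' @slot validBin logical, bins with enough windows to estimate p(i|x).
#' @slot cap activity cap (counts above are pooled into the top level).
#' @slot nGrid grid resolution per axis.
#' @slot dt window length, s.
#' @export
setClass("FrameDistributions",
  representation(
    frame = "character", levels = "integer", pCond = "matrix",
    pMarg = "numeric", binCount = "integer", validBin = "logical",
    cap = "integer", nGrid = "integer", dt = "numeric"
  )
)

setValidity("FrameDistributions", function(object) {
  msgs <- character()
  if (abs(sum(object@pMarg) - 1) > 1e-8) {
    msgs <- c(msgs, "marginal must sum to 1")
  }
  rs <- rowSums(object@pCond[object@validBin, , drop = FALSE])
  if (length(rs) && any(abs(rs - 1) > 1e-8)) {
    msgs <- c(msgs, "conditional rows must sum to 1 on valid bins")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FrameDistributions", function(object) {
  cat(sprintf(
    "FrameDistributions (%s frame): %d valid bins of %d, activity levels 0..%d, dt %.3f s\n",
    object@frame, sum(object@validBin), length(object@validBin),
    max(object@levels), object@dt
  ))
})

#' EnsemblePreference: ensemble delta-Ipos series and its SFEP summary
#'
#' @slot t window-centre times, s.
#' @slot deltaI ensemble mean delta-Ipos per window (room minus arena).
#' @slot sfepRoom proportion of non-tied windows with room preference.
#' @slot runsZ runs-test z of the ensemble series about its mean.
#' @slot runsP two-sided normal p for runsZ.
#' @slot nCells number of cells averaged.
#' @slot nTies number of exactly-tied windows excluded from the proportion.
#' @export
setClass("EnsemblePreference",
  representation(
    t = "numeric", deltaI = "numeric", sfepRoom = "numeric",
    runsZ = "numeric", runsP = "numeric", nCells = "integer",
    nTies = "integer"
  )
)

setMethod("show", "EnsemblePreference", function(object) {
  cat(sprintf(
    "EnsemblePreference: %d windows, %d cells; SFEP(room) = %.3f; runs z = %.2f (p = %.3g)\n",
    length(object@t), object@nCells, object@sfepRoom, object@runsZ,
    object@runsP
  ))
})

#' sfepRoom accessor
#' @param x an [EnsemblePreference-class].
#' @return proportion of room-preferring windows.
#' @export
sfepRoom <- function(x) {
  stopifnot(is(x, "EnsemblePreference"))
  x@sfepRoom
}

#' PreferenceMap: spatial probability of room-frame preference
#'
#' @slot mids bin centre coordinates, cm (room frame).
#' @slot pRoom matrix, P(room-preferring | location); NA where masked.
#' @slot count matrix, windows per bin.
#' @slot minSamples mask threshold.
#' @export
setClass("PreferenceMap",
  representation(
    mids = "numeric", pRoom = "matrix", count = "matrix",
    minSamples = "integer"
  )
)

setMethod("show", "PreferenceMap", function(object) {
  cat(sprintf(
    "PreferenceMap: %dx%d bins, %d unmasked, mean P(room) = %.3f\n",
    nrow(object@pRoom), ncol(object@pRoom), sum(!is.na(object@pRoom)),
    mean(object@pRoom, na.rm = TRUE)
  ))
})

# ---- CO region table --------------------------------------------------------

#' Canonical brain regions of the cytochrome-oxidase panel
#'
#' The 14 functionally related regions whose pairwise CO-activity
#' correlations define the metabolic covariance network.
#' @export
canonicalRegions <- c(
  "RSD", "RSG", "RE", "CEA", "BMA", "BLA", "dCA1", "dCA2", "dCA3",
  "dDG", "vCA1", "vCA3", "vDG", "DS"
)

#' RegionTable: subject-by-region normalised CO activity
#'
#' @slot values numeric matrix, subjects x regions.
#' @slot group character, per-subject group label ("sham"/"lesion").
#' @export
setClass("RegionTable",
  representation(values = "matrix", group = "character")
)

setValidity("RegionTable", function(object) {
  msgs <- character()
  if (nrow(object@values) != length(object@group)) {
    msgs <- c(msgs, "one group label per subject row")
  }
  if (is.null(colnames(object@values))) {
    msgs <- c(msgs, "region columns must be named")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionTable
#' @param values subjects x regions numeric matrix (rownames = subjects,
#'   colnames = regions).
#' @param group per-subject group labels.
#' @return A [RegionTable-class].
#' @export
RegionTable <- function(values, group) {
  new("RegionTable", values = as.matrix(values), group = as.character(group))
}

setMethod("show", "RegionTable", function(object) {
  cat(sprintf(
    "RegionTable: %d subjects x %d regions (%s)\n",
    nrow(object@values), ncol(object@values),
    paste(sprintf("%s: %d", names(table(object@group)),
                  as.integer(table(object@group))), collapse = ", ")
  ))
})
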