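# Basic discharge properties and the cell-type gates that admit units into
# the place-coding analyses.

#' Mean firing rate
#' @param train a [SpikeTrain-class].
#' @param sessionLength recording length, s (> 0).
#' @return spikes/s.
#' @export
meanRate <- function(train, sessionLength) {
  stopifnot(is(train, "SpikeTrain"), sessionLength > 0)
  length(train@times) / sessionLength
}

#' Burst ratio
#'
#' Count of inter-spike intervals no longer than 30 ms divided by the count
#' of intervals in the closed window 100-130 ms. Each interval is attributed
#' once, so the ratio is symmetric in spike order and invariant to a uniform
#' time shift. When no interval falls in the 100-130 ms window the ratio is
#' undefined: NA is returned with a warning and such units are excluded from
#' group means.
#'
#' @param train a [SpikeTrain-class] with at least 2 spikes.
#' @return dimensionless ratio, or NA when undefined.
#' @export
burstRatio <- function(train) {
  stopifnot(is(train, "SpikeTrain"))
  if (length(train@times) < 2) stop("burstRatio: need at least 2 spikes")
  isi <- diff(train@times)
  den <- sum(isi >= 0.100 & isi <= 0.130)
  if (den == 0) {
    warning("burstRatio undefined: no inter-spike interval in 100-130 ms")
    return(NA_real_)
  }
  sum(isi <= 0.030) / den
}

#' Classify a unit as pyramidal, theta or unclassified
#'
#' Complex-spike (pyramidal) cells: waveform duration > 250 us and rate
#' < 5 spikes/s. Theta cells (putative interneurons): duration < 250 us and
#' rate > 2 spikes/s. Everything else — including units whose features
#' satisfy neither gate — is unclassified. Only hippocampal pyramidal units
#' enter the overdispersion and frame-preference pipelines.
#'
#' @param meanRate spikes/s.
#' @param waveformUs waveform duration, microseconds (NA allowed).
#' @return one of "pyramidal", "theta", "unclassified".
#' @export
classifyUnit <- function(meanRate, waveformUs) {
  stopifnot(is.finite(meanRate), meanRate >= 0)
  if (is.na(waveformUs)) {
    warning("classifyUnit: missing waveform duration; unit left unclassified")
    return("unclassified")
  }
  if (waveformUs > 250 && meanRate < 5) return("pyramidal")
  if (waveformUs < 250 && meanRate > 2) return("theta")
  "unclassified"
}

#' Discharge-metric table for a set of units
#'
#' @param trains list of [SpikeTrain-class].
#' @param sessionLength recording length, s.
#' @return data.frame: `unit_id`, `n_spikes`, `mean_rate_hz`, `burst_ratio`,
#'   `class`.
#' @export
unitMetrics <- function(trains, sessionLength) {
  rows <- lapply(trains, function(tr) {
    mr <- meanRate(tr, sessionLength)
    br <- if (length(tr@times) >= 2) {
      suppressWarnings(burstRatio(tr))
    } else {
      NA_real_
    }
    cls <- suppressWarnings(classifyUnit(mr, tr@waveformUs))
    data.frame(
      unit_id = tr@unitId, n_spikes = length(tr@times),
      mean_rate_hz = mr, burst_ratio = br, class = cls
    )
  })
  do.call(rbind, rows)
}

#' Pyramidal-unit filter
#'
#' Units admitted to the place-coding analyses: hippocampal, classified
#' pyramidal, with at least `minSpikes` spikes in the session.
#'
#' @param trains list of [SpikeTrain-class].
#' @param sessionLength recording length, s.
#' @param minSpikes minimum session spike count (default 50).
#' @return the admitted subset of `trains`.
#' @export
pyramidalUnits <- function(trains, sessionLength, minSpikes = 50) {
  keep <- vapply(trains, function(tr) {
    tr@regionTag %in% c("hippocampus", "unknown") &&
      length(tr@times) >= minSpikes &&
      suppressWarnings(
        classifyUnit(meanRate(tr, sessionLength), tr@waveformUs)
      ) == "pyramidal"
  }, logical(1))
  trains[keep]
}
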