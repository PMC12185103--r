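# End-point measures of active place avoidance: distance walked, time to
# first enter the shock zone, number of entrances, and the savings index.

# optional [t0, t1) time window applied to every endpoint
windowSeries <- function(series, window = NULL) {
  if (is.null(window)) return(series)
  stopifnot(length(window) == 2, window[2] > window[1])
  keep <- series@t >= window[1] & series@t < window[2]
  if (!any(keep)) stop("time window contains no samples")
  PositionSeries(series@t[keep], series@x[keep], series@y[keep],
                 series@theta[keep], series@arenaRadius)
}

#' Distance walked
#'
#' Sum of Euclidean room-frame steps, ignoring steps shorter than `minStep`
#' so that tracker jitter at the 3.2 mm video resolution does not accumulate
#' into spurious distance.
#'
#' @param series a [PositionSeries-class].
#' @param minStep minimum step counted, cm (default 0.32, the tracking
#'   resolution).
#' @param window optional `c(t0, t1)` window, s.
#' @return distance in metres.
#' @export
pathLength <- function(series, minStep = 0.32, window = NULL) {
  stopifnot(is(series, "PositionSeries"))
  series <- windowSeries(series, window)
  if (length(series@t) < 2) stop("pathLength: need at least 2 samples")
  step <- sqrt(diff(series@x)^2 + diff(series@y)^2)
  sum(step[step >= minStep]) / 100
}

#' Shock-zone entrances
#'
#' An entrance is a transition from outside to inside the (room-frame) zone.
#' The first entry of a session always counts; each later transition counts
#' only after the animal has been continuously outside for at least
#' `refractory` seconds, which stops boundary chatter from inflating the
#' count.
#'
#' @param series a [PositionSeries-class].
#' @param zone a room-frame [SectorSpec-class].
#' @param refractory debounce time, s (default 1.5).
#' @param window optional `c(t0, t1)` window, s.
#' @return list with `count` and `times` (timestamps of counted entrances).
#' @export
entrances <- function(series, zone, refractory = 1.5, window = NULL) {
  stopifnot(is(series, "PositionSeries"), is(zone, "SectorSpec"))
  if (zone@frame != "room") stop("entrances: zone must be in the room frame")
  series <- windowSeries(series, window)
  inside <- inSector(series@x, series@y, zone)
  times <- numeric(0)
  lastInside <- -Inf   # time of the most recent inside sample
  entered <- FALSE
  for (i in seq_along(inside)) {
    if (inside[i]) {
      outsideFor <- series@t[i] - lastInside
      if (!entered || outsideFor >= refractory) {
        if (!entered || !inside[i - 1L]) {
          times <- c(times, series@t[i])
          entered <- TRUE
        }
      }
      lastInside <- series@t[i]
    }
  }
  list(count = length(times), times = times)
}

#' Time to first enter the shock zone
#'
#' Latency from session start to the first sample inside the zone. Sessions
#' that never enter return the session length with `censored = TRUE` (the
#' convention that keeps latency averages finite).
#'
#' @inheritParams entrances
#' @return list with `latency` (s) and `censored` (logical).
#' @export
timeToFirstEntry <- function(series, zone, window = NULL) {
  stopifnot(is(series, "PositionSeries"), is(zone, "SectorSpec"))
  if (zone@frame != "room") {
    stop("timeToFirstEntry: zone must be in the room frame")
  }
  series <- windowSeries(series, window)
  inside <- inSector(series@x, series@y, zone)
  if (any(inside)) {
    list(latency = series@t[which(inside)[1]] - series@t[1], censored = FALSE)
  } else {
    list(latency = sessionLength(series), censored = TRUE)
  }
}

#' Savings index
#'
#' Percent reduction in shock-zone entrances between the first trials of the
#' two conflict-training days: 100 (entrances_c1 - entrances_c9) /
#' entrances_c1. Positive values mean improvement; the index is bounded above
#' by 100 (reached only when entrances_c9 = 0) and unbounded below.
#'
#' @param entrancesC1 entrance count, first conflict trial (> 0).
#' @param entrancesC9 entrance count, first trial of the second conflict day.
#' @return savings index, percent.
#' @export
savingsIndex <- function(entrancesC1, entrancesC9) {
  stopifnot(entrancesC1 >= 0, entrancesC9 >= 0)
  if (entrancesC1 == 0) {
    stop("savingsIndex: undefined when the first-trial entrance count is 0")
  }
  100 * (entrancesC1 - entrancesC9) / entrancesC1
}

#' All behavioural end points of one session
#'
#' @inheritParams entrances
#' @param minStep distance filter, cm.
#' @return one-row data.frame: `distance_m`, `time_to_first_entry_s`,
#'   `censored`, `n_entrances`, `session_length_s`.
#' @export
behaviorEndpoints <- function(series, zone, refractory = 1.5,
                              minStep = 0.32, window = NULL) {
  series <- windowSeries(series, window)
  tte <- timeToFirstEntry(series, zone)
  ent <- entrances(series, zone, refractory = refractory)
  data.frame(
    distance_m = pathLength(series, minStep = minStep),
    time_to_first_entry_s = tte$latency,
    censored = tte$censored,
    n_entrances = ent$count,
    session_length_s = sessionLength(series)
  )
}
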