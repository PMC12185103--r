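# Episode-level overdispersion: how much a place cell's discharge deviates
# from the firing its rate map predicts, standardized per 5 s episode as
# z = (obs - exp) / sqrt(exp). Under a pure inhomogeneous Poisson model the
# z distribution has variance 1; excess variance is extra-positional
# modulation.

binIndex <- function(v, mids, binCm) {
  idx <- round((v - mids[1]) / binCm) + 1L
  idx[idx < 1L | idx > length(mids)] <- NA_integer_
  idx
}

# small separable Gaussian blur with zero padding
gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- matrix(0, nrow(m) + 2 * r, ncol(m) + 2 * r)
  pad[r + seq_len(nrow(m)), r + seq_len(ncol(m))] <- m
  # rows then columns
  rowsm <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
  both <- t(apply(t(rowsm), 2, function(rw) stats::filter(rw, k, sides = 2)))
  out <- both[r + seq_len(nrow(m)), r + seq_len(ncol(m))]
  out[is.na(out)] <- 0
  out
}

#' Estimate a binned, smoothed firing-rate map
#'
#' Spike positions (looked up at each spike's nearest tracker sample) and
#' occupancy are histogrammed on a square grid over the arena in the chosen
#' frame, both are smoothed with the same Gaussian kernel, and their ratio
#' gives the rate. Bins whose raw occupancy falls below `minOccupancy` are
#' masked (NA), and queries on masked bins stay NA rather than 0.
#'
#' @param train a [SpikeTrain-class].
#' @param series the session [PositionSeries-class].
#' @param frame "room" or "arena".
#' @param binCm bin size, cm (default 2.5).
#' @param smoothingSigma Gaussian smoothing sigma in bins (default 1).
#' @param minOccupancy occupancy threshold, s (default 0.5).
#' @return A [BinnedRateMap-class].
#' @export
rateMap <- function(train, series, frame = c("room", "arena"), binCm = 2.5,
                    smoothingSigma = 1, minOccupancy = 0.5) {
  frame <- match.arg(frame)
  stopifnot(is(train, "SpikeTrain"), is(series, "PositionSeries"))
  dt <- 1 / samplingRate(series)
  xy <- if (frame == "room") {
    list(x = series@x, y = series@y)
  } else {
    arenaCoordinates(series)
  }
  R <- series@arenaRadius
  nb <- ceiling(2 * R / binCm)
  mids <- -R + binCm * (seq_len(nb) - 0.5)
  ix <- binIndex(xy$x, mids, binCm)
  iy <- binIndex(xy$y, mids, binCm)
  ok <- !is.na(ix) & !is.na(iy)
  if (!any(ok)) stop("rateMap: no samples fall on the grid")
  occ <- matrix(0, nb, nb)
  tab <- table(factor(ix[ok], levels = seq_len(nb)),
               factor(iy[ok], levels = seq_len(nb)))
  occ[] <- as.numeric(tab) * dt
  if (sum(occ) == 0) stop("rateMap: zero total occupancy")
  # assign each spike to its nearest tracker sample
  si <- pmin(length(series@t),
             pmax(1L, round((train@times - series@t[1]) / dt) + 1L))
  sx <- binIndex(xy$x[si], mids, binCm)
  sy <- binIndex(xy$y[si], mids, binCm)
  sok <- !is.na(sx) & !is.na(sy)
  spk <- matrix(0, nb, nb)
  stab <- table(factor(sx[sok], levels = seq_len(nb)),
                factor(sy[sok], levels = seq_len(nb)))
  spk[] <- as.numeric(stab)
  sOcc <- gaussBlur(occ, smoothingSigma)
  sSpk <- gaussBlur(spk, smoothingSigma)
  rate <- matrix(NA_real_, nb, nb)
  open <- occ >= minOccupancy & sOcc > 0
  rate[open] <- sSpk[open] / sOcc[open]
  new("BinnedRateMap",
    frame = frame, mids = mids, rate = rate, occupancy = occ,
    binCm = binCm, smoothingSigma = smoothingSigma,
    minOccupancy = minOccupancy
  )
}

#' @describeIn rateAt lookup in a binned map (NA on masked/off-grid bins)
#' @export
setMethod("rateAt", "BinnedRateMap", function(map, x, y) {
  ix <- binIndex(x, map@mids, map@binCm)
  iy <- binIndex(y, map@mids, map@binCm)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(ix) & !is.na(iy)
  out[ok] <- map@rate[cbind(ix[ok], iy[ok])]
  out
})

#' @describeIn rateAt analytic Gaussian field evaluation
#' @export
setMethod("rateAt", "GaussianRateField", function(map, x, y) {
  d2 <- (x - map@center[1])^2 + (y - map@center[2])^2
  map@baseline + (map@peak - map@baseline) * exp(-d2 / (2 * map@sigma^2))
})

# positions of the series expressed in the map's frame
seriesInFrame <- function(series, frame) {
  if (frame == "room") list(x = series@x, y = series@y)
  else arenaCoordinates(series)
}

#' Expected spike count of an episode under a rate map
#'
#' Sum over the episode's tracker samples of rate(bin(sample)) * sample
#' period: the inhomogeneous-Poisson expectation given where the animal
#' actually was. NA (episode undefined) when any sample falls on a masked
#' bin of a binned map.
#'
#' @param map a [RateSource-class].
#' @param x,y episode sample positions in the map's frame, cm.
#' @param dt sample period, s.
#' @return expected count (NA if any sample is masked).
#' @export
expectedCount <- function(map, x, y, dt) {
  r <- rateAt(map, x, y)
  if (any(is.na(r))) return(NA_real_)
  sum(r) * dt
}

#' Standardized episode deviations of observed from expected firing
#'
#' The session is cut into consecutive non-overlapping episodes (default
#' 5 s). Per episode, `obs` is the spike count, `exp` the rate-map
#' expectation along the actual path, and z = (obs - exp) / sqrt(exp).
#' Episodes are retained for the overdispersion estimate only when exp
#' exceeds the cell's mean firing per episode (selecting passes through the
#' central region of the firing field) and exp > 0; episodes touching masked
#' bins are dropped and logged in the `reason` column.
#'
#' @param train a [SpikeTrain-class].
#' @param series the session [PositionSeries-class].
#' @param map a [RateSource-class] in `frame`.
#' @param episodeLen episode length, s (default 5).
#' @return data.frame: `episode`, `t_start`, `obs`, `exp`, `z`, `retained`,
#'   `reason` ("ok", "masked", "exp_zero", "exp_below_mean").
#' @export
episodeZs <- function(train, series, map, episodeLen = 5) {
  stopifnot(is(train, "SpikeTrain"), is(series, "PositionSeries"),
            is(map, "RateSource"))
  dt <- 1 / samplingRate(series)
  perEp <- round(episodeLen / dt)
  n <- length(series@t)
  nEp <- floor(n / perEp)
  if (nEp == 0) stop("episodeZs: session shorter than one episode")
  xy <- seriesInFrame(series, map@frame)
  t0 <- series@t[1]
  meanCount <- length(train@times) / sessionLength(series) * episodeLen
  starts <- (seq_len(nEp) - 1L) * perEp + 1L
  tStart <- series@t[starts]
  obs <- as.numeric(table(factor(
    findInterval(train@times, c(tStart, tStart[nEp] + episodeLen)),
    levels = seq_len(nEp)
  )))
  # spikes before the first episode (none: episodes start at t0)
  expv <- numeric(nEp)
  for (e in seq_len(nEp)) {
    idx <- starts[e]:(starts[e] + perEp - 1L)
    expv[e] <- expectedCount(map, xy$x[idx], xy$y[idx], dt)
  }
  z <- (obs - expv) / sqrt(expv)
  reason <- rep("ok", nEp)
  reason[is.na(expv)] <- "masked"
  reason[!is.na(expv) & expv == 0] <- "exp_zero"
  reason[!is.na(expv) & expv > 0 & expv <= meanCount] <- "exp_below_mean"
  retained <- reason == "ok"
  z[!retained] <- NA_real_
  data.frame(
    episode = seq_len(nEp), t_start = tStart, obs = obs, exp = expv,
    z = z, retained = retained, reason = reason
  )
}

#' Overdispersion: variance of the episode z distribution
#'
#' @param zs numeric z values, or the data.frame from [episodeZs()] (only
#'   retained episodes are used).
#' @return list with `variance` (sample variance, denominator n - 1), `n`,
#'   and `mean`.
#' @export
overdispersionVariance <- function(zs) {
  if (is.data.frame(zs)) zs <- zs$z[zs$retained]
  zs <- zs[!is.na(zs)]
  if (length(zs) < 2) stop("overdispersionVariance: need at least 2 episodes")
  list(variance = stats::var(zs), n = length(zs), mean = mean(zs))
}

#' F-test comparing overdispersion between two conditions
#'
#' The ratio of the two z-variances is referred to an F distribution with
#' (n_a - 1, n_b - 1) degrees of freedom; the two-sided p doubles the
#' smaller tail.
#'
#' @param zsA,zsB z samples (vectors or [episodeZs()] data.frames).
#' @return list: `F`, `dfA`, `dfB`, `p`.
#' @export
varianceRatioTest <- function(zsA, zsB) {
  if (is.data.frame(zsA)) zsA <- zsA$z[zsA$retained]
  if (is.data.frame(zsB)) zsB <- zsB$z[zsB$retained]
  zsA <- zsA[!is.na(zsA)]; zsB <- zsB[!is.na(zsB)]
  stopifnot(length(zsA) >= 2, length(zsB) >= 2)
  f <- stats::var(zsA) / stats::var(zsB)
  dfA <- length(zsA) - 1L
  dfB <- length(zsB) - 1L
  p <- 2 * min(stats::pf(f, dfA, dfB), stats::pf(f, dfA, dfB,
                                                 lower.tail = FALSE))
  list(F = f, dfA = dfA, dfB = dfB, p = min(1, p))
}

#' Pick the more coherent frame for a cell
#'
#' Builds rate maps in both frames and returns the frame with the higher
#' spatial information per spike (Skaggs information of the binned map) —
#' the default frame for the overdispersion expectation when none is forced.
#'
#' @param train a [SpikeTrain-class].
#' @param series the session [PositionSeries-class].
#' @param ... passed to [rateMap()].
#' @return "room" or "arena".
#' @export
preferredFrame <- function(train, series, ...) {
  info <- function(frame) {
    m <- rateMap(train, series, frame, ...)
    ok <- !is.na(m@rate) & m@occupancy > 0
    p <- m@occupancy[ok] / sum(m@occupancy[ok])
    r <- m@rate[ok]
    rbar <- sum(p * r)
    if (rbar == 0) return(0)
    pos <- r > 0
    sum(p[pos] * r[pos] / rbar * log2(r[pos] / rbar))
  }
  if (info("room") >= info("arena")) "room" else "arena"
}
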