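# Spatial-frame-specific momentary positional information. Per 133 ms
# window, the activity level i of a cell and the animal's location x in a
# frame give Ipos = |p(i|x) log2(p(i|x)/p(i))|, computed separately for the
# room and arena frames. Their difference, averaged over the ensemble,
# yields the spatial frame ensemble preference (SFEP).

#' Discretise a spike train into activity windows
#'
#' Cuts the session into consecutive windows of length `dt` (default 133 ms),
#' counts spikes per window, and assigns each window the room- and
#' arena-frame position of its centre sample along with the spatial bin on
#' an `nGrid` x `nGrid` grid over the arena square.
#'
#' @param train a [SpikeTrain-class].
#' @param series the session [PositionSeries-class].
#' @param dt window length, s (default 0.133).
#' @param nGrid spatial grid resolution per axis (default 16).
#' @return data.frame: `window`, `t_center`, `i`, `x_room`, `y_room`,
#'   `x_arena`, `y_arena`, `roomBin`, `arenaBin` (bin ids, NA off-grid).
#' @export
discretize <- function(train, series, dt = 0.133, nGrid = 16) {
  stopifnot(is(train, "SpikeTrain"), is(series, "PositionSeries"))
  t0 <- series@t[1]
  fs <- samplingRate(series)
  span <- sessionLength(series)
  nWin <- floor(span / dt)
  if (nWin < 1) stop("discretize: session shorter than one window")
  edges <- t0 + dt * (0:nWin)
  i <- as.numeric(table(factor(
    findInterval(train@times, edges, rightmost.closed = FALSE),
    levels = seq_len(nWin)
  )))
  tc <- t0 + dt * (seq_len(nWin) - 0.5)
  ci <- pmin(length(series@t), pmax(1L, round((tc - t0) * fs) + 1L))
  xr <- series@x[ci]; yr <- series@y[ci]
  av <- roomToArena(xr, yr, series@theta[ci])
  R <- series@arenaRadius
  binCm <- 2 * R / nGrid
  binOf <- function(x, y) {
    bx <- floor((x + R) / binCm) + 1L
    by <- floor((y + R) / binCm) + 1L
    bad <- bx < 1L | bx > nGrid | by < 1L | by > nGrid
    id <- (by - 1L) * nGrid + bx
    id[bad] <- NA_integer_
    id
  }
  out <- data.frame(
    window = seq_len(nWin), t_center = tc, i = as.integer(i),
    x_room = xr, y_room = yr, x_arena = av$x, y_arena = av$y,
    roomBin = binOf(xr, yr), arenaBin = binOf(av$x, av$y)
  )
  attr(out, "nGrid") <- as.integer(nGrid)
  attr(out, "dt") <- dt
  out
}

#' Estimate the empirical activity distributions of one frame
#'
#' Builds the joint histogram of activity level against spatial bin,
#' normalises p(i|x) per visited bin and p(i) over all retained windows.
#' Activity levels above the 99th percentile of i are pooled into the top
#' level to stabilise the tails; bins with fewer than `minSamples` windows
#' are dropped from the estimate (and their windows from any information
#' series built from it), so conditionals are never formed from a handful
#' of visits.
#'
#' @param disc a [discretize()] data.frame.
#' @param frame "room" or "arena".
#' @param minSamples minimum windows per spatial bin (default 10).
#' @param capQuantile activity-cap quantile (default 0.99).
#' @return A [FrameDistributions-class].
#' @export
estimateDistributions <- function(disc, frame = c("room", "arena"),
                                  minSamples = 10, capQuantile = 0.99) {
  frame <- match.arg(frame)
  stopifnot(nrow(disc) > 0)
  bin <- if (frame == "room") disc$roomBin else disc$arenaBin
  keep <- !is.na(bin)
  if (!any(keep)) stop("estimateDistributions: no windows on the grid")
  cap <- max(1L, as.integer(ceiling(
    stats::quantile(disc$i[keep], capQuantile, names = FALSE)
  )))
  iCap <- pmin(disc$i[keep], cap)
  bins <- bin[keep]
  nGrid <- attr(disc, "nGrid")
  if (is.null(nGrid)) nGrid <- as.integer(ceiling(sqrt(max(bins))))
  nGrid2 <- nGrid^2
  counts <- table(factor(bins, levels = seq_len(nGrid2)),
                  factor(iCap, levels = 0:cap))
  counts <- matrix(as.numeric(counts), nrow = nGrid2,
                   dimnames = list(NULL, as.character(0:cap)))
  binCount <- as.integer(rowSums(counts))
  validBin <- binCount >= minSamples
  retained <- counts[validBin, , drop = FALSE]
  pMarg <- colSums(retained) / sum(retained)
  pCond <- counts / pmax(1, rowSums(counts))
  pCond[!validBin, ] <- NA_real_
  new("FrameDistributions",
    frame = frame, levels = 0:cap, pCond = pCond, pMarg = as.numeric(pMarg),
    binCount = binCount, validBin = validBin, cap = cap,
    nGrid = as.integer(round(sqrt(nGrid2))), dt = if (nrow(disc) > 1) {
      disc$t_center[2] - disc$t_center[1]
    } else NA_real_
  )
}

#' Momentary positional information of one (activity, location) observation
#'
#' Ipos = |p(i|x) log2(p(i|x) / p(i))|: large whenever the cell's activity
#' at the current location is surprising relative to its overall activity
#' distribution, zero when the conditional equals the marginal. Activity
#' levels above the estimation cap are pooled into the top level, matching
#' the distribution estimate.
#'
#' @param dist a [FrameDistributions-class].
#' @param i observed activity level (spike count in the window).
#' @param bin spatial bin id.
#' @return non-negative information value (bits scale).
#' @export
ipos <- function(dist, i, bin) {
  stopifnot(is(dist, "FrameDistributions"))
  if (is.na(bin) || bin < 1 || bin > nrow(dist@pCond) ||
      !dist@validBin[bin]) {
    stop("ipos: queried bin was not retained in the estimate")
  }
  lev <- min(i, dist@cap) + 1L
  pc <- unname(dist@pCond[bin, lev])
  pm <- unname(dist@pMarg[lev])
  if (pm == 0) stop("ipos: activity level never observed in session")
  if (pc == 0) return(0)
  abs(pc * log2(pc / pm))
}

# vectorised in-session Ipos series; NA where the window's bin is invalid
iposSeries <- function(disc, dist, frame) {
  bin <- if (frame == "room") disc$roomBin else disc$arenaBin
  lev <- pmin(disc$i, dist@cap) + 1L
  out <- rep(NA_real_, nrow(disc))
  ok <- !is.na(bin) & bin >= 1 & bin <= nrow(dist@pCond) &
    dist@validBin[pmax(1L, ifelse(is.na(bin), 1L, bin))]
  pc <- dist@pCond[cbind(bin[ok], lev[ok])]
  pm <- dist@pMarg[lev[ok]]
  v <- ifelse(pc == 0, 0, abs(pc * log2(pc / pm)))
  out[ok] <- v
  out
}

#' Per-cell delta-Ipos series
#'
#' Ipos(room) - Ipos(arena) per window, with each frame's distributions
#' estimated from the same session. Positive values mark momentary room
#' preference. Windows falling in a sparse bin of either frame are NA.
#'
#' By default a cell contributes its frame vote only in windows where it
#' emitted at least one spike (`includeZero = FALSE`): silence is shared by
#' most cells in any 133 ms window and its "information" reflects the
#' occupancy structure of the session rather than momentary signalling, so
#' including it biases the ensemble preference away from one half whenever
#' the two frames have unequal active time. Set `includeZero = TRUE` to keep
#' every window in the cell's series.
#'
#' @param train a [SpikeTrain-class].
#' @param series the session [PositionSeries-class].
#' @param dt window length, s.
#' @param nGrid spatial grid per axis.
#' @param minSamples minimum windows per bin.
#' @param includeZero include windows with zero spikes in this cell's
#'   delta-Ipos contribution (default FALSE).
#' @return data.frame: `window`, `t_center`, `i`, `I_room`, `I_arena`,
#'   `dI`.
#' @export
cellDeltaIpos <- function(train, series, dt = 0.133, nGrid = 16,
                          minSamples = 10, includeZero = FALSE) {
  disc <- discretize(train, series, dt = dt, nGrid = nGrid)
  dRoom <- estimateDistributions(disc, "room", minSamples = minSamples)
  dArena <- estimateDistributions(disc, "arena", minSamples = minSamples)
  iR <- iposSeries(disc, dRoom, "room")
  iA <- iposSeries(disc, dArena, "arena")
  dI <- iR - iA
  if (!includeZero) dI[disc$i == 0] <- NA_real_
  data.frame(
    window = disc$window, t_center = disc$t_center, i = disc$i,
    I_room = iR, I_arena = iA, dI = dI
  )
}

#' Ensemble spatial-frame preference
#'
#' Averages the per-window delta-Ipos over all cells (NA windows of a cell
#' are dropped from that window's mean; windows with no contributing cell
#' are dropped altogether). SFEP(room) is the fraction of non-tied windows
#' whose ensemble mean is positive; the series' serial structure is
#' assessed by a runs test about its mean.
#'
#' @param cellTables list of [cellDeltaIpos()] data.frames on a shared
#'   window grid.
#' @return An [EnsemblePreference-class].
#' @export
deltaIposEnsemble <- function(cellTables) {
  if (length(cellTables) == 0) stop("deltaIposEnsemble: no cells")
  nWin <- nrow(cellTables[[1]])
  for (ct in cellTables) {
    if (nrow(ct) != nWin) {
      stop("deltaIposEnsemble: cells must share the window grid")
    }
  }
  dI <- vapply(cellTables, function(ct) ct$dI, numeric(nWin))
  dI <- matrix(dI, nrow = nWin)
  m <- rowMeans(dI, na.rm = TRUE)
  have <- rowSums(!is.na(dI)) > 0
  t <- cellTables[[1]]$t_center[have]
  m <- m[have]
  ties <- sum(m == 0)
  nz <- m[m != 0]
  sfep <- if (length(nz)) mean(nz > 0) else NA_real_
  rt <- tryCatch(runsTest(m), error = function(e) {
    list(z = NA_real_, p = NA_real_)
  })
  new("EnsemblePreference",
    t = t, deltaI = m, sfepRoom = sfep, runsZ = rt$z, runsP = rt$p,
    nCells = length(cellTables), nTies = as.integer(ties)
  )
}

#' Runs test for serial non-randomness
#'
#' Dichotomises the series at `threshold` (default its mean; exact ties are
#' dropped), counts runs R, and standardises against the permutation null:
#' mu = 2 n1 n2 / (n1 + n2) + 1, sigma^2 = 2 n1 n2 (2 n1 n2 - n1 - n2) /
#' ((n1 + n2)^2 (n1 + n2 - 1)). Positive z means more alternation than
#' chance, negative z fewer, longer runs — the signature of a state dwelling
#' in one frame for many consecutive windows.
#'
#' @param x numeric series.
#' @param threshold dichotomisation level (default `mean(x)`).
#' @return list: `z`, `p` (two-sided normal), `runs`, `n1`, `n2`.
#' @export
runsTest <- function(x, threshold = mean(x)) {
  s <- x[x != threshold] > threshold
  n1 <- sum(s); n2 <- sum(!s)
  if (n1 < 2 || n2 < 2) {
    stop("runsTest: need at least 2 values on each side of the threshold")
  }
  runs <- 1L + sum(diff(s) != 0)
  nn <- n1 + n2
  mu <- 2 * n1 * n2 / nn + 1
  s2 <- 2 * n1 * n2 * (2 * n1 * n2 - nn) / (nn^2 * (nn - 1))
  z <- (runs - mu) / sqrt(s2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), runs = runs, n1 = n1, n2 = n2)
}

#' Spatial probability map of room-frame preference
#'
#' Per room-frame bin, the fraction of windows whose ensemble delta-Ipos is
#' positive (ties excluded). Bins with fewer than `minSamples` windows are
#' masked.
#'
#' @param pref an [EnsemblePreference-class].
#' @param series the session [PositionSeries-class].
#' @param nGrid grid per axis (default 16).
#' @param minSamples mask threshold (default 10).
#' @return A [PreferenceMap-class].
#' @export
preferenceMap <- function(pref, series, nGrid = 16, minSamples = 10) {
  stopifnot(is(pref, "EnsemblePreference"), is(series, "PositionSeries"))
  fs <- samplingRate(series)
  t0 <- series@t[1]
  ci <- pmin(length(series@t), pmax(1L, round((pref@t - t0) * fs) + 1L))
  R <- series@arenaRadius
  binCm <- 2 * R / nGrid
  bx <- floor((series@x[ci] + R) / binCm) + 1L
  by <- floor((series@y[ci] + R) / binCm) + 1L
  ok <- bx >= 1L & bx <= nGrid & by >= 1L & by <= nGrid & pref@deltaI != 0
  cnt <- matrix(0L, nGrid, nGrid)
  pos <- matrix(0L, nGrid, nGrid)
  tc <- table(factor(bx[ok], levels = seq_len(nGrid)),
              factor(by[ok], levels = seq_len(nGrid)))
  cnt[] <- as.integer(tc)
  okPos <- ok & pref@deltaI > 0
  tp <- table(factor(bx[okPos], levels = seq_len(nGrid)),
              factor(by[okPos], levels = seq_len(nGrid)))
  pos[] <- as.integer(tp)
  p <- matrix(NA_real_, nGrid, nGrid)
  open <- cnt >= minSamples
  p[open] <- pos[open] / cnt[open]
  mids <- -R + binCm * (seq_len(nGrid) - 0.5)
  new("PreferenceMap",
    mids = mids, pRoom = p, count = cnt, minSamples = as.integer(minSamples)
  )
}

#' Near/far summary of a preference map
#'
#' Occupancy-weighted mean P(room-preferring) over the bins of the near and
#' far sectors of a [nearFarPartition()] (bins assigned by the polar angle
#' of their centre).
#'
#' @param map a [PreferenceMap-class].
#' @param partition list with `near`, `far` [SectorSpec-class] objects.
#' @return list: `pNear`, `pFar`.
#' @export
nearFarSummary <- function(map, partition) {
  stopifnot(is(map, "PreferenceMap"))
  if (is.null(partition$far)) {
    stop("nearFarSummary: far sector is empty (coverage = 1)")
  }
  grid <- expand.grid(x = map@mids, y = map@mids)
  ang <- atan2(grid$y, grid$x) * 180 / pi
  nearBin <- matrix(
    angleInSector(ang %% 360, partition$near@center, partition$near@width),
    nrow = length(map@mids)
  )
  w <- map@count
  ok <- !is.na(map@pRoom) & w > 0
  summ <- function(sel) {
    use <- ok & sel
    if (!any(use)) stop("nearFarSummary: no unmasked bins in a sector")
    sum(map@pRoom[use] * w[use]) / sum(w[use])
  }
  list(pNear = summ(nearBin), pFar = summ(!nearBin))
}

#' Across-recording bias test of SFEP
#'
#' Convenience wrapper: one-sample t-test of per-recording SFEP(room)
#' proportions against 0.5.
#'
#' @param sfeps numeric vector of SFEP(room) values, one per recording.
#' @return the `htest` from [stats::t.test()].
#' @export
sfepBiasTest <- function(sfeps) {
  stopifnot(length(sfeps) >= 2)
  stats::t.test(sfeps, mu = 0.5)
}
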