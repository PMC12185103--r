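# Angle convention throughout: degrees, counterclockwise positive, 0 at +x.
# The arena rotation angle theta accumulates without wrapping.

deg2rad <- function(d) d * pi / 180

#' Polar angle of points, degrees in [0, 360)
#'
#' @param x,y coordinates, cm.
#' @return angles in degrees. Points at the origin have no angle and raise an
#'   error rather than silently defaulting (a silent default would corrupt
#'   sector statistics).
#' @export
polarAngle <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("polarAngle: non-finite coordinates")
  }
  if (any(x == 0 & y == 0)) {
    stop("polarAngle: angle undefined at the origin")
  }
  (atan2(y, x) * 180 / pi) %% 360
}

#' Transform room-frame points into the rotating arena frame
#'
#' The arena rotates by `theta` degrees (counterclockwise positive) relative
#' to the room, so a stationary room point appears at the room position
#' rotated by `-theta` when expressed on the arena surface. Radius is
#' preserved exactly.
#'
#' @param x,y room-frame coordinates, cm.
#' @param theta arena rotation angle(s), degrees; scalar or per-point.
#' @return list with components `x`, `y`: arena-frame coordinates.
#' @export
roomToArena <- function(x, y, theta) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(theta))) {
    stop("roomToArena: non-finite input")
  }
  a <- deg2rad(-theta)
  list(x = x * cos(a) - y * sin(a), y = x * sin(a) + y * cos(a))
}

#' Transform arena-frame points back into the room frame
#'
#' Exact inverse of [roomToArena()].
#'
#' @inheritParams roomToArena
#' @param x,y arena-frame coordinates, cm.
#' @return list with components `x`, `y`: room-frame coordinates.
#' @export
arenaToRoom <- function(x, y, theta) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(theta))) {
    stop("arenaToRoom: non-finite input")
  }
  a <- deg2rad(theta)
  list(x = x * cos(a) - y * sin(a), y = x * sin(a) + y * cos(a))
}

#' Arena-frame coordinates of a PositionSeries
#'
#' @param series a [PositionSeries-class].
#' @return list with `x`, `y`: the trajectory on the arena surface.
#' @export
arenaCoordinates <- function(series) {
  stopifnot(is(series, "PositionSeries"))
  roomToArena(series@x, series@y, series@theta)
}

#' Sector membership test
#'
#' A point is inside a sector iff its polar angle lies in
#' \[center - width/2, center + width/2) after reduction modulo 360: the
#' trailing edge is inclusive, the leading edge exclusive, so abutting
#' sectors tile the circle without double counting. Invariant to adding
#' full turns to any angle.
#'
#' @param x,y point coordinates in the sector's frame, cm.
#' @param sector a [SectorSpec-class].
#' @return logical vector.
#' @export
inSector <- function(x, y, sector) {
  stopifnot(is(sector, "SectorSpec"))
  ang <- polarAngle(x, y)
  angleInSector(ang, sector@center, sector@width)
}

# membership by angle alone; half-open [lo, lo + width)
angleInSector <- function(angle, center, width) {
  ((angle - (center - width / 2)) %% 360) < width
}

#' Occupancy fraction of an angular sector
#'
#' Fraction of samples of a room-frame trajectory whose polar angle falls in
#' the sector.
#' @param series a [PositionSeries-class].
#' @param sector a room-frame [SectorSpec-class].
#' @return fraction in \[0, 1\].
#' @export
sectorOccupancy <- function(series, sector) {
  stopifnot(is(series, "PositionSeries"))
  mean(inSector(series@x, series@y, sector))
}

#' Near/far partition of the arena around the least-visited sector
#'
#' Splits the room frame into the "near" half — the largest sector that
#' contains at least `coverage` of the recording time and surrounds the
#' least-visited `seedWidth`-degree sector — and the complementary "far"
#' half. The seed centre is found by scanning candidate centres on a 1-degree
#' grid for minimum occupancy (ties broken by the smallest angle); the near
#' sector then grows symmetrically in 1-degree steps on both edges until its
#' occupancy fraction reaches `coverage`.
#'
#' @param series a [PositionSeries-class] (room frame).
#' @param seedWidth seed sector width, degrees (default 20).
#' @param coverage occupancy fraction the near sector must reach (default 0.5).
#' @return list with `near` and `far` [SectorSpec-class] objects
#'   (`far` is NULL when the near sector spans the full circle).
#' @export
nearFarPartition <- function(series, seedWidth = 20, coverage = 0.5) {
  stopifnot(is(series, "PositionSeries"))
  if (length(series@t) == 0) stop("nearFarPartition: empty series")
  stopifnot(coverage > 0, coverage <= 1)
  ang <- polarAngle(series@x, series@y)
  # occupancy per 1-degree bin; counts[k] covers [k-1, k)
  counts <- tabulate(floor(ang) + 1L, nbins = 360L)
  n <- sum(counts)
  # candidate seed centres on the integer-degree grid
  centers <- 0:359
  seedOcc <- vapply(centers, function(c0) {
    sectorBinSum(counts, c0, seedWidth)
  }, numeric(1))
  seedCenter <- centers[which.min(seedOcc)]  # which.min takes first = smallest angle
  width <- seedWidth
  while (sectorBinSum(counts, seedCenter, width) / n < coverage &&
         width < 360) {
    width <- min(width + 2, 360)
  }
  near <- SectorSpec("room", seedCenter, width)
  far <- if (width >= 360) NULL else {
    SectorSpec("room", (seedCenter + 180) %% 360, 360 - width)
  }
  list(near = near, far = far)
}

# sum of 1-degree occupancy bins inside [center - width/2, center + width/2);
# bin k (covering [k-1, k)) is attributed by its lower edge, matching the
# half-open membership rule at integer widths/centres
sectorBinSum <- function(counts, center, width) {
  lo <- (center - width / 2) %% 360
  idx <- (floor(lo) + seq_len(ceiling(width)) - 1L) %% 360L + 1L
  sum(counts[idx])
}
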