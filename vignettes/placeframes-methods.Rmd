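---
title: "Methods: dual-frame place avoidance analysis"
author: "placeframes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-frame place avoidance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placeframes)
```

# The two-frame problem

On a slowly rotating arena (82 cm diameter, 1 rpm) with a stationary shock
sector, position is ambiguous: the animal occupies one location in the
stationary *room* frame and a different, continuously drifting location on
the *arena* surface. Every analysis in this package therefore starts from a
`PositionSeries` — room-frame coordinates sampled at 30 Hz together with the
accumulated rotation angle θ(t) — and derives arena-frame coordinates by a
rigid rotation of −θ. Angles are degrees, counterclockwise positive, 0° at
the +x axis, and θ accumulates without wrapping so the revolution count is
never lost. The rotation direction is a signed rate: nothing in the task
fixes it, so the simulator and the transform accept either sign and the
tests exercise both.

Sector membership is half-open, `[center − width/2, center + width/2)` after
reduction modulo 360, so abutting sectors tile the circle without double
counting. A point exactly at the origin has no polar angle; such queries
raise an error rather than defaulting, because a silent default would leak
corrupt samples into sector statistics.

# Behavioural end points

Three measures summarise avoidance behaviour, each windowable (the first
5 minutes are the conventional window for savings analyses):

- **Distance** — the sum of Euclidean room-frame steps, discarding steps
  shorter than `minStep` (default 0.32 cm, the video-tracking resolution),
  so stationary jitter does not accumulate into distance.
- **Entrances** — outside→inside transitions of the room-frame shock
  sector. The first entry always counts; later entries require at least
  `refractory` seconds (default 1.5 s) of continuous prior absence. The
  task software's debounce is not documented, so the value is exposed in
  the configuration; 1.5 s suppresses boundary chatter at 30 Hz while
  leaving genuine re-entries (which involve leaving and returning) intact.
- **Time to first entry** — latency of the first inside sample. Sessions
  that never enter return the session length with a censoring flag, which
  keeps latency averages finite and matches how latency ceilings behave in
  practice.

The savings index, `100 (entrances_c1 − entrances_c9)/entrances_c1`,
compares the first trials of the two conflict-training days; it is bounded
above by 100 (no entrances on the later day) and undefined when the first
count is zero, which is reported as an error, never as a value.

# Single-unit gates

Units enter the place-coding analyses only when hippocampal, classified as
pyramidal (waveform > 250 µs and rate < 5 spikes/s; theta cells are
< 250 µs and > 2 spikes/s, everything else unclassified), and active enough
to estimate distributions (≥ 50 session spikes by default). The burst ratio
divides the count of inter-spike intervals ≤ 30 ms by the count in the
closed interval [100, 130] ms; each interval is attributed once, making the
ratio symmetric in spike order and shift-invariant. An empty denominator
yields NA with a warning and such units are excluded from group means.
Burstiness is recorded but is deliberately not a classification gate — no
numeric burst threshold is defensible from first principles, and the
duration/rate gates suffice.

# Overdispersion

A place cell that signals only position is an inhomogeneous Poisson
process: over any 5 s episode the observed count `obs` should deviate from
the map-based expectation `exp` by about `√exp`. The standardized deviation
`z = (obs − exp)/√exp` therefore has variance 1 under the positional-only
model, and excess variance measures extra-positional modulation.

`exp` is accumulated sample by sample along the actual path,
`Σ rate(bin(x_t)) Δt`, from a *rate source*: either a `BinnedRateMap`
estimated from the same session (2.5 cm bins, shared Gaussian smoothing of
spike and occupancy histograms with σ = 1 bin, bins under 0.5 s occupancy
masked — standard values, all configurable) or a `GaussianRateField`, the
analytic tuning curve of a simulated cell. The analytic source exists so
that calibration tests can score simulated spikes against the exact
generative expectation; with a plug-in map, estimation error would be
confounded with the quantity under test. Episodes touching a masked bin are
dropped and logged, never imputed.

Retention follows the rule that an episode is informative only when the
animal passes through the field's central region: `exp` must exceed the
cell's mean firing. Counts and rates are not commensurable, so this is read
in count units — `exp > mean rate × 5 s` — the only dimensionally
consistent interpretation; a rate-unit variant can be recovered by scaling.
The expectation frame defaults to whichever frame gives the cell the more
coherent map (higher spatial information per spike) and can be forced to
room or arena; outputs record the frame used.

Between conditions, overdispersion is compared by the ratio of z-variances
referred to an F distribution with (n₁ − 1, n₂ − 1) degrees of freedom,
two-sided.

# Momentary positional information and SFEP

Activity is discretised into consecutive Δt = 133 ms windows; each window
carries the spike count i and the room- and arena-frame position of its
centre sample (the centre sample, not a within-window average, so a window
never straddles bins by construction). Positions are binned on a 16 × 16
grid per frame; activity levels above the session's 99th percentile pool
into a top level so conditional tails are not estimated from singletons;
bins with fewer than 10 windows are dropped from the estimate and their
windows from any information series built on it.

Per window and frame,

$$I_{pos} = \left| p(i \mid x)\, \log_2 \frac{p(i \mid x)}{p(i)} \right|,$$

with both probabilities empirical from the same session. The magnitude is
large when the observed activity at the current location is surprising
relative to the cell's overall activity distribution, zero when the
conditional equals the marginal. The per-cell frame preference is
`ΔI_pos = I_pos(room) − I_pos(arena)`; the ensemble mean of ΔI_pos per
window, the fraction of non-tied windows in which it is positive (the
SFEP), its runs-test z, and its spatial distribution (preference map, and
the occupancy-weighted near/far summary over the partition grown around the
least-visited 20° sector) are the main outputs.

**Zero-spike windows.** Whether a silent window should contribute a cell's
ΔI_pos to the ensemble mean is genuinely open. This package's default is to
let a cell vote only in windows where it fired (`includeZero = FALSE`).
The reason is a bias, not an aesthetic: in any 133 ms window most cells are
silent, and "observing silence at this location" carries nonzero I_pos in
*both* frames whenever activity is spatially structured. When the two
frames have unequal active time — precisely the situation SFEP is meant to
quantify — the dominant frame's conditionals are sharper, its
silence-information is larger, and the ensemble mean is pushed further
toward that frame than the underlying state warrants: on synthetic sessions
with a known room-state fraction of 0.7 the inclusive estimator reads
≈ 0.82 while the spike-gated estimator recovers 0.70 within ±0.02 (and
0.3/0.5 likewise). The inclusive reading remains one switch away for
sensitivity analyses.

**Runs-test convention.** The z statistic is the classical
`(R − μ_R)/σ_R` about the dichotomisation threshold (the series mean; exact
ties dropped): a strictly alternating 10 + 10 series gives z = +4.135, and
frame dwelling — many consecutive windows on one side — gives large
*negative* z. Significance of the representational alternation is therefore
a matter of |z|; summaries report the signed value and the two-sided p.

# The synthetic generator

The generator exists to give every analysis a ground truth; it is an
explicit statistical stand-in, not a biophysical model, and the session
manifest labels it as such.

- **Trajectory** — exact-discretisation Ornstein–Uhlenbeck velocity
  (relaxation `ouTau` = 1 s, per-axis stationary scale `ouSigma` = 8 cm/s,
  giving realistic rat foraging speeds of ~10 cm/s) with specular
  reflection at the wall. Avoidance is a tangential repulsion from the
  configured room sector fading over 45° beyond its edge; gain 1.5 depresses
  zone occupancy to a few percent, similar to a trained animal.
- **Tuning** — Gaussian place fields anchored to one frame
  (`rate = baseline + (peak − baseline) e^{−d²/2σ²}`, d in the cell's own
  frame). "Strong tuning" in the calibration studies means 30 Hz peaks over
  a 0.05 Hz baseline with σ = 10 cm.
- **Latent state** — in `dwell` mode the room/arena state strictly
  alternates with exponential dwell durations whose means are
  `2p·meanDwell` and `2(1−p)·meanDwell`, so the overall mean dwell is
  `meanDwell` and the room-time fraction is exactly `p`; in `proximity`
  mode renewals on an exponential clock draw room with probability
  `pRoomNear` within 90° of the zone centre and `pRoomFar` beyond. A cell
  whose frame disagrees with the current state is suppressed to baseline
  (not silenced), keeping its activity marginal estimable in both frames.
- **Gain** — a multiplier held constant over 5 s segments (the episode
  length) and redrawn per segment; gains {1} recover an exact
  inhomogeneous-Poisson cell, gains {0.5, 1.5} give the reference
  overdispersion condition.
- **Spiking** — Poisson counts per 1/30 s bin with spike times jittered
  uniformly within the bin, so the generator is an exact Poisson oracle at
  the analysis resolution.
- **Seeds** — one master seed spawns fixed substreams for trajectory,
  state, gain, and each cell, so any component can be regenerated alone and
  whole sessions are bit-reproducible.

What the generator does *not* emulate: theta rhythm and phase coding,
burst structure within fields, shock-triggered escape kinematics, head
direction, or any interaction between behaviour and the neural state. Tests
passing on this generator demonstrate that the estimators recover the
statistical structure they target — not that real recordings contain that
structure.

# Study conditions used by the verification suite

The deterministic sizes were chosen once, as the smallest sessions at which
the targeted effects are comfortably identifiable: overdispersion
calibration uses a 3600 s session and 40 cells (~8500 retained episodes, so
var(z) is estimated to about ±0.03); gain sensitivity uses 1200 s and 20
cells per spread; SFEP fraction recovery uses 2000 s with 10 room and 10
arena cells and 2 s mean dwells (~1000 dwells per session, so the realized
room fraction sits within ~0.02 of nominal); the proximity-gradient study
uses 2000 s, avoidance gain 1.5 and 1.5 s dwells; null-size checks (F-test,
runs test, FDR) use 1000 replicates.

# CO covariance network

Optical densities are averaged over 3–6 replicate readings and both
hemispheres per subject and region, optionally normalised by the slope of a
per-batch standards curve (OD against 20/40/60/80 µm homogenate thickness —
a common rescaling that leaves every Pearson correlation invariant, which
is why the normalisation detail is pluggable). Pearson r and two-sided p
(exact t transform) are computed for all C(14, 2) = 91 pairs of the
canonical region panel per group, with pairwise-complete subjects and a
minimum of four. Two significance tiers are reported rather than choosing
one: uncorrected p < 0.05, and Benjamini–Hochberg FDR at q = 0.01 within
each group's 91 tests; the FDR tier is nested inside the first. Group
differences per edge use the Fisher-z statistic
`(atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))`, and proportions of
significant edges are compared with the standard pooled two-proportion z.
The pooled formula is documented because printed values elsewhere computed
with unknown variants do not constrain it; this implementation states its
formula and stands by it. Graphs are exported with all regions as nodes and
the p < 0.05 edges carrying r, p and tier attributes.

# Numerical choices and degenerate inputs

- Modular angle arithmetic is used everywhere; membership half-open; the
  least-visited seed sector is scanned on a 1° occupancy histogram with
  ties broken toward the smallest angle, and the near sector grows in
  symmetric 1° steps per edge until coverage is met — the least-committal
  reading of "surrounds".
- Exact ΔI ties are excluded from SFEP proportions and runs tests: they are
  measure-zero on real data but routine in degenerate tests.
- Empty spike trains are legal everywhere metrics permit (rate 0), error
  where a ratio would be undefined (burst ratio with < 2 spikes).
- Episodes with `exp = 0` are undefined and excluded, with the exclusion
  reason logged per episode.
- All CSV output is comma-separated, '.'-decimal, UTF-8, LF; result
  directories carry the configuration hash and seed registry, and reruns
  with identical configuration and seed are byte-identical.

# Known limitations

The generator's latent state is shared by all cells; real ensembles
fragment. Plug-in rate maps share data between the expectation and the
scored episodes, which deflates overdispersion slightly relative to a
cross-validated map (an optional split is the obvious extension). The
near/far partition is defined on occupancy alone, so in sessions without
avoidance the "near" label is arbitrary. The burst-ratio denominator window
and the classification thresholds are field conventions, not fitted
quantities, and should not be tuned per dataset.
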