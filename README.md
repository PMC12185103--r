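# placeframes

Analysis of rodent behaviour and hippocampal single-unit recordings from the
two-frame active place avoidance task, and a synthetic-session generator that
gives every stage of the analysis a known ground truth.

In this task a rat forages on an 82 cm disk arena rotating at 1 rpm while a
stationary 60° sector of the *room* delivers a mild shock. Because the arena
surface rotates under the animal, positions are defined in two dissociated
spatial frames — the stationary room frame and the rotating arena frame — and
hippocampal place-cell ensembles alternate between representing locations in
each. `placeframes` implements the full analysis chain for such sessions:

- **Frame geometry** — exact transforms between room and arena coordinates,
  angular-sector membership, and the occupancy-based near/far partition of
  the arena around the least-visited 20° sector.
- **Behavioural end points** — distance walked, number of shock-zone
  entrances (debounced), time to first entry (censored at session length),
  and the savings index
  `100 · (entrances_c1 − entrances_c9) / entrances_c1`.
- **Single-unit metrics** — mean rate, burst ratio (ISIs ≤ 30 ms over ISIs
  in 100–130 ms), and the pyramidal/theta classification gates
  (waveform > 250 µs & rate < 5 /s vs waveform < 250 µs & rate > 2 /s).
- **Overdispersion** — the session is cut into 5 s episodes; per episode
  `z = (obs − exp) / √exp` with `exp` the inhomogeneous-Poisson expectation
  along the actual path under the cell's rate map; the variance of the z
  distribution measures extra-positional modulation and is compared between
  conditions with an F-test.
- **Momentary positional information and SFEP** — per 133 ms window,
  `I_pos = |p(i|x) · log₂(p(i|x) / p(i))|` computed separately in each frame;
  `ΔI_pos = I_pos(room) − I_pos(arena)` averaged over the ensemble gives the
  spatial frame ensemble preference (SFEP), its serial structure is assessed
  by a runs test, and its spatial distribution by a preference map with a
  near/far summary.
- **CO covariance network** — replicate averaging and standards
  normalisation of cytochrome-oxidase optical densities over a canonical
  14-region panel, Pearson correlations over all 91 region pairs,
  Benjamini–Hochberg FDR tiers, Fisher-z group comparison, and graph export.
- **Synthetic sessions** — Ornstein–Uhlenbeck foraging with wall reflection
  and sector avoidance, frame-locked Gaussian place fields, a latent
  room/arena state switching on a seconds timescale (optionally dependent on
  shock-zone proximity), and per-pass gain modulation that produces
  overdispersion with a known magnitude.

## Worked example

Simulate a 10-minute avoidance session with a proximity-dependent frame
state and analyse it end to end:

```r
library(placeframes)

zone   <- SectorSpec("room", 120, 60)                    # shock zone
cfg    <- SimConfig(duration = 600, seed = 1,
                    avoidanceGain = 1.5, avoidanceZone = zone)
series <- simulateTrajectory(cfg)
behaviorEndpoints(series, zone)
#>   distance_m time_to_first_entry_s censored n_entrances session_length_s
#> 1   40.21165              22.73333    FALSE          13              600
```

The animal walked 40 m, first entered the avoided sector after 23 s and
entered 13 times. Add an ensemble of 8 room-frame and 8 arena-frame place
cells whose latent frame state prefers the room near the shock zone
(P(room) = 0.9) and the arena far from it (0.1):

```r
state  <- latentState(series, StateProcess("proximity", meanDwell = 1.5,
                      pRoomNear = 0.9, pRoomFar = 0.1, zone = zone), seed = 1)
cells  <- c(lapply(1:8, function(j) CellSpec("room",
              18 * c(cos(2*pi*j/8), sin(2*pi*j/8)), sigma = 10, peak = 30)),
            lapply(1:8, function(j) CellSpec("arena",
              18 * c(cos(2*pi*(j+.5)/8), sin(2*pi*(j+.5)/8)), sigma = 10, peak = 30)))
trains <- simulateEnsemble(series, cells, state, GainProcess(1), seed = 1)

ens <- deltaIposEnsemble(lapply(trains, cellDeltaIpos, series = series))
ens
#> EnsemblePreference: 3432 windows, 16 cells; SFEP(room) = 0.389; runs z = -25.05 (p = 1.64e-138)

nf <- nearFarSummary(preferenceMap(ens, series), nearFarPartition(series))
sprintf("P(room-preferring): near half %.2f, far half %.2f", nf$pNear, nf$pFar)
#> "P(room-preferring): near half 0.49, far half 0.28"
```

The ensemble is arena-preferring overall (SFEP(room) = 0.39, as expected
when the animal spends most time far from the zone), its ΔI_pos series has
far fewer runs than chance (z = −25, the signature of dwelling in one frame
for many consecutive windows), and room preference concentrates in the half
of the arena near the shock zone (0.49 vs 0.28).

Overdispersion detects per-pass gain modulation against the
inhomogeneous-Poisson floor:

```r
quiet <- simulateTrajectory(SimConfig(duration = 1200, seed = 2))
cell  <- CellSpec("room", c(15, 0), sigma = 10, peak = 8, baseline = 0.5)
for (g in list(GainProcess(1), GainProcess(c(0.5, 1.5)))) {
  spk <- simulateEnsemble(quiet, list(cell), NULL, g, seed = 2)[[1]]
  ov  <- overdispersionVariance(episodeZs(spk, quiet, trueRateField(cell)))
  cat(sprintf("gains {%s}: var(z) = %.2f over %d retained episodes\n",
              paste(g@gains, collapse = ", "), ov$variance, ov$n))
}
#> gains {1}: var(z) = 0.90 over 83 retained episodes
#> gains {0.5, 1.5}: var(z) = 3.51 over 89 retained episodes
```

A purely positional Poisson cell sits at variance ≈ 1; doubling-and-halving
the gain per 5 s pass inflates it several-fold.

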