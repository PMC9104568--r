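---
title: "Monitoring hot and cold spots in aerated static-pile biostabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring hot and cold spots in aerated static-pile biostabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilespot)
```

## The monitoring problem

Aerobic biostabilization of the organic fraction of municipal solid waste is
run in static piles tens of metres long, aerated from below through three
channels. The process is judged healthy when the waste passes through a
thermophilic phase (~60–70 °C) under aerobic conditions; it fails *locally*:
overheated oxygen-starved pockets ("hot spots", where anaerobic and
thermochemical chemistry takes over and CO rises) and cool well-aerated
pockets ("cold spots", where the waste is never sanitized). A weekly lance
campaign measures temperature, O₂, CO₂ and CO at four cross-sections
(2.5, 17.5, 32.5, 47.5 m from the fan), at three heights on both sides plus
one deep centre point — seven probes per section, 28 per pile per cycle.

`pilespot` models that campaign end to end: grid geometry, field
reconstruction between probes, threshold classification, and campaign-level
inventories, plus a synthetic generator so that every stage can be validated
against known ground truth.

## Probe-grid geometry

A pile is an isosceles-trapezoid prism (base = pile width, top defaulting to
0.25 × base — the apex width of a membrane-covered pile is not standardized,
and no downstream result is sensitive to it). Sidewall piles have vertical
concrete walls up to `wall_height_m`; the wall height is only constrained by
the probing protocol (the lowest probe H1 is blocked by the wall, the middle
probe H2 is not), so the default is 1.0 m, between the two.

Probes are horizontal lances inserted at least 1.25 m deep, with the probe
tip `insertion_depth_m` along the probe axis from its entry point on the
surface. On sidewall piles the H1 measurement is made at 45° over the wall;
the entry height is chosen so the tip lands exactly at H1, offset
`insertion_depth_m/√2 ≈ 0.884 m` inward and downward from the entry point.
Deep measurements sit on the centreline at mid height. Every generated
location is verified to lie strictly inside the section outline; a probe
that would exit the pile is a hard error naming the location.

Zone labels (`center`, `top`, `bottom`, `left`, `right`, `near-sidewall`)
drive the localization phrases of spot reports. On sidewall piles the
`near-sidewall` tag is attached both to probes within `margin_m` (default
0.5 m) of the wall plane and to the 45° H1 probes themselves: those probes
exist precisely to sample the wall-foot region, even though the tip of a
1.25 m lance ends up ~2 m inboard.

## Field reconstruction

Cross-section fields use **natural-neighbor (Sibson) interpolation**: the
value at a query point is the convex combination of site values weighted by
the Voronoi-cell area the inserted query steals from each site. The package
computes the weights exactly, by half-plane clipping of the inserted cell
(compiled code), rather than by raster approximation — exactness at sites,
non-negativity and partition of unity then hold to machine precision and are
asserted against an independent pure-R "stolen area" oracle in the tests.
Queries outside the sites' convex hull have no Sibson coordinates; the
ambient boundary ring (below) includes the outline vertices, so the hull
covers the whole section and masked queries are always interior. If a
degenerate configuration still produces an exterior query, the nearest-site
value is used and the event reported.

Longitudinal sections use **RBF interpolation** with a multiquadric kernel
`φ(r) = √(r² + ε²)` plus a linear polynomial tail, so constant and affine
fields are reproduced exactly. The shape parameter ε defaults to the mean
nearest-neighbour spacing of the sites — a standard heuristic; the original
commercial gridding tool does not publish its parameterization, so ε, the
kernel and the boundary-point count are configuration, not claims. Duplicate
sites make the saddle system singular and raise an error (for the Sibson
route a repeated site with an identical value is merely redundant and is
deduplicated — a documented asymmetry). An ill-conditioned system
(κ > 10¹²) falls back to a small ridge with a warning.

**Boundary conditions.** The pile exchanges with atmospheric air on its
outline and with blower air at the three channel positions on the base:
24 evenly spaced outline points (plus the outline vertices) carry ambient
values — 20.9 % O₂, 0.04 % CO₂, 0 ppm CO and the day's outside temperature —
and the channel positions carry channel measurements when available,
otherwise the same ambient values. Ring points colliding with a channel
position yield to the channel value.

Grids default to 0.1 m cells (cross-sections ≈ 81 × 25 nodes, longitudinal
≈ 500 × 26), chosen as desk scale: fine enough that 0.5 m anomalies span many
nodes, coarse enough that a full pile-day (4 cross + 2 longitudinal sections,
4 variables) reconstructs in seconds. Reconstructed gas fields are clamped to
physical bounds post hoc (RBF can overshoot); clamp counts are recorded on
the grid object. Cycles are reconstructed independently — no temporal
interpolation across the weekly spacing.

## Spot criteria and counting

A probe reading is a hot spot iff `T > 60 °C` and `O₂ < 15 %` and
`CO₂ > 5 %` simultaneously, a cold spot iff `T < 30 °C` and `O₂ > 15 %` and
`CO₂ < 5 %`. The inequalities are strict — a reading exactly at a threshold
is not a spot — with a non-strict mode available. CO is deliberately not a
criterion; it is generated, reconstructed and reported for interpretation.

The counting unit is the **(pile, day, distance) occurrence**: several
triggering probes in one cross-section are one spot record (their zone labels
union), and the same distance may carry both a hot and a cold record on one
day through different probes. This is the unit under which the published
campaign totals are consistent, and the packaged inventory fixture reproduces
them (hot 6/3/8/1/3 for A1/A2/B2/C1/C2; cold 5/11/2/5/8/12 for
A1/A2/B1/B2/C1/C2). Records missing any of the three criterion variables are
rejected before classification (a missing CO value alone is not a rejection);
rejection is per record, since the finer-grained practice behind "incomplete
data were rejected" is not documented.

Cold-spot **exclusion windows** are data, not hard-code: the default
configuration excludes cold records for piles A1 and A2 during days 1–16,
the extended startup lag during which those whole piles — not localized
pockets — were still cold.

`field_spot_regions()` generalizes the point criteria to reconstructed
fields: per-node classification, 8-connected component labelling (own
compiled labelling; `EBImage::bwlabel` is the cross-check in the tests), and
a minimum region area (default 0.05 m², half a cell short of a 0.5 m-radius
disc's core) to suppress single-node speckle.

## The synthetic campaign generator

The generator emulates the qualitative dynamics the analysis assumes, not a
calibrated mechanistic model:

* **Temperature**: ambient during a lag phase (0 d for high-mass "B-type"
  piles, 14 d for small-mass highly aerated "A-type" piles), then a
  logistic-family rise `ambient + (plateau − ambient)·tanh(rate·(t − lag)/2)`
  — the member of the logistic family that is *exactly* ambient at the lag
  boundary — followed by exponential relaxation toward ambient after
  `cooling_start_day`. A basal term `strength·exp(−z/depth_scale)` cools the
  base above the aeration channels (defaults 10 °C at ground, 0.5 m scale).
* **Gases**: O₂ drawn down linearly with temperature excess
  (0.18 %/°C default) and clamped to [0, 20.9]; CO₂ mirroring the depletion
  (`CO₂ = 0.8·(20.9 − O₂)`, so `O₂ + CO₂/0.8 = 20.9` identically — the
  inverse coupling observed in aerobic treatment); CO exponential in
  temperature, anchored at 1800 ppm at 75 °C (the reported extreme) with
  rate 0.1 /°C. The drawdown and mirror coefficients are free parameters —
  the real coupling strength is not quantified — chosen so that a 65 °C
  thermophilic core crosses the hot thresholds while a 45 °C mid-range pile
  does not.
* **Anomalies**: Gaussian-kernel injections (`exp(−d²/2r²)`, 3-D distance)
  with per-variable deltas over a day range. The helper
  `inject_at_probes()` centres injections on probe tips and sizes deltas to
  clear each threshold by a margin (default 2 units ≥ 2 instrument
  resolutions). The default radius is 0.5 m — local to a single probe;
  neighbouring probes receive only negligible partial deltas, which keeps
  injected ground truth and threshold recovery aligned probe-for-probe.
* **Measurement model**: independent Gaussian noise per variable (the
  instruments publish precision, not an error model), truncation to physical
  bounds, then quantization to instrument resolution (1 °C, 0.1 % gas
  volumes, 1 ppm CO).

Ground truth is the spot inventory implied by the criteria on the
*noise-free, quantized* signal at probe locations — invariant to any
interpolation settings. One refinement: on days when the pile-median
noise-free temperature is itself below the cold threshold, cold records are
excluded from the truth (and symmetric startup windows are applied in
recovery), because a uniformly cold startup pile is not a localized anomaly —
the same reasoning under which the published campaign excluded its first
weeks. This is toggleable (`exclude_cold_startup = FALSE`).

What the generator does **not** emulate: heat and mass transport between
probes (no PDE), waste heterogeneity and anisotropic airflow, drifting
ambient conditions, correlated sensor error, or probe placement error.
Passing recovery tests therefore demonstrates the pipeline's correctness and
its noise behaviour at the probe grid, not field performance on real waste.

## Validation design and problem sizes

The test suite checks each interpolant against an independently coded
brute-force oracle (Voronoi stolen-area computation for Sibson weights; a
dense QR saddle-system solve for RBF) on 100+ random 5–12-site
configurations, property-style invariants (partition of unity to 1e-9,
min–max boundedness, affine reproduction to 1e-7, site residuals below 1e-8
relative), and end-to-end recovery: noise-free scenarios with 1/3/5 injected
hot and cold anomalies recover with precision = recall = 1, and mean recall
over 50 seeds per level is non-increasing across temperature noise SDs of
0/2/5/10 °C (12 injected spots per scenario, 600 spot trials per level — the
scale at which the expected recall gaps dominate Monte-Carlo error).
`scripts/acceptance.R` recomputes the same quantities from scratch under a
caller-supplied seed.

## Known limitations

* The sidewall outline (wall height, membrane apex) and probe entry points
  are conventions where the construction drawings give none; absolute probe
  coordinates carry decimetre-scale conventional uncertainty, though section
  topology and all counting results are unaffected.
* Sibson weights are computed in O(n²) per query after clipping; fine for
  the ~35-site sections this package targets, not for thousands of sites.
* The published inventory fixture is transcribed at (pile, day, distance)
  granularity with the tables' localization phrases; the underlying raw
  probe readings are not redistributable here, so reconstructed fields of
  the real campaign are out of scope.
* Spot counts are reported as-is; no inferential statistics are attached to
  differences between aeration regimes.
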