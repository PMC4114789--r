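---
title: "Methods: quantifying individual movement responses to a linear barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying individual movement responses to a linear barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadresponse)
```

This vignette is the package's own account of its models and the design
choices behind them: what is estimated, under which assumptions, which
defaults matter, and what the validation experiments do and do not show.

## The inference problem

Telemetry of territorial carnivores near roads comes in *tracking
sessions*: a night of intensive radio-tracking yields a short series of
fixes at roughly half-hour intervals, and an animal contributes a handful
to a few dozen such sessions. Nothing about this design supports
population-level road-effect models; each animal must be its own control.
The package therefore frames every question as *observed vs simulated
self*: the animal's space use, turning behavior and road crossings are
compared either against a nested statistical null (for response angles)
or against replicates of a simulation that copies the animal's own
movement capacity but is blind to the road (for space use and crossings).

All geometry is planar, in projected meters; one coordinate system for
fixes, highway, passages and rasters. Angles are radians,
counter-clockwise from +x, wrapped to (−π, π]. The highway is a single
polyline; "side" is the sign of the cross product against the local
segment direction, with points exactly on the line assigned side 0 (a
divided carriageway with a median is not modelled as two lines).

## Steps and the gap rule

A step joins consecutive fixes of the same session. Pairs more than
`max_gap = 90` minutes apart yield no step: the tracking protocol loses
contact occasionally, and a chord across a 2-hour hole is not a movement
path. The default is roughly twice the typical 39-minute inter-fix
interval, so ordinary one-miss gaps still form steps while overnight
losses do not. Zero-displacement steps keep length 0 and inherit the
previous step's heading (their own is undefined); if there is none they
are dropped from angle analyses. Fixes flagged inactive (resting animals)
are retained for space-use estimation but excluded from response-angle
fitting — a resting animal expresses no directional choice.

## Utilization distributions by biased random bridges

Between two fixes the animal's true path is unknown; the biased random
bridge treats it as a constrained random walk pinned at both ends.
Operationally, each retained step (duration `T` ≤ `T_max`) is discretized
into interpolated points at spacing `tau` along the straight chord, at
relative times `p` (midpoint rule), each carrying weight `T/n` so a
step's points jointly weigh its share of total tracked time. Each point
is smoothed by a bivariate Gaussian kernel with bandwidth

    h²(p) = h_min² + 4 p (1 − p) (h_max² − h_min²),   h_max² = h_min² + D·T/2

so uncertainty collapses to `h_min` at the observed fixes and is maximal
mid-step. `D` is the planar diffusion coefficient (m²/min) in the
standard convention: per-coordinate displacement variance `2·D·dt`, which
makes the mid-step bridge variance per coordinate exactly `D·T/2` and
pins the formula above. `estimate_diffusion()` obtains `D` by the
closed-form MLE of the Brownian-bridge prediction of every odd-indexed
fix from its two neighbors (per-coordinate variance `2·D·T·p(1−p)`); a
grid-search over the same likelihood is kept as a test oracle.

Defaults, with reasoning:

* `tau = 5` min — fine enough that halving it moves no cell by more than
  1% at the study's step durations (a convergence property under test);
* `h_min = 30` m — one land-cover cell; fix precision below this scale is
  not informative;
* `T_max = 90` min — equal to the step gap rule;
* `L_min = 5` m — steps shorter than this are treated as stationary: a
  kernel pile at the mean location, avoiding zero-length chord artifacts;
* `D` — estimated per animal unless configured.

The UD raster stores per-cell probability mass summing to 1 (±1e−6,
asserted everywhere). The home range is the 95% isopleth: cells taken in
descending mass order until 95% is enclosed (ties broken by column-major
scan order), then the cell union's outer boundary traced into polygon
rings. Containment uses the even-odd rule, boundary counts as inside, so
multi-part ranges and holes need no special casing.

## The response-angle model

For each step starting at distance `T` from the highway, the response
angle is `A = wrap(B − C)`: heading minus highway bearing, both measured
at the step's start — the response is decided before moving, so `T` is
the start distance. The direction convention (B − C rather than C − B)
is one of two readable interpretations of "difference"; the von Mises
density is symmetric and results are reported as `|μ|` on [0, π], so the
choice is consequence-free and is fixed here once.

The *no-response* model says `A ~ vonMises(μ, κ)` with constant
concentration; its MLE is closed-form (`atan2` resultant for μ, Bessel
ratio inversion for κ, capped at 10⁴ for degenerate samples). The
*responsive* model lets concentration decay exponentially with distance,
`κ(T) = θ₁·exp(−θ₂·T)`: `θ₁` is the concentration at the road itself,
`θ₂` (per m) the decay rate, and far from the road movement becomes
uniform with respect to the highway bearing. Fitting is by L-BFGS-B with
an analytic gradient over (μ, θ₁ ≥ 0, θ₂ ≥ 0), from 8 grid starts
(μ ∈ {0, ±π/2, π} × θ₁ ∈ {0.5, 5}, θ₂ started at 1/median(T)) because
the likelihood is multimodal in μ; the no-response MLE with θ₂ = 0 is
always included as a start, which enforces the nesting inequality
loglik₁ ≥ loglik₀ by construction rather than by hope.

The models are compared by `2·(loglik₁ − loglik₀)` against χ²(1)
(clamped at 0), and significant responsive fits are classified by `|μ|`:
below π/4 attraction, above 3π/4 avoidance, otherwise parallel movement.
The thresholds are package conventions — the source behaviors are
described qualitatively in the field — chosen as the symmetric quartering
of [0, π].

**A known property of this test.** Under the no-response null, θ₂ = 0
lies on the boundary of its parameter space, so the LR statistic follows
the mixture ½χ²₀ + ½χ²₁ rather than χ²(1). The conventional df = 1
p-value used here (and in the literature this model comes from) is
therefore *conservative*: simulation at n = 300, κ = 1.5 gives a
rejection rate near 3% at nominal α = 5% (measured 0.027–0.035 across
3 × 1000 null datasets). Significant results are thus trustworthy; the
test simply has less power than its nominal level suggests. We keep the
df = 1 convention deliberately, for comparability with published fits.

## Crossings and UD_cross

A crossing is a consecutive same-session fix pair on strictly opposite
sides; a fix exactly on the line is no side change. The crossing location
is the chord's intersection with the polyline (nearest to the start fix
if the chord cuts a curved road several times); pairs whose side signs
flip without a polyline intersection (possible at the ends of a finite
mapped section) fall back to the chord midpoint's nearest chainage. No
distance cap is applied to the endpoints — a crossing is a crossing —
but the 200 m band applied to `UD_cross` keeps the location inference
local to the road.

`UD_cross` runs the same BRB machinery on the crossing pairs only (each
pair as a two-point track), masks the surface to cells within 200 m of
the highway, renormalizes, and projects onto the road: the polyline is
sampled at half-cell spacing, each sample reads its cell's mass, samples
are averaged within 250 m chainage bins, and bins are normalized to sum
to 1. Bin width is configurable; 250 m gives ~40 bins over a 10 km
section, matching the scale at which passages are spaced.

## The barrier-naïve null model

The null animal knows its home range and its own gait, and nothing else.
Per replicate, each observed session is replayed: start at a resting site
chosen uniformly (resting sites are each session's first fix plus any
inactive fixes — the only systematically observed resting locations),
then take exactly the observed step lengths, in their observed order,
each in a direction drawn uniformly on (−π, π] and redrawn until the
endpoint lies inside the home-range polygon. Lengths are never resampled;
direction-only redrawing is the right reading of a null that preserves
the step-length *sequence*. Directions are independent draws — no
persistence — because directional persistence is part of what the null
deliberately destroys.

If no admissible direction appears within `max_direction_draws` (1000),
the step is truncated at the polygon boundary along the last drawn
direction and the event is counted; this preserves step count and
containment. The fallback fires only for degenerate geometry (steps
longer than the polygon, as in the unit tests); across realistic ranges
it is absent. Each replicate runs on an RNG stream derived from
(seed, replicate index), so any single replicate is reproducible without
regenerating the rest.

## Percentile envelopes

Observed statistics are classified against the replicates' empirical 5th
and 95th percentiles (`quantile` type 7, linear interpolation — fixed so
small replicate sets are reproducible across implementations): below,
within, or above. This is done for the scalar crossing count, per UD
cell within the home-range mask, and per chainage bin of the crossing
profile. No multiplicity correction is applied across cells or bins —
the framework flags cells marginally, as exploratory maps of where space
use departs from the null, and any global claim should rest on the
scalar statistics. With 200 replicates the band endpoints carry visible
Monte-Carlo noise; 1000 (the default `null_config()`) is the full-
fidelity setting.

The calibration experiment in the acceptance suite checks the nominal
two-tail rate (10%) by exchangeability: a pool of 401 null replicates is
generated once, and each of 200 trials holds one replicate out as the
"observed" dataset against an envelope of 200 drawn from the rest.
Because observed and envelope members come from the same generator, the
marginal flag probability is exactly the two-tail rate; trials share
pool members and are therefore weakly dependent, which the test's ±3–4
point bands absorb. This design keeps the experiment three orders of
magnitude cheaper than regenerating independent pools per trial, at no
cost in the expectation being tested.

## Habitat screen

Before attributing movement structure to the road, a two-class weighted
compositional analysis asks whether space use tracks land cover (forest
vs agricultural): per animal, `d = ln(used_f/used_a) − ln(avail_f/avail_a)`
with zero proportions replaced by 0.01 (the standard compositional fix),
availability defined by the UD mass over each class and use by fix
counts. Wilks' Λ for the weighted one-sample test of mean d = 0 reduces,
with one log-ratio, to `Σw(d − d̄_w)² / Σw d²`; animals are weighted by
fix count because tracking effort varies several-fold between
individuals. Significance comes from sign randomization (d is symmetric
about 0 under no selection); with ≤10 animals all 2ⁿ sign patterns are
enumerated and the p-value is exact. The calibration experiment draws
used proportions from Dirichlet noise around availability and recovers
the nominal rejection rate.

## The synthetic-telemetry generator

No public dataset pairs session-structured carnivore telemetry with a
mapped highway, so the package carries its own generator with recorded
ground truth. Its defaults are the study regime the methods were designed
for: 5–28 nightly sessions, ~10 ± 5 fixes per session at ~39 ± 22 min
(5-min floor), log-normal step lengths (median ~100 m, sdlog 0.7), and
home ranges whose 95% isopleths land near 2–3 km². Sessions start at one
of `n_rest = 6` resting sites scattered (sd 600 m) around the home
center, start fixes are flagged inactive, and each step's heading is the
composition of a home-attraction draw (von Mises toward the home center,
κ_home = 0.5) with — within 1000 m of the road — a highway-response draw:
a response angle from vonMises(μ_true, θ₁·exp(−θ₂·T)) applied around the
highway bearing, so generated angles follow exactly the model the fitting
stage estimates. The two draws are composed as the direction of the sum
of their unit vectors (a documented harness convention; the home pull
dilutes the response signal, making recovery experiments conservative).
κ_home, the rest-site spread and the step law were calibrated once,
against the 2–3 km² range-size target, before any recovery experiment
was run, and have not been revisited.

Crossing policies resolve steps whose chord crosses the highway:
`non_crosser` reflects the endpoint across the local road tangent;
`naive` crosses in place with a configurable probability (else reflects);
`passage_faithful` detours the step through the nearest allowed passage
within a chainage tolerance (default 1500 m), so the chord crosses
exactly at the passage — the behavior of a resident that knows its
culvert.

What the generator does *not* emulate: triangulation error, habitat-
dependent movement (land cover is generated but does not steer the
agent), traffic avoidance by time of day, directional persistence within
sessions, and demography. Recovery results therefore validate the
estimators under the model's own assumptions plus realistic session
structure — they do not prove robustness to, e.g., autocorrelated
headings or location error, which real telemetry has.

## Validation problem sizes

The acceptance experiments use: 200 datasets of n = 300 angles for
parameter recovery (median |μ̂ − μ| < 0.1 rad, median relative θ₁ error
< 30%); 1000 null datasets for LR calibration; a 401-replicate pool with
200 holdout trials for envelope calibration; 50 seeds per behavior class
for end-to-end discrimination (avoiders recovered as avoidance with
significant LR, passage-faithful crossers' profile mode in the true
passage's 250 m bin, indifferent agents left unclassified — each in
≥80% of seeds); and 500 trials for the compositional calibration. The
demo pipeline (three animals, 200 replicates) is the same configuration
`scripts/acceptance.R` runs.

## Known limitations

* The highway is one polyline: no median strip, no network of roads, no
  lane-level geometry.
* BRB settings interact: a `tau` much coarser than step durations biases
  bridges toward their endpoints; the `grid cell > h_min` warning exists
  because a coarse grid under-resolves the kernel.
* The responsive model fits a single decay form (exponential) and no
  covariates beyond distance; individuals are fitted separately, with no
  pooling across animals.
* Envelope inference is per-statistic and uncorrected; treat cell-wise
  maps as descriptive.
* The compositional screen is two-class by design; multi-class ranking
  matrices are out of scope.
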