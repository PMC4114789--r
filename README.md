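# roadresponse

Individual-level analysis of animal movement responses to a linear barrier
(a highway), from session-structured radio- or GPS-telemetry.

Road ecologists repeatedly find the same puzzle in medium-sized carnivores:
high road-kill counts on highways whose drainage culverts and underpasses
the same species demonstrably uses. One explanation is that individuals
differ — some animals avoid the road, some ignore it, some cross routinely
but only where they know a passage. Testing that requires inference at the
level of the *individual*, where sample sizes are far too small for the
usual population-level models. This package implements an analytical
framework built for exactly that situation: every observed behavior is
compared against simulations parameterized by that same animal's own data.

## What it computes

For each tracked animal:

1. **Utilization distribution (UD)** by biased random bridges (BRB), a
   movement-based kernel density estimator. Interpolated points are laid
   along each step's chord and smoothed with a bandwidth
   `h²(p) = h_min² + 4p(1−p)(h_max² − h_min²)`, `h_max² = h_min² + DT/2`,
   which collapses to `h_min` at the observed fixes and widens mid-step
   with the step duration `T` and diffusion coefficient `D` (estimated
   from the data by a Brownian-bridge leave-one-out likelihood). The home
   range is the 95% isopleth of the UD.

2. **Movement response angles.** For each step, the response angle
   `A = wrap(B − C)` compares the step heading `B` with the bearing `C`
   to the nearest highway point: `A = 0` is movement straight toward the
   highway, `|A| = π` straight away, `|A| = π/2` parallel. Two nested von
   Mises models are fitted by maximum likelihood: a *no-response* model
   with constant concentration `κ`, and a *responsive* model with
   `κ(T) = θ₁·exp(−θ₂·T)` where `T` is the distance to the highway — the
   response is strongest at the road and fades to uniform far away. The
   models are compared by a likelihood-ratio test on 1 df, and significant
   fits are classified by `|μ|` as attraction, avoidance, or parallel
   movement.

3. **Highway crossings**: consecutive same-session fixes on opposite
   sides. Crossing fix pairs are smoothed with the same BRB estimator into
   `UD_cross`, masked to 200 m around the highway and projected onto the
   road's chainage axis — a profile of *where* the animal crosses.

4. **A barrier-naïve null model**: a constrained random walk that replays
   each tracking session — same start sites, same number of steps, the
   observed step lengths in their observed order — with uniformly random
   directions inside the animal's home-range polygon, 1000 replicates by
   default. Observed crossing counts, per-cell UD mass and the chainage
   profile are classified against the replicates' 5–95% percentile
   envelopes: outside the band means more (or less) than expected from a
   highway-blind animal with the same movement capacity.

A weighted compositional analysis (log-ratio of used vs available habitat,
Wilks' Λ with a sign-randomization p) screens for habitat selection before
movement is attributed to the road, and a synthetic-telemetry generator
with known ground truth (`behavior_truth()`, `generate_scenario()`) makes
every stage testable end to end.

## Worked example

Simulate one highway-avoiding animal under the default study regime
(25 nightly sessions, ~12 fixes per session at ~39 ± 22 min) and ask
whether its movement responds to the highway:

```r
library(roadresponse)

scen <- generate_scenario(
  list(F2 = behavior_truth("avoidance", home_center = c(5000, 500),
                           n_sessions = 25, fixes_mean = 12)),
  seed = 42)
track <- scen$tracks$F2
track
#> Animal 'F2': 25 sessions, 301 fixes, 186.3 tracked hours
#>   inter-fix interval 40 +/- 20 min

ang  <- response_angles(track, scen$landscape$highway)
fit0 <- vm_response(A ~ 1, ang)   # no-response: constant kappa
fit1 <- vm_response(A ~ T, ang)   # responsive: kappa decays with distance
summary(fit1)
#> von Mises responsive model, n = 248
#>   |mu| = 3.01 rad (reported 0..pi)
#>   theta1 = 2.23, theta2 = 0.0044 /m (half-distance 157 m)
#>   log-likelihood -439.94

anova(fit0, fit1)
#> Likelihood-ratio comparison
#>             df  logLik  Chisq Pr(>Chisq)
#> no-response  2 -447.97
#> responsive   3 -439.94 16.067  6.116e-05 ***

classify_response(fit1, lr_test(fit0, fit1))
#> [1] "avoidance"
```

The fitted `|μ| = 3.01` rad (near π: steps point away from the road when
close to it), `θ₁ = 2.23` (moderate concentration at the road itself) and
`θ₂ = 0.0044`/m (the response halves every ~160 m) recover the generating
avoidance behavior, and the LR test rejects the distance-independent model.
The 95% isopleth home range is ~2.5 km² and the animal never crossed:

```r
hr <- isopleth(estimate_ud(track, brb_params()), 0.95)
hr
#> Polygon: 3 ring(s), area 2.534 km^2
nrow(detect_crossings(track, scen$landscape$highway))
#> [1] 0
```

`run_pipeline()` chains all stages — UD, response model, crossings, null
replicates, envelopes, habitat screen — for a set of animals and writes
per-animal artifacts plus a run manifest.

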