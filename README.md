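# iftflow

Quantitative analysis of intraflagellar transport (IFT) motor dynamics in
cilia, for researchers working with fluorescence time-lapse movies of
labelled motors (for example IFT dynein in *C. elegans* phasmid cilia).
The package covers the full chain from raw image stacks to kinetic
parameters and back to predicted ensemble distributions:

* **Ensemble kymographs** — build kymographs along a ciliary spline,
  separate anterograde / retrograde / static components by 2-D Fourier
  filtering, extract train traces and compute position-dependent velocity,
  motor-number, train-frequency and flux profiles.
* **Two-colour colocalization** — channel registration on static features,
  background / bleaching / bleed-through correction, thresholded Manders
  coefficients M1 and M2, and on-train intensity ratios.
* **Single molecules** — spot detection and linking, spline projection,
  rule-based classification (anterograde, retrograde, base-diffusive,
  stationary, turnaround, with pause detection), and turnaround-hazard
  estimation.
* **Stochastic simulation** — a single-motor shuttle model that converts
  single-molecule switching statistics into the steady-state motor
  distribution along the cilium.
* **Synthetic data** — a ground-truth generator for trajectories,
  kymographs and image stacks, so every stage is testable without raw
  microscopy data.

## The model at the core

Single motors switch direction stochastically with a probability density
per distance travelled: `P_AR` for anterograde-to-retrograde switches,
`P_RA` for the reverse. Under this exponential-distance model,

* distance to the next switch: `d ~ Exp(P)`;
* hazard estimate from tracks: `P = N / D` (switch count over at-risk
  distance; Poisson error `sqrt(N)/D`);
* effective run length: `1/P`;
* probability of crossing a cilium of length `L` without switching:
  `exp(-P L)` — the reach-tip / reach-base probability.

`turnaround_statistics()` fits this model to a classified trajectory set
and returns a model object with `print`, `summary`, `coef`, `confint` and
`simulate` methods; `simulate()` runs the stochastic ensemble model at the
fitted hazards.

## Worked example

Hazards from switch counts and travelled distances (34 anterograde-to-
retrograde switches over 242.9 µm anterograde; 4 reverse switches over
57.1 µm retrograde; 9 µm cilium):

```r
library(iftflow)
fit <- turnaround_from_counts(n_ar = 34, d_antero = 242.9,
                              n_ra = 4, d_retro = 57.1, L = 9)
summary(fit)
#> IFT-dynein turnaround hazards (exponential-distance model)
#>   P_AR = 0.140 +/- 0.024 /um  (34 turns over 242.9 um anterograde)
#>   P_RA = 0.070 +/- 0.035 /um  (4 turns over 57.1 um retrograde)
#>   run lengths: anterograde 7.1 +/- 1.2 um, retrograde 14.3 +/- 7.1 um
#>   reach probabilities over 9 um: tip 28% +/- 6%, base 53% +/- 17%
```

So an anterograde-moving dynein reverses on average every 7 µm and has a
28% chance of reaching the tip of a 9 µm cilium, while a retrograde motor
reaches the base with 53% probability — the asymmetry that distinguishes
dynein as active driver from dynein as carried cargo.

The full synthetic round trip — generate 2000 single-motor tracks at known
kinetics, classify them, re-estimate the hazards and compare the ensemble
distribution simulated at recovered versus true parameters:

```r
rep <- run_recovery_pipeline(n_trajectories = 2000, n_events = 4000, seed = 1)
rep
#> synthetic-data recovery report
#>   trajectories kept: 1453
#>   hazards: true (0.140, 0.070), recovered (0.154 +/- 0.017, 0.065 +/- 0.015) /um
#>   class shares (%): anterograde 37.1, retrograde 23.6, base_diffusive 15.1, stationary 12, turnaround 7.8, rejected 4.5
#>   occupancy residual (recovered vs true hazards): 0.050
```

And the ensemble prediction from the fitted single-molecule statistics:

```r
sim <- simulate(fit, seed = 1, n_events = 10000)
sim
#> stochastic motor simulation: 10000 events (P_AR = 0.140, P_RA = 0.070 /um)
#>   clean base-to-tip transits: 28.8%
#>   mid-track turns: 9351 A-to-R, 4762 R-to-A over 67323 / 67323 um
plot(sim)   # corrected, PSF-smoothed occupancy along the cilium
```

The measured 28.8% of clean base-to-tip transits matches the closed form
`exp(-0.14 * 9) = 0.284` within counting error, and the plotted occupancy
is relatively constant along the cilium once the phasmid-overlap correction
and PSF smoothing are applied.

See the vignette (`vignettes/ift-dynein-motility.Rmd`) for the models,
rules and design decisions behind each stage.

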