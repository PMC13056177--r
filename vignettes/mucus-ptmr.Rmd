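---
title: "Particle tracking microrheology and sperm kinematics in cervical mucus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle tracking microrheology and sperm kinematics in cervical mucus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmr)
options(ptmr.verbose = FALSE)
```

## The measurement problem

Cervical mucus regulates fertility mechanically: when it thickens, sperm
cannot ascend; when it thins around ovulation, they can. Clinical appraisal
of this property is still largely qualitative (stretchability scores and the
like). `ptmr` implements a paired, quantitative alternative:

1. **Particle tracking microrheology (PTMR).** Micron-sized beads are mixed
   into a mucus sample and filmed (10 s at 30 frames per second). Their
   thermal jitter is tracked, converted to a mean squared displacement (MSD),
   and inverted through the generalized Stokes-Einstein relation (GSER) into
   the complex viscosity $\eta^*$ — a scalar readout of how thick the sample
   is at a reference frequency.
2. **Sperm kinematics.** Sperm swimming in parallel aliquots of the same
   sample are filmed (5 s at 20 frames per second) and tracked with the same
   detector, opened up to larger, more elongated shapes. The standard CASA
   metrics (VSL, VCL, VAP, LIN, STR, ALH) are computed per trajectory; the
   sample summary is the median log10 straight-line velocity (VSL).

Across a half-fold dilution series of each sample the two readouts move in
opposite directions, and the package's analysis module quantifies that:
log10 VSL against log10 $\eta^*$ by Pearson correlation, and velocity against
relative concentration $c$ (= 1/dilution factor) by a log-log power-law fit.

Because no public image data accompany this assay, the package ships a
physics-grounded simulator that generates every input the pipeline consumes
— trajectories and rendered image stacks with known ground truth — so each
stage is testable end to end.

## The model chain

### Bead dynamics and the GSER

A bead of radius $a$ in a Newtonian fluid of viscosity $\eta$ diffuses with
$D = k_B T / (6 \pi \eta a)$. The simulator draws exact Gaussian increments
with per-axis variance $2 D \Delta t$ at the frame interval $\Delta t$ —
Brownian increments are exact at any step size, so there is no integration
error to control. The time-averaged 2-D MSD of a trajectory is
$\langle \Delta r^2(\tau) \rangle$ over all overlapping frame pairs at lag
$\tau$; trajectories are ensemble-averaged with weights equal to the number
of displacement pairs at each lag.

The GSER inversion follows the local power-law (Mason) approximation: at
probing frequency $\omega = 1/\tau$,

$$|G^*(\omega)| = \frac{2 k_B T}
{3 \pi a \, \langle \Delta r^2(\tau) \rangle \, \Gamma[1 + \alpha(\omega)]},
\qquad
G' = |G^*| \cos(\pi \alpha / 2), \quad
G'' = |G^*| \sin(\pi \alpha / 2), \quad
\eta^* = |G^*| / \omega,$$

where $\alpha(\omega) = \mathrm{d} \ln \langle \Delta r^2 \rangle /
\mathrm{d} \ln \tau$ is the local logarithmic slope, estimated by a quadratic
fit in log-log space over a five-point window (edge-truncated) and clipped to
$[0, 1]$. The factor $2/(3\pi a)$ embeds the $3/2$ conversion from a 2-D MSD
to its 3-D equivalent; under this convention a Newtonian fluid returns
$\eta^*(\omega) = \eta$ *exactly*, which the test suite asserts to numerical
precision.

```{r newtonian}
D <- stokes_einstein_D(rheo_params(), viscosity = 1e-3) # um^2/s in water
lags <- seq(0.1, 3, 0.1)
spec <- gser_spectrum(tibble::tibble(lag = lags, msd = 4 * D * lags,
                                     n_obs = 100L))
eta_star_at(spec, omega_ref = 2 * pi) # 1e-3 Pa s, exactly
```

### Sperm motion

Each simulated sperm swims with a persistent heading (the heading angle
diffuses with variance $\Delta t / \text{persistence}$ per step) at a
progressive speed drawn lognormally around the median
$v(c) = v_1 \, c^{-\beta}$, plus a sinusoidal lateral head oscillation
perpendicular to the path. $\beta$ defaults to $0.5$: halving the mucus
concentration multiplies the median speed by $\sqrt{2}$.

### The paired dilution cohort

`simulate_dilution_series()` ties the two arms together per
(animal, dilution) point: bead dynamics use
$\eta(c) = \eta_\text{buffer} + (\eta_\text{neat} - \eta_\text{buffer})\,
c^{\,p}$ and sperm speeds the swimmer law. `run_dilution_cohort()` processes
every point through both chains, either from the simulated trajectories
directly (`via = "tracks"`) or through rendering and re-tracking of synthetic
videos (`via = "images"`), and ends with the Pearson test.

```{r cohort, eval = FALSE}
cohort <- run_dilution_cohort(n_animals = 6, dilution_factors = 2^(0:7),
                              seed = 42, via = "tracks")
cohort$correlation
autoplot(cohort$correlation)
plot_dilution_series(cohort$points)
```

## Tracking: Crocker-Grier with the assay's two regimes

Detection is the classic scheme: band-pass filtering (Gaussian blur at the
noise scale minus a boxcar background at the feature scale, clipped at
zero), local maxima above an intensity percentile, iterative sub-pixel
centroid refinement inside a circular mask, and intensity-moment statistics.
The moment eccentricity is
$(\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)$ for the eigenvalues
$\lambda_i$ of the second central moment matrix of the masked spot: 0 for a
circular spot, about 0.38 for the 1.5:1 elongation used to render sperm
heads. The two regimes differ only in shape parameters:

| parameter         | bead | sperm |
|-------------------|------|-------|
| feature diameter  | 11 px | 17 px |
| max eccentricity  | 0.3  | 0.5   |
| frame rate        | 30 Hz | 20 Hz |
| min duration      | —    | 1 s   |
| search range      | 5 px | 15 px |
| linking memory    | 3    | 0     |

Linking minimizes the total squared displacement between consecutive frames
within the search range (exact enumeration inside connected candidate
subnetworks of up to 7 particles, deterministic greedy matching above that,
an error beyond a hard cap of 60). The search ranges derive from the expected
per-frame displacements: beads move at most a few tenths of a micron per
frame ($\sqrt{4 D \Delta t} \approx 1.2$ px at buffer viscosity and
0.2 um/px), while the fastest simulated sperm cover about 11 px per frame at
1 um/px. Sperm get no memory because a fast swimmer's identity cannot be
safely re-acquired after a miss.

The duration convention is `(last_frame - first_frame) / frame_rate`, so at
20 fps a trajectory must span 21 observed frames to pass the 1 s filter —
displacement-based velocities use elapsed time between the first and last
observation.

## Parameters that matter

* **Temperature** (default 293.15 K). The source assay does not state its
  measurement temperature; $\eta^*$ scales linearly with the assumed $T$, so
  the value is configurable everywhere and echoed in outputs.
* **Reference frequency** (default 1 Hz, $\omega = 2\pi$ rad/s). A scalar
  $\eta^*$ must be read off somewhere; 1 Hz sits comfortably inside the lag
  window below.
* **Lag window** (default 3 frames to 0.3 x track span). Single-frame lags
  are dominated by localization error; long lags average too few pairs.
* **Drift correction** (beads on, sperm off). When at least 5 simultaneous
  tracks exist, the per-frame ensemble mean displacement is subtracted.
  Subtracting the mean of $N$ displacements removes $1/N$ of the thermal
  variance, biasing $\eta^*$ up by $\approx N/(N-1)$; with the default FOV
  occupancies (12 beads, ~100 in the reference checks) this stays well inside
  the assay's tolerance. Sperm are never drift-corrected — directed motion is
  the signal.
* **Localization noise** (default 0.01 um per axis). Adds a constant
  $4\sigma^2$ to the MSD; this noise floor is what limits PTMR at high
  viscosity, where true displacements shrink toward it. No static-error
  subtraction is applied by default (the assay has no calibration sample);
  the floor is visible as a mild compression of $\eta^*$ at the neat end.
* **Aggregation** (median of log10 values). Distribution-family selection by
  Anderson-Darling tests (`choose_transform_family()`) picks log10 on the
  simulated cohort, whose dispersions are lognormal by construction; ties go
  to log10. The source describes both ensemble means and median log10 values
  in different places; the median is the default here, with the mean
  available by flag.
* **Correlation pooling.** All animal-by-dilution points are pooled into one
  Pearson test (a per-animal stratified run is a trivial `group_by` away);
  two-sided p-values, $\alpha = 0.05$, no multiple-testing correction.

## What the simulator does and does not emulate

It reproduces the features the pipeline is sensitive to: exact Brownian
statistics at the acquisition frame rates, power-law concentration scaling
with lognormal heterogeneity between sperm and between animals, lateral head
oscillation, camera pixelation, Gaussian/Poisson noise, finite fields of view
(fast sperm leave the frame and their tracks truncate — the same selection
pressure the real assay faces), and detection-induced localization error.

It does not emulate: non-Newtonian mucus microstructure (beads diffuse as in
an effective Newtonian fluid at each concentration, so $\alpha \approx 1$
everywhere; real mucus shows elastic plateaus), bead-network interactions,
3-D diffusion with defocus, flagella (sperm render as single elongated-head
spots), collisions, or pH/osmolarity physiology. Passing tests therefore
demonstrate that the measurement chain is faithful — not that real mucus is
Newtonian.

## Numerical choices and degenerate inputs

* Band-pass kernels are separable with edge replication; the Gaussian is
  truncated at $2\sigma$ and renormalized. A uniform image maps to exactly
  zero.
* Centroid refinement runs at most 10 iterations, shifting the integer mask
  while the offset exceeds 0.5 px; duplicate maxima closer than one feature
  diameter merge, larger mass wins, ties break toward lower (y, x) so the
  detector is order-independent.
* Candidates whose peak cannot reach `min_mass` even if the whole mask were
  at peak intensity are skipped before refinement (a provable bound, not a
  heuristic cut).
* MSD lags with non-positive values are excluded with a warning before the
  GSER (log of zero); a spectrum with no usable lag is an error. Local
  slopes above 1 (apparent superdiffusion, a finite-sample artifact for
  thermal beads) clip to 1 with a warning; below 0 clip to 0.
* `eta_star_at()` interpolates log-log and refuses to extrapolate.
* Ensemble MSDs use the intersection lag grid by contract; the internal
  rheology chain uses the union grid with an `n_obs` floor because linking
  fragments tracks unevenly — the intersection would be dictated by the
  shortest fragment.
* Zero-VSL tracks are excluded (and counted) from log10 summaries; non-
  positive $\eta^*$ replicates likewise.
* All stochastic stages take explicit seeds; multi-stage runs derive child
  seeds from one master seed, so identical configurations reproduce
  bit-identical outputs.

## Problem sizes used in the checks

The reference checks run the buffer-viscosity recovery with 100 beads for
10 s at 30 fps; the scaling-exponent check with 50 sperm per dilution across
1:1..1:128 (dispersion 0.05 log10 units); and the cohort correlation with
6 animals x 8 dilutions (12 beads and 20 sperm per point when imaging). The
image-based cohort uses 128 px bead fields at 0.2 um/px and 256 px sperm
fields at 1.0 um/px — single-field occupancies and calibrations typical of
the assay's optics.

## Known limitations

* The GSER inversion assumes the local power-law approximation; sharply
  curved MSDs (gel points) are smoothed by the five-point slope window.
* $\eta^*$ saturates near the localization-noise floor at high viscosity, so
  neat-mucus values are compressed rather than unbiased; dilution trends and
  correlations are unaffected in direction.
* At high dilution, faster sperm exit the field sooner, so the 1 s duration
  filter preferentially retains slower cells and the measured median VSL
  under-reads the generator's median — the same residence-time selection any
  finite-field assay has. The log-log correlation with $\eta^*$ remains
  strongly negative.
* The linker is frame-greedy (optimal per transition, not over whole
  trajectories); crossing sperm paths can swap identities, which perturbs
  VCL/ALH slightly but barely moves VSL medians.
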