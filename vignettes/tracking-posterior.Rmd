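---
title: "Posterior sampling of single-particle tracking solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior sampling of single-particle tracking solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-particle tracking (SPT) reconstructs molecular trajectories from
per-frame point detections. Conventional trackers return one linking
solution and no measure of how certain it is; in crowded or blinking data
many alternative linkings are nearly as plausible, and any quantity derived
from a single solution (a diffusion coefficient, say) inherits an unknown
error. `sptmcmc` treats tracking itself as Bayesian inference: it samples
the joint posterior of the *track partition* $\omega$ (the assignment of
every detection to a track or to clutter) and the governing parameters
$\theta$, so that link probabilities and error bars on derived quantities
come out of the same machinery.

## The model

**Data.** $Y$ is the set of $N$ detections $(x, y, t)$ over $T$ frames in a
field of view $[0,W)\times[0,H)$. Event rates are expressed in the unit E =
one event per frame per $100\,\mathrm{px}\times100\,\mathrm{px}$.

**Partition.** A track is a time-ordered set of at least two observations,
at most one per frame; consecutive observations form *links* (frames need
not be adjacent — blinking creates dark gaps). Every observation belongs to
exactly one track or to the clutter.

**Parameters.** $\theta = (\lambda_b, \lambda_c, p_o, p_s, R)$: the birth
and clutter rates (E), the per-frame observation probability, the per-frame
survival probability, and the $2\times2$ localisation-noise covariance
(px²) — seven scalar dimensions.

**Partition prior** $P(\omega\mid\theta)$: per-frame Poisson birth and
clutter counts with area-scaled means $\lambda_b WH/A$ and $\lambda_c WH/A$;
per-frame Bernoulli survival (geometric lifetimes of mean $1/(1-p_s)$,
right-censored at the end of the movie); per-live-frame Bernoulli
observation. Exactly these forms make the parameter conditionals conjugate.

**Likelihood.** Clutter positions are uniform over the field of view. Each
track is scored by a linear-Gaussian state-space model with state
$X=(x,\dot x,y,\dot y)$: positions integrate their velocities, and the
velocities follow their own random walk. A Kalman filter runs over the
track's span (predict-only across dark frames); each observation contributes
the bivariate normal log-density $\mathcal N(Y;\,B\hat X,\,\hat S)$ of its
position under the predicted state, where the innovation covariance
$\hat S = B P B^\top + R$ combines the localisation noise with the state
uncertainty. Because the filter refits the whole track, reassigning one
observation changes the likelihood terms of *all* its observations. A
Rauch–Tung–Striebel pass provides smoothed states where estimates based on
all observations are required.

## The sampler

A Gibbs sampler alternates

1. $\omega_i \sim P(\omega \mid \theta_{i-1}, Y)$ via Metropolis–Hastings
   sweeps, and
2. $\theta_i \sim P(\theta \mid \omega_i, Y)$ by direct conjugate draws:
   Gamma for the rates (shape = count + 1, rate = exposure, from the flat
   improper prior), Beta for the probabilities, and inverse-Wishart for $R$.

The MH proposal draws one of nine move types uniformly — birth/death,
extend/reduce, split/merge, update, transfer, cross-over — and then descends
a move-specific sampling tree; the proposal mass $Q(\omega^*\mid\omega)$ is
the product of the branch probabilities actually taken, and the probability
of the unique inverse path is evaluated in the proposed state, so the
acceptance ratio uses exact $Q$ values in both directions. Dead ends (a
birth chain that collects fewer than two observations, a death move with no
tracks, ...) propose the identity, which is accepted by construction but
bookkept as rejected. Proposals are speed-gated: no link may span more than
`max_speed` px/frame or more than `gate_frames` frames.

For the $R$ update, a state trajectory is drawn for every track by
forward-filtering backward-sampling and the residuals are taken about the
*sampled* states. Residuals about the smoothed mean would underestimate the
noise — the smoothed mean absorbs part of it, and over Gibbs iterations $R$
would collapse toward zero; conditioning on sampled states is the exactly
conjugate step.

**Two chains and convergence.** One chain starts from the minimum partition
(everything clutter), the other from a randomised greedy maximum partition
(no further link addable), deliberately far apart. Convergence requires
both: the mean cross-chain graph edit distance (GED: number of links in
which two partitions differ) must not exceed the sum of the two mean
inner-chain GEDs, and the Gelman–Rubin statistic of each of $\lambda_b,
\lambda_c, p_o, p_s$ must fall below `psrf_threshold` (default 1.1).
After convergence each chain records `n_record` thinned samples; the
thinning interval is $\mathrm{round}(2/a)$ for acceptance rate $a$ (1 in 8
at 25%): the lower the acceptance rate, the sparser the recording, since a
slowly moving chain repeats itself.

## Tunable parameters

| key | default | unit | role |
|---|---|---|---|
| `max_speed` | 16 | px/frame | link speed gate, far above physiological speeds |
| `gate_frames` | 4 | frames | maximum frame gap of a link |
| `q_pos` | 1.0 | px²/frame | position process noise |
| `q_vel` | 0.1 | (px/frame)²/frame | velocity process noise |
| `prior_sigma0` | 10 | px | near-diffuse initial position s.d. |
| `prior_sigmav` | 2 | px/frame | initial velocity s.d. |
| `phi_scale`, `wishart_dof` | 0.01, 4 | px², — | weakly-informative IW prior on $R$ |
| `steps_per_sweep` | $\max(N, 100)$ | steps | MH steps per $\theta$ draw |
| `max_sweeps` | 20000 | sweeps | burn-in budget |
| `n_record` | 4000 | samples | recorded samples per chain |

`gate_frames = 4` admits up to three consecutive dark frames; at an
observation probability of 0.9 the fraction of true links with longer gaps
is about $10^{-4}$, so the gate removes essentially no real links while
keeping candidate sets small. The greedy initialiser uses a 2-frame gap:
its only job is to produce *a* maximal partition far from the minimum one.
The process-noise defaults make the motion prior tolerant of sub-pixel to
pixel-scale per-frame motion; they are deliberately loose — the design goal
is a tracker that needs no per-dataset tuning — and are exposed in
`sampler_config()` for unusual dynamics.

## What the simulator emulates

`simulate_ground_truth()` draws per-frame Poisson births at uniform
positions, geometric lifetimes, and one of four motion modes (random walk
with diffusion coefficient $D$; directed motion with Gaussian heading
turns; a 50/50 mixture; per-frame mode switching). `realise()` applies
Bernoulli observation, isotropic Gaussian localisation error, uniform
Poisson clutter, and crops to the field of view, keeping the labels and the
set of true links. `simulate_crossing_lines()` adds a deterministic pattern
of intersecting straight lines whose crossings exercise split/merge
ambiguity. Not emulated: camera noise and image formation (detection is
upstream), non-uniform clutter or birth intensity, anomalous diffusion,
photophysics beyond Bernoulli blinking. Passing tests on these simulations
therefore demonstrates correctness of the inference machinery under the
stated generative model, not robustness to arbitrary real microscopy data.

## Numerical choices

* Kalman updates use the Joseph form and symmetrisation, keeping
  covariances PSD over arbitrarily long recursions.
* The unnormalised log posterior is maintained incrementally (per-track
  likelihood cache plus count deltas); it is recomputed against an
  independent R implementation in the tests to $10^{-9}$.
* Exact proposal masses: an R-level enumerator walks each move's full
  sampling tree on toy problems and verifies both that the masses sum to
  one and that the compiled kernel's forward and reverse log-masses match
  path by path.
* Ties in the greedy initialiser and all sampling are driven by R's RNG:
  one seed reproduces a run bit for bit.
* Degenerate inputs: an empty observation set yields minimum-partition
  chains and prior draws; tracks alive at the final frame contribute no
  death event; empty count cells fall back to their priors.

## Design choices on open points

* **GED** is defined purely on link sets; unobserved birth/death times do
  not enter. Moves never propose unobserved overhangs, so track birth and
  death times equal the first/last observation frames.
* **Reduce** removes a whole end segment (branch product
  $\tfrac19\cdot\tfrac1K\cdot\tfrac12\cdot\tfrac1c$ over the $c$
  allowed cut points); its inverse, **extend**, therefore appends a geometric-length
  chain of clutter observations, mirroring the birth chain, so the pair
  stays mutually reachable in one step.
* **Update** swaps a track observation against a clutter observation in the
  same frame (GED ≤ 4); **transfer** moves one interior observation into a
  strictly interior slot of another track (GED = 6); **cross-over**
  exchanges the suffixes of two tracks after a common cut time (GED ≤ 4).
  These semantics pin down the per-move GED footprints.
* **Sweep structure:** one conjugate $\theta$ draw per `steps_per_sweep`
  MH steps amortises the parameter update while keeping the Gibbs
  structure.
* The cross/inner GED criterion is estimated on at most `ged_pairs`
  random sample pairs (full pairwise distance is quadratic).

## Problem sizes used in the shipped checks

The test-suite and the acceptance script regenerate everything: toy
stationarity uses a 5-observation, 13-partition problem with $10^6$ MH
steps thinned 1:53 before the $\chi^2$ comparison (thinning removes the
autocorrelation that the multinomial test does not model); move footprints
use $\ge 10^5$ proposals on partitions evolved from mid-density
simulations; the link-accuracy studies use the study generation
settings ($D = 0.08$ px²/frame, $p_o = 0.9$, $p_s = 0.98$, 0.1 px
localisation error, clutter 0.4E, $T = 100$; birth rate 0.1E on
$100\times100$ px or 1.6E on $25\times25$ px, three seeds each, medians
reported) with 300 recorded samples per chain; the coverage study uses 20
data sets at birth rate 1.6E on $30\times30$ px over 50 frames with 150
recorded samples per chain. Burn-in budgets (16000–20000 sweeps) are set
so that the minimum-partition chain reliably crosses from its early
wrong-assembly mode into the posterior mode; the convergence criterion,
not the budget, decides when recording starts.

## Known limitations

* Mixing is slow by construction: most proposals change one or two links,
  so burn-in dominates the run (as the move statistics tables show, final
  acceptance rates sit at a few percent). Crowded data can leave the two
  chains in slightly different modes; pooling both chains' records is the
  package's default for all downstream estimates.
* The survival model implies geometric lifetimes truncated by the movie;
  $p_s$ samples are accordingly biased for short movies, and the sampler
  shares the documented mild preference for fewer, longer tracks (merging
  two short tracks across a gap raises $p_s$, lowers $p_o$ and
  $\lambda_b$, leaving the observation count unchanged).
* Smallest-interval credible intervals on derived quantities (e.g. the
  diffusion coefficient) under-cover: the partition posterior does not
  account for the randomness of the realisation itself. The coverage study
  reproduces this deficit rather than hiding it.
* No spatial chunking: run time grows with $N$ through the per-sweep step
  count; data sets beyond a few thousand observations call for windowed
  analysis.
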