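# sptmcmc — posterior sampling of single-particle tracking solutions

Single-particle tracking (SPT) links per-frame spot detections
`(x, y, frame)` into molecular trajectories. Conventional trackers return
one linking and no error bar; in crowded, blinking single-molecule movies
many alternative linkings are almost equally plausible. `sptmcmc` samples
the full posterior of tracking solutions instead: a Gibbs sampler
alternates Metropolis–Hastings moves on the *track partition* ω (the
assignment of every detection to a track or to clutter) with direct
conjugate draws of the governing parameters

θ = (λ_b, λ_c, p_o, p_s, R)

— birth rate, clutter rate, observation probability, survival probability
(per frame), and the 2×2 localisation-noise covariance. Track likelihoods
P(Y_i | k_i, θ) come from a Kalman filter / RTS smoother over a
near-constant-velocity motion model, so blinking gaps are handled natively;
the partition prior P(ω | θ) uses per-frame Poisson births and clutter,
geometric lifetimes and Bernoulli observation; acceptance follows

min{1, [P(ω*|θ,Y) Q(ω|ω*)] / [P(ω|θ,Y) Q(ω*|ω)]}

with exact forward and reverse proposal masses from the nine-move sampling
tree (birth/death, extend/reduce, split/merge, update, transfer,
cross-over). Two chains start from the minimum (all-clutter) and a greedy
maximum partition; convergence requires the cross-chain graph-edit distance
criterion and Gelman–Rubin statistics of the four scalar parameters. The
output is a set of thinned partition samples from which the package
computes link probabilities p̂(l), performance metrics against simulated
ground truth (JSC, recall, precision), and posterior distributions of
derived quantities such as the diffusion coefficient with
smallest-interval credible intervals.

It is aimed at single-molecule microscopists and methods developers who
need tracking *uncertainty* — link-level confidence and error bars on
derived biophysics — rather than a single best solution. Spot detection is
upstream: the package consumes localisation tables, not images.

## Worked example

```r
library(sptmcmc)

# simulate a low-density single-molecule movie: diffusion 0.08 px^2/frame,
# 90% observation probability, 0.1 px localisation error, clutter 0.4 E
set.seed(42)
gt   <- simulate_ground_truth(lambda_b = 0.1, p_s = 0.98,
                              motion = list(mode = "random_walk", D = 0.08),
                              fov = c(100, 100), n_frames = 100)
real <- realise(gt, p_o = 0.9, loc_error = 0.1, lambda_c = 0.4)
real
#> <spt_realisation> N = 349 observations (41 clutter), 290 true links

run <- run_sampler(real$obs, sampler_config(n_record = 300), seed = 1)
run
#> <spt_chains> 2 chains, 300 recorded samples each; burn-in 8400 sweeps x 349 steps; converged
run$convergence
#> <spt_convergence> cross GED 1.64 vs inner 1.06 + 1.99; PSRF max 1.015; converged

lp <- link_probabilities(pooled_samples(run), real$obs)
scores(confusion(lp, real$true_links, p_min = 0.5, real$obs))
#>       jsc    recall precision
#> 0.9897611 1.0000000 0.9897611

# posterior of the diffusion coefficient, from every recorded solution
D <- diffusion_posterior(pooled_samples(run), real$obs)
median(D); smallest_interval_ci(D[is.finite(D)], 0.95)
#> [1] 0.08078
#> [1] 0.06513 0.09928
```

The run converges once the graph-edit-distance and Gelman–Rubin criteria
both pass; at `p_min = 0.5` every true link is recovered at 99.0%
precision, and the posterior spread of D is the tracking uncertainty
propagated into the derived quantity (the generating value was
0.08 px²/frame; this realisation's own ground-truth D was 0.0837, inside
the 95% interval).

A thin command-line front end with `simulate`, `track`, `metrics` and
`diffusion` subcommands ships in `inst/cli/sptmcmc-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sptmcmc-cli.R", package="sptmcmc"))')" \
    track --input spots.csv --seed 1 --out outdir
```

See `vignettes/tracking-posterior.Rmd` for the model, the move kernel, all
tunable parameters and the package's design decisions.

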