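---
title: "Models, numerics and design choices in sfsdfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in sfsdfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sfsdfe infers piecewise-constant demographic histories and gamma-family
distributions of fitness effects (DFEs) from folded site-frequency
spectra (SFSs) built from one quasi-phased bacterial genome per host.
This vignette documents the model assumptions, the numerical machinery,
and the decisions taken where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The model

**Sampling.** For each host, the dominant strain's haplotype is called at
sites where the major allele reaches a frequency of 0.8 at a depth of at
least 20 reads; intermediate frequencies (0.5–0.8) are explicit missing
data. Across hosts this yields `n` haplotypes per species; per site the
number of called haplotypes `c` varies, so minor counts `(m, c)` are
projected to a fixed `n_target = 14` by hypergeometric sampling, dropping
sites with `c < 14`. Projection masses at folded count 0 (and at
`n_target`, after folding) are monomorphic-in-sample and are discarded
from the spectrum but the site still counts toward the monitored-site
total `L`. Fractional projected bin counts are kept unrounded; rounding
would bias the low-frequency bins that carry most of the selection
signal, and both likelihoods accept fractional counts through `lgamma`.

**Demography.** The synonymous folded SFS is treated as neutral. Expected
spectra under a piecewise-constant history come from coalescent
lineage-count expectations: the time spent with `k` ancestral lineages
has a closed form (a finite sum of exponentials in time-rescaled units)
for any sequence of instantaneous size changes, and the expected folded
bin is a fixed combinatorial contraction of those times. This is exact,
smooth in the parameters, and microseconds per evaluation, so it can sit
inside a multi-start optimizer — a grid-based diffusion solve would give
the same numbers (the test suite verifies agreement to ~1e-6) at ~1e5
times the cost. The multinomial likelihood uses only bin proportions, so
`theta_s` is profiled analytically as observed-total / model-total; a
k-epoch family therefore has `2(k-1)` free parameters, which is also the
`k` used in AIC.

**Selection.** Conditional on the fitted demography, nonsynonymous
spectra are modeled as independent Poisson bins (Poisson random field)
with mean `theta_ns` times a mixture over the DFE of per-unit-theta
selected spectra. `s` is the haploid fitness cost of a mutation; the
population-scaled coefficient is `gamma = 2 N_Anc s`, and
`theta_ns = 2.31 theta_s` fixes the nonsynonymous mutational opportunity.
The DFE families are deleterious-only: gamma(shape, scale) on `|s|`, or
that gamma plus a neutral point mass `p_neu` (one extra parameter).

## Numerical machinery

**Diffusion engine.** Expected spectra under selection solve the 1-D
Wright–Fisher diffusion for the density of segregating frequencies. In
flux form with `psi = V(x) phi` the advection coefficient is the constant
`gamma * nu`, so the finite-volume scheme uses Scharfetter–Gummel
(exponentially fitted) fluxes, which remain stable when advection
dominates. Time stepping is Crank–Nicolson with step `2e-4` (in 2·N_Anc
generations) starting from the analytic ancestral equilibrium; mutations
are injected at the first interior node at the classical rate. The solve
runs on three sin²-spaced grids (120/160/200 points, crowded at the
boundaries) followed by quadratic Richardson extrapolation in the mean
spacing; the extrapolated neutral equilibrium error is ~1e-7 and the
two-epoch neutral error vs the coalescent closed form is ~3e-6.

**Strong selection.** Above `|gamma| = 150` the density concentrates
below the first grid point, but mutation–selection balance is reached on
a timescale `~1/(2 |gamma| nu)`, far shorter than any epoch of interest,
so the engine returns the stationary spectrum at the current epoch size
by adaptive quadrature of the analytic density (the integrand's boundary
layer at `x ~ 1/(2|gamma|)` is isolated by interval splitting). The
approximation degrades only in the corner where `|gamma|` is large but
`|gamma * nu|` is small (a severe contraction combined with strong
selection); such components contribute little polymorphism to the
mixture. One-epoch models always use the analytic stationary density —
on the grid quadrature inside the engine, by independent adaptive
quadrature in the PRF oracle, keeping the two routes distinct.

**DFE mixture.** The mixture integrates over a log-spaced `|gamma|` grid
(default 60 nodes from 1e-4 to 2000) by the trapezoid rule on the log-s
axis. Gamma mass below the lowest node is added to the neutral component;
mass above the highest node is treated as effectively lethal (zero
polymorphism) — spectra are numerically flat out there. The default grid
resolves DFEs with shape up to ~10 (node spacing must stay below the
log-s standard deviation `1/sqrt(shape)`); the near-point-mass test uses
a locally refined grid for exactly this reason. Node spectra are cached
per demography because fits and LRT grids re-use them heavily.

**Optimization.** All fits are multi-start (at least 25 log-uniform
starts) L-BFGS-B on log-parameters; search boxes are `nu` in
`[1e-3, 1e4]`, epoch durations in `[1e-4, 0.15]` (the stated upper limit
on how far back a size change is allowed), shape in `[1e-3, 50]`, mean
effect in `[1e-9, 1]`. Bound hits are reported, not silently clipped.
Ties across starts go to the best objective value, then the first start.
The constrained (shared-DFE) model in the equality LRT is optimized on a
40×40 log grid over (shape, mean effect) — better conditioned than
(shape, scale) — then refined by Nelder–Mead; nesting
(`ll_constrained <= ll_full`) is enforced with a 1e-3 tolerance and the
statistic floored at `-1e-6`.

**Confidence intervals.** The two-epoch likelihood surface is evaluated
on a global log grid spanning the full search bounds plus a finer patch
around the MLE; intervals take the extremes of `{LL >= LL_max - 3}`. The
global span matters: the (nu, tau) likelihood has a long ridge, and a
grid centered on the MLE truncates the region whenever the MLE sits at a
ridge end (this was observed directly as undercoverage before the fix).
Interval ends falling between grid nodes are reported at the midpoint of
the bracketing nodes unless a node lies exactly on the contour; regions
touching the grid edge are flagged unbounded on that side. Three-epoch
fits report no interval (four free parameters; the df = 2 rule is defined
for the two-parameter surface).

## The synthetic world

The generator's defaults state the world the package is tested in:
samples projected to 14 haplotypes; `theta_s = 1600` (about 5,000
expected synonymous SNPs); `theta_ns/theta_s = 2.31`; read depth
log-normal around 50× (sigma 0.3, floored at 0) with the 20× calling
floor; two strains per host with the dominant at 0.95 by default; 15% of
monitored sites fourfold-degenerate (roughly the fraction of strictly 4D
positions in bacterial coding genomes). SFS bin counts are drawn as
independent Poissons around the model expectation — the generative
counterpart of the PRF likelihood — so linkage enters the tests only
through the masking module. Pileups place across-host polymorphism by
drawing per-bin segregating-site numbers from the expected SFS at
`n_hosts` and assigning carriers uniformly; the secondary strain draws
its allele from the same population frequency. All generators are pure
functions of (parameters, seed), with named substreams derived from one
master seed so adding a generator never perturbs existing streams.

What the generator does **not** emulate: linkage disequilibrium and
draft, within-host evolution, horizontal transfer, more than two strains
per host, sequencing error in the read pileup, and reference-mapping
artifacts. A green test therefore establishes correctness of the
estimators under their own assumptions (free recombination, PRF
independence, known mutation classes), not robustness to those
violations — the masking filters are the only knob exercised against
linkage-like structure.

The forward Wright–Fisher oracle is haploid (fitnesses 1 and `1+s`): a
haploid population of size `N` corresponds to the diffusion's
`2 N_Anc = N`, so `gamma = N s` and the time unit is `N` generations. At
equilibrium it follows independent mutation trajectories from count 1 to
absorption and accumulates exact without-replacement sampling
probabilities (renewal–reward), giving clean between-trajectory Monte
Carlo errors; the non-equilibrium variant simulates whole populations
through burn-in (8·N generations), an instantaneous size change with
binomial resampling, and hypergeometric sampling of `n` haplotypes.

## Open-design decisions

* **Clonal exclusion** keeps one representative per connected component
  of the "divergence < 2e-4/bp" graph (most called sites, ties
  lexicographic) rather than dropping every member: dropping all would
  discard whole clusters of hosts and the information they carry. The
  retained set is verified to contain no pair below threshold.
* **Change times vs durations.** The public model stores cumulative
  change times before the present (validated strictly decreasing); the
  engine and the fit work with the equivalent inter-change epoch
  durations, each bounded by 0.15 · 2 N_Anc generations.
* **Time in years.** `tau * 2 N_Anc` is a number of generations; at one
  generation per day that is the same number of days, i.e.
  `tau * 2 N_Anc / 365` years. The conversion is linear in
  `1/generations_per_day`, so a faster clock proportionally shortens the
  inferred times.
* **L accounting.** `L` for `N_Anc = theta_s / (4 mu L_syn)` counts
  monitored synonymous sites that pass every filter including the
  `c >= n_target` projection rule — the same set of sites whose
  polymorphism `theta_s` was fitted on, keeping numerator and denominator
  consistent.
* **Mutation classes.** Only strictly fourfold-degenerate (4D) sites are
  synonymous and only 1D sites nonsynonymous; 2D/3D sites are ignored
  rather than apportioned.
* **Permutation null for the genus contrast** re-assigns genus labels to
  species (holding genus sizes fixed) and recomputes the standardized
  rank-sum statistic of between- vs within-genus pair values;
  permutations that leave a group empty are discarded. Permuting pair
  labels instead would break the dependence among pairs sharing a
  species.
* **Pagel's lambda** is bounded by positive-definiteness of the
  transformed covariance (found by bisection, capped at 1.5), not by 1,
  and the p-value uses a plain chi-square(1) without the boundary mixture
  correction, matching common phylogenetic-signal implementations.
  Zero-length terminal branches are perturbed by 1e-8 with a warning;
  star trees and zero-variance traits are rejected as unidentifiable.
* **Number of comparisons `m`** in the Bonferroni correction is always
  caller-supplied (the pipeline defaults to the number of pairs it
  actually tests), because the appropriate battery size depends on the
  analysis design, not the package.

## Degenerate inputs and tie-breaks

Empty call tables quasi-phase to empty haplotypes; sites with more than
two observed alleles violate the biallelic assumption and are dropped
with a counted warning; `m > c` is an error. Folding puts a site split
exactly `c/2 : c/2` at the midpoint bin once (no double counting). AIC
ties within 1e-6 go to the fewer-parameter model. An expected count of
zero where data are observed makes the Poisson likelihood `-Inf` with a
warning, which multi-start optimization treats as a rejected point.

## Known limitations

The composite-likelihood framework ignores linkage, so LRT statistics are
anti-conservative on strongly linked data; the engine models no
beneficial mutations, migration, or continuous growth; three-epoch
confidence intervals are not provided; and the quasi-static
strong-selection approximation is least accurate for severe contractions
combined with `|gamma| > 150`. The pipeline's accessory-gene path reuses
the core-gene machinery on a different gene class and inherits all of the
above.
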