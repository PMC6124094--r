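---
title: "Inferring demographic history from whole mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring demographic history from whole mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtskyline` reconstructs changes in effective population size $N_e(t)$ from
whole-mtDNA alignments with a coalescent change-point model in the style of
extended Bayesian skyline plots (EBSP), compares the resulting demographic
profiles between populations with a log-scale curve-similarity statistic,
and relates profile similarity to genetic differentiation (Hudson $F_{ST}$)
through neighbour-joining clustering and a Mantel test. A bundled coalescent
and sequence simulator generates data with the statistical structure the
analysis assumes, so the whole pipeline is testable without any external
download.

## The coalescent change-point model

Time $t$ runs in years before present. The demographic function is
piecewise linear in $N_e$ versus $t$, with knots restricted to the
coalescent event times of a genealogy and selected by binary indicators.
With $k$ lineages extant, the hazard of the next coalescence at time $t$ is

$$\frac{k(k-1)}{2}\cdot\frac{1}{g\,f\,N_e(t)},$$

where $g$ is the generation time in years (default 25; the mutation rates
are per year, so the coalescent needs an explicit generation time) and $f$
is the population factor (default 0.5, the maternal-only contribution of
haploid mtDNA). $f$ scales the coalescent rate only; all reported
trajectories are the unscaled $N_e$. All interval integrals are exact
closed forms on linear segments, and the log-likelihood of a genealogy
adds $-\log(g f N_e)$ at each event; this matches adaptive quadrature to
below $10^{-8}$ in the test suite.

Priors follow the EBSP construction: the number of active change points $K$
is Poisson with mean $\ln 2$ (half the prior mass on "no change", so
detected changes must earn their keep), spread uniformly over the
$\binom{n-1}{K}$ indicator configurations; each active size is log-uniform
on $[1, 10^9]$ (configurable through `skyline_config()`). Between active
knots the trajectory is linear in $N_e$; beyond the oldest active knot it
is constant.

### The point-genealogy simplification

The major, deliberate simplification relative to a full Bayesian analysis:
**inference conditions on a single genealogy** rather than jointly sampling
trees and demography. Recovery experiments use the true simulated
genealogy, which isolates the demographic model; the data path builds an
ultrametric clock tree by UPGMA on partition-weighted TN93 distances
converted to years (`build_clock_tree()`), with partitions weighted by
`n_sites * rate` (partitions that accumulate more substitutions date nodes
more precisely). The cost of this shortcut is measurable and is flagged
rather than hidden: distance-built trees carry event-time artifacts —
zero-length cherries from identical sequences, average-linkage distortion
of node ages — that the change-point posterior partly "explains" with
extra knots, inflating $K$ and slowing the configuration dimension of the
chain. On 85-sequence clock trees the effective sample size of the
log-likelihood can stay below the 200 gate at desk-scale chain lengths;
such populations are flagged by the gate and kept, their profiles to be
read with caution rather than dropped. On true genealogies the same
chains pass the gate by an order of magnitude.

### Sampler

`skyline_mcmc()` runs a reversible-jump Metropolis sampler (C++ core):

* indicator flips that redraw the incoming knot's log-size from a
  two-scale normal mixture centred on the current interpolated trajectory
  (70% at `flip_sd`, 30% at `3.5 * flip_sd`), with the exact Hastings
  correction — the wide component lets a new knot propose a genuinely
  different size;
* random-walk updates of one active log-size (window `scale_width`);
* moves of an active change point, half to an adjacent event, half to a
  uniformly chosen inactive event (both symmetric);
* a joint shift of all active log-sizes.

Proposal weights and widths were set for mixing on simulated genealogies
(acceptance near 0.5 for the random-walk move; the flip acceptance is
intrinsically low because activating an indicator pays the
$\mathrm{Poisson}(\ln 2)/\binom{n-1}{K}$ prior cost). With the likelihood
disabled the sampler reproduces its Poisson prior on $K$ exactly
(goodness-of-fit in the test suite), which validates the reversible-jump
acceptance ratios. Chains are reproducible given a seed; replicate runs
are combined LogCombiner-style by `combine_traces()` after removing a 10%
burn-in fraction from each.

The desk-scale defaults divide the full-scale protocol ($10^8$ states
sampled every $10^4$) by 100: chains of $10^6$ thinned every 100, two replicate
runs, ESS $\ge 200$ on the log-likelihood, log-prior, $K$ and $N_e(0)$
traces as the convergence gate. The bundled analysis scripts use $10^7$
states for the 85-sequence clock-tree runs, which that harder posterior
needs.

### Diagnostics

`ess()` uses the Tracer-style initial-positive-sequence rule: the
autocorrelation sum is truncated at the first negative estimate; a
constant trace reports $N$ with a warning. `hpd_interval()` is the
Chen–Shao smallest-width window over `round(N * prob)` steps of the sorted
sample, ties broken toward the smaller lower endpoint — on integer samples
(the change-point count) endpoints are integers, and "the 95% HPD of $K$
excludes 0" is the constancy test used throughout.

## Profile similarity

`extract_profile()` summarises a posterior on an even grid from the present
to the root age: per-point median and central 95% posterior bounds of
$N_e$. Two profiles are compared over the shorter history length $L$ at
the 21 times $iL/20$, $i = 0\ldots 20$:

$$\lambda = \sum_{i=0}^{20} \left| \log s_1(iL/20) - \log s_2(iL/20) \right|,$$

with natural logarithms and linear interpolation of the median track on the
natural size scale between flanking profile points (a `log_scale` switch
allows log-scale interpolation as a sensitivity check; default off).
$\lambda$ uses medians only — the CPD bounds are not propagated. It is
symmetric, zero exactly on agreeing tracks, invariant to common rescaling
of both sizes or both time axes, and a pseudometric on constant profiles.
The formula's limits are read as 21 point evaluations ($i = 0\ldots20$
inclusive); had the intent been 20 points, every $\lambda$ would scale by
20/21 — immaterial for the comparative use the statistic gets, but fixed
here as a convention.

## Differentiation and association

`hudson_fst_locus()` implements the finite-sample Hudson estimator
$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$,
$\hat D = p_1(1-p_2) + p_2(1-p_1)$, combined across loci as a ratio of
averages (`fst_pair()`): loci with $\hat D = 0$ in the pooled pair carry no
information and are skipped; no frequency filter is applied; slightly
negative estimates are reported unclamped. `nj_tree()` is Saitou–Nei
neighbour joining with two determinism conventions fixed — Q-criterion ties
break toward the lexicographically smallest label pair (internal nodes
inherit their smallest leaf label), and negative branch lengths are clamped
to zero with the deficit moved to the sister branch, preserving path
lengths. `profile_fst_association()` reports the Spearman correlation over
population pairs and a Mantel permutation p-value (matrix entries are not
independent, so the permutation null is the honest test; the plain
correlation is reported alongside).

## What the synthetic data emulate — and what they do not

`sample_coalescent_tree()` + `simulate_alignment()` emulate the shape of
full mtDNA population samples: ~16.5 kb alignments (default partition sizes 1122 / 4060 /
7574 / 3787, approximate rCRS proportions; the rate calibration fixes
rates, not site counts) of 85 haploid sequences per population, evolved under
TN93 with four discrete-gamma categories and an invariant-site class
(implemented as a zero-rate category with probability `prop_invariant`;
gamma multipliers average one over the variable sites), at the four fixed
per-year rates of the ancient-DNA-calibrated partition scheme. TN93
parameters not fixed by the rate calibration use human-mtDNA-like defaults
(base frequencies 0.31/0.31/0.13/0.25, $\kappa_1 = \kappa_2 = 20$, gamma
shape 0.5); tests depend on them only through self-consistency.
`simulate_snp_counts()` produces Balding–Nichols allele counts with a
controllable differentiation parameter, optionally nested
(region-level $F$, within-region $F_w$) so that between-region pairs are
more differentiated than within-region pairs.

The benchmark demography for detection checks grows linearly ten-fold from
$N_e = 1000$ at 40 ka to $10\,000$ at present — the shape and scale of the
rapid post-45–40 ka growth that human mtDNA skyline profiles show, e.g.
across South Asia. Constant-size controls use $N_e = 5000$.

Deliberately not emulated: recombination (absent in mtDNA), migration and
admixture, selection, ancient (dated-tip) samples, and joint
tree-and-demography uncertainty. Passing tests therefore demonstrate
correctness of the coalescent/substitution machinery and internal
consistency of the inference — not robustness to population structure,
admixture or tree mis-estimation on real data — the standard caveats when
reading single-marker demographic reconstructions.

## Numerical choices

* Interval integrals use the exact linear-segment form
  $\Delta t \,\ln(N_2/N_1)/(N_2-N_1)$, switching to the stable
  $2\Delta t/(N_1+N_2)$ when $|N_2-N_1|$ is below $10^{-9} \max(N_1,N_2)$.
* Coalescent waiting times invert the accumulated intensity analytically
  segment by segment; the constant tail guarantees termination.
* Chains initialise at the constant-size maximum-likelihood fit with no
  active indicators.
* Distance-built trees can carry $O(10^{-12})$ negative node ages
  (floating round-off); event times are clamped at zero, and genuinely
  negative ages are an error.
* TN93 saturation (a non-positive logarithm argument) raises a dedicated
  condition class, distinct from ordinary input errors, and
  `build_clock_tree()` lists the offending pairs.
* The `+I` proportion enters simulation and distance correction but is not
  re-estimated during the skyline MCMC.

## Known limitations

The point-genealogy conditioning (above) is the main one. Others: the
UPGMA clock tree slightly underestimates deep node ages (multiple-hit
saturation under rate heterogeneity is not gamma-corrected in the distance
step); detection power at 40 sequences is genuinely limited — a minority of
simulated ten-fold-expansion genealogies carry too little likelihood
signal for the change-point posterior to exclude constancy, which full
85-sequence datasets largely resolve; and $\lambda$ compares median tracks
only, ignoring the very different uncertainty widths of deep versus recent
profile segments.
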