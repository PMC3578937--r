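---
title: "Sweep detection with demographic calibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep detection with demographic calibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sweepvalley)
```

This vignette documents the models behind `sweepvalley`, the assumptions they
make, the parameters that matter, and the numerical and design choices taken
where the methodology leaves room. It states no empirical results beyond what
the package's tests and `scripts/acceptance.R` compute.

## The scientific setting

A recent selective sweep drags linked neutral variation to fixation and
leaves three local signatures: reduced polymorphism, a site frequency
spectrum (SFS) skewed toward rare and high-frequency derived alleles, and
elevated linkage disequilibrium (LD) within each flank of the selected site
but not across it. All three are mimicked by population bottlenecks, so a
credible sweep test in a derived population — such as European *D.
melanogaster*, founded from sub-Saharan Africa roughly 10–20 thousand years
ago — must calibrate its null distribution under an explicit demographic
model rather than under panmictic neutrality. The package implements the
candidate-region workflow: polarize a re-sequenced alignment against an
outgroup, summarize diversity, scan with an SFS-based composite likelihood
ratio (CLR) and with the LD-based ω statistic, and obtain significance
thresholds from coalescent simulations of a fitted three-population
bottleneck model whose parameters can themselves be re-estimated by ABC.

## Alignment classification and polarization

Every alignment column is classified once (`classify_sites()`): `indel` if
any sequence carries a gap, `masked` if no ingroup base is called,
`fixed_difference` when two population samples are each internally fixed
(full call rate by default) for different bases, otherwise `segregating` or
`monomorphic`. Polarization is single-outgroup parsimony: the allele shared
with the outgroup is ancestral, an allele absent from the outgroup is
derived; columns where the outgroup is gapped, missing, or carries a third
allele stay unpolarized and never enter derived counts. A site can therefore
never be derived-private in both populations. Runs of adjacent fixed-indel
columns are merged into one indel event, since biological indels span
multiple columns but are single mutations.

For SFS work the invariant classes 0 and *n* are kept. Class *n*
(fixed derived) for a focal population is assigned by *joint* polarization:
a focal-monomorphic site counts as fixed derived only when the combined
ingroup dataset is variable at that column and the focal allele is the
derived one. Columns where all ingroup samples agree are class 0 even when
the outgroup differs — those are ordinary divergence sites (about 6% of
columns at this species pair) and carry no sweep information; treating them
as class *n* would swamp the spectrum with ~1,300 spurious high-frequency
"derived" sites per 20-kb region. This mirrors the practice of using the
combined sample to assign the state of monomorphic focal sites.

## Summary statistics

`watterson_theta()` is S/(a₁L); `nucleotide_diversity()` is the unbiased
per-site pairwise heterozygosity n_s/(n_s−1)(1−Σf²) averaged over usable
columns; `tajimas_d()` uses the standard variance constants and is undefined
(NA) at S = 0; `divergence()` is the mean fraction of ingroup alleles
differing from the outgroup. Gap and masked columns are excluded everywhere
and the effective length reduced accordingly, the convention of standard
polymorphism software. Sliding windows default to 1,000 bp sliding by 500 bp;
trailing columns form their own window when at least half a window long and
otherwise merge into the last window, avoiding high-variance tail windows.
`region_summary()` reports both the unweighted mean of per-window statistics
(the usual way regional means are quoted for sliding-window analyses) and
whole-region estimates, since which of the two a published regional value
refers to is often ambiguous.

The clustering of derived alleles is tested by an exact binomial upper tail:
with m derived-private alleles in the region and a segment covering a
fraction f of it, `binomial_cluster_test(m, obs, f)` returns P(X ≥ obs),
X ~ Binomial(m, f); with all m alleles in half the region this is 2^(−m)
(m = 8 gives 0.0039, reported as P = 0.004). The Wilcoxon rank-sum
comparison of regional windows against a chromosome-wide baseline uses
`stats::wilcox.test` (exact for small tie-free samples); completely tied
inputs return p = 1.

## The demographic model and simulator

`demographic_model()` encodes a three-population history: an ancestral
African population of size N_afr_anc expands instantaneously to N_afr_cur at
time T_afr_exp; Europe is founded from Africa at T_exit through a bottleneck
of size N_eur_bot; Asia is founded from Europe at T_asia through its own
bottleneck. There is no migration and no exponential growth. Times are given
in years and converted at 10 generations per year. Defaults are the fitted
X-chromosome posterior modes (sizes ~4.6M/1.6M/0.34M current, bottlenecks
~23k/11k, ancestral ~1.9M; T_exit 15,628 y, T_asia 3,264 y, T_afr_exp
27,643 y).

Two quantities the fit does not pin down are set here and exposed as
parameters:

* **Bottleneck duration.** Founding populations stay at the bottleneck size
  from the founding time until a recovery event halfway to the present
  (duration = founding time / 2), then jump to the current size.
* **Mutation rate.** μ = 1.5 × 10⁻⁹ per bp per generation, a
  divergence-based value: with ~6% divergence to the outgroup species and a
  split on the order of 2 × 10⁷ generations, 0.06 ≈ 2μT. The recombination
  rate default is r = 3.64 × 10⁻⁸ per bp per generation, the estimate for
  this X-linked region.

θ is always fixed by (N, μ), never by an observed number of segregating
sites, which is known to bias null distributions.

`simulate_region()` runs a Hudson-style ancestral recombination graph in
compiled code: lineages carry their ancestral material as intervals tagged
with a descendant bitmask (≤ 64 samples); coalescence within a population at
rate k(k−1)/(4N) per generation, recombination at rate r × breakable span,
and mutation as a third competing exponential event whose position is
uniform on the lineage's material. Material that reaches its sample-wide MRCA
is dropped, so mutations older than the sample MRCA (invisible in any sample
statistic) are never produced. Mutations live at continuous positions
(infinite sites); `sim_positions_bp()` maps them to unique integer base
pairs, resolving collisions to the nearest free position. Correctness is
property-tested against closed forms: E[S] = θa₁, E[π] = θ, the 1/k neutral
SFS, the 2μT excess of between-population divergence after a clean split,
and linearity of E[S] in μ.

## The CLR sweep scan

The sweep model is the classic star-like approximation: at distance d from
the swept site each lineage escapes independently with probability
p_e = 1 − e^(−αd); non-escapees coalesce into a single founder. Given a
normalized background spectrum over classes 0..n, `post_sweep_sfs()` forms
the exact mixture over the binomial number of escapees and a hypergeometric
down-projection of the background onto the founders, with the founder
carrying a derived allele with probability j/m. The two limits are built-in
checks: at αd → ∞ the background is returned unchanged, at d = 0 all mass
sits on classes 0 and n.

`clr_scan()` evaluates, at each of `grid_size` equally spaced candidate
positions (default 1,000), the composite log-likelihood of all site classes
under the sweep model maximized over α, against the neutral background
log-likelihood; the statistic is twice the difference, floored at zero (the
sweep model nests neutrality as escape becomes certain). The published
description of "overlapping windows of variable sizes" is implemented as a
positional grid with every site contributing through the distance model,
which is how the cited method family actually computes the scan.

Numerical choices:

* the background is estimated from neutral replicates of the demographic
  model (`neutral_background()`, pooling counts over replicates with
  invariant-site bookkeeping); zero-mass classes receive a 0.5-site
  pseudocount before normalization so no observed class has probability zero;
* sweep-model log-probabilities are tabulated over 256 log-spaced values of
  the compound parameter s = αd between 10⁻⁶ and 50 (beyond 50 the model is
  the background to < 10⁻¹⁰); the table lookup is exact to the grid
  resolution, which is far below Monte-Carlo noise in the background itself;
* the invariant class-0 bulk is binned into ~40-bp position bins (the model
  varies smoothly in distance), while every polymorphic or fixed-derived site
  enters exactly;
* α is maximized over a log-spaced grid (default 64 points spanning an edge
  escape probability of 10⁻⁴ to 0.9999) with a Brent refinement around the
  grid argmax, tolerance 10⁻⁶ relative;
* the factor 2 in the statistic is a convention; it rescales thresholds and
  data identically, so calibrated inference is unaffected.

## The ω scan

`r2_pair()` is the squared allelic correlation on pairwise-complete
haplotypes. `omega_at_split()` implements the block ratio with combinatorial
pair-count denominators; undefined pairs contribute zero to the sums; a zero
between-block sum with positive within-block LD yields the +Inf sentinel.
`omega_scan()` places the candidate position at each grid center, splits the
sites there, and maximizes ω jointly over the outer borders of the left and
right flanks, which vary independently over a geometric (√2) ladder of
half-widths with the total window constrained to 2,000–10,000 bp and at
least two sites per flank. Ties prefer the smaller window, then the leftmost
center. Singleton sites are excluded by default (minor allele count ≥ 2);
singletons carry no LD information and the choice is exposed as `mac_min`.
For threshold calibration, infinite sentinels are capped at the 99.9th
percentile of the finite null values so a handful of degenerate replicates
cannot dictate the threshold.

With bottlenecked samples of only a few dozen usable sites per region, the
maximized ω null distribution is heavy-tailed: near-two-block configurations
arise by chance in a few percent of neutral replicates, so the calibrated
95th percentile is several-fold above the null median and is sensitive to
the minimum flank occupancy and to singleton handling — both unreported in
the method's published applications. The calibration is internally
consistent (the same scan settings are used on null and observed data), which
is what the hypothesis test requires.

## Threshold calibration

`calibrate_thresholds()` simulates neutral replicates of the full region
under the demographic model, computes each statistic's maximum on the
*European subset* of every replicate, and returns empirical upper quantiles
(default q = 0.95). Replicates where a statistic is undefined (fewer than
four usable sites for ω) contribute its defined minimum of zero. The
replicates sample both the European and African populations so that joint
polarization — including the class-n sites created by fixation along the
European stem — behaves identically in the null and in analyzed data; only
the European statistics enter the null distribution.

## ABC demographic inference

`abc_reject()` is plain rejection ABC: draw the nine parameters from
independent log-uniform priors (defaults span the fitted 95% credibility
intervals widened threefold on each side; draws are constrained to
T_exit > T_asia by joint redraw), simulate a fragment panel per draw
(default 250 × 500 bp in three samples of 12), summarize, standardize each
summary by the simulation pool's median absolute deviation, and accept the
smallest Euclidean distances (default 0.5%). No regression adjustment is
applied: rejection is the conservative baseline and keeps acceptance
diagnostics interpretable. Summaries per population are the mean and
variance of π, the mean and variance of Tajima's D over fragments where it
is defined, mean S, and the number of monomorphic fragments. The
monomorphic-fragment counts are the distinctive addition: fragments with
S = 0 are usually dropped because D is undefined there, yet their frequency
is exactly what a bottleneck null must explain if variation-free regions are
to be attributed to drift. Zero-spread summaries (e.g. African monomorphic
counts, which are almost always zero) are dropped with a warning rather than
poisoning the distance. Posterior location is reported as the Gaussian-KDE
mode (Silverman bandwidth) with 2.5%/97.5% quantiles, sizes in diploid
individuals and times in years.

The summary set is a reconstruction — the original pipeline's exact vector
is not printed in the sources available — so credible intervals should be
read as internally calibrated (parameter-recovery tests below), not as a
replication of any published interval.

## Synthetic data: what it emulates and what it does not

`generate_genome_scan()` emulates a multi-locus scan: independent fragments
under the model, summarized per population. `generate_sweep_region()`
emulates the candidate-region data: neutral haplotypes from the model,
nucleotide states with the ancestral base uniform on A/C/G/T and the derived
base uniform on the remaining three, an outgroup with i.i.d. substitutions
at 6% (so divergence is flat by construction, as observed), and an optional
sweep. Sweep injection uses the same exponential-escape model as the CLR
likelihood: per haplotype, left and right escape breakpoints at
Exponential(α) distances from the sweep position, the enclosed interval
replaced by a shared founder haplotype. This deliberate self-consistency
means detection-power results demonstrate the estimator works when its model
is true; they do not measure robustness to a mis-specified sweep process.
Other simplifications: no sequencing error, no missing data, no mutation-rate
heterogeneity, no migration, and the fixed insertion in the deterministic
fixture is a single column rather than a 20-bp microsatellite expansion.

One geometric property of the exponential-escape model is worth stating
because it shapes expectations: deep loss of polymorphism requires *all* n
lineages swept (probability e^(−nαd), radius ~ ln2/(nα)), while full
recovery requires most lineages escaped (d ≳ 2/α) — radii that differ by a
factor of ~35 at n = 12. A 20-kb region therefore cannot display both a
near-zero 10-kb valley and fully recovered flanks under this model at any α;
the injected sweep produces a relative suppression of central variation
(paired against the same-seed neutral region, central S drops to ~60% on
average at the default α = 2 × 10⁻⁴) rather than a hard valley. The tests
assert the attainable property.

## Problem sizes used by tests and the acceptance script

Calibration and power checks in the test suite use 1,000 null replicates of
the 20,011-bp region (background from 100 replicates), 400 fresh null
replicates, 100 injected-sweep regions, scan settings of 200 grid positions
and 32 α values, 5,000 constant-size simulator replicates, and an ABC pool
of 5,000 simulations of 60 fragments shared across 10 pseudo-observed
recovery runs (the pool reuse is standard for coverage checks and changes
nothing about each run's inference). `scripts/acceptance.R` uses 500
calibration replicates, 200 fresh nulls, 60 sweeps, 3,000 constant-size
simulator replicates, and a 2,000-simulation ABC pool with five recovery
runs. These sizes are the package's own choices
for routine single-CPU runs; all of them are parameters of the exported
functions and can be raised (e.g. the conventional 10,000 calibration
replicates) without code changes.

## Known limitations

* The simulator supports at most 64 sampled haplotypes (descendant bitmasks).
* The CLR uses composite likelihood: sites are treated as independent, so the
  statistic's scale has no χ² interpretation; only calibrated quantiles are
  meaningful.
* Thresholds depend on the unprinted mutation rate and bottleneck-duration
  conventions above; both are exposed as parameters, and threshold magnitudes
  should be re-calibrated rather than transplanted whenever they change.
* No recombination-rate heterogeneity along the region; a single rate is
  used, matching the single published estimate for the region.
* The ω null tail is sensitive to minimum flank occupancy and singleton
  handling (see above).
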