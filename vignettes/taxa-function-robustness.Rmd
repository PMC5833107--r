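---
title: "Quantifying taxa-function robustness of microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying taxa-function robustness of microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxafun)
```

## The question and the model

Microbial communities often keep doing the same things even as their
species composition drifts. taxafun makes that observation quantitative:
it asks how far a community's *aggregate functional profile* moves when its
*taxonomic composition* is perturbed, and summarizes the answer in two
community-specific robustness factors.

The chain of models is:

1. **Taxa-to-function mapping.** A community's functional profile is a
   linear combination of its members' genome contents: the abundance of
   gene family $j$ is $F_j = \sum_i a_i c_{ij}$, where $a_i$ is the
   relative abundance of taxon $i$ (after division by its 16S rRNA copy
   number, which converts read fractions to genome equivalents) and
   $c_{ij}$ its genomic copy number of family $j$. Gene families can be
   rolled up to pathways by splitting each family's abundance evenly
   across the pathways that contain it, which conserves total mapped
   abundance.

2. **Perturbation model.** A perturbation multiplies each non-zero
   abundance by $m_i^{d_i}$, with $m_i$ uniform on $(0, M]$ and
   $d_i \in \{-1, +1\}$ a fair coin, then renormalizes. No taxon is
   created or destroyed: this emulates stochastic abundance fluctuations
   without migration. The expected size of each taxon's change is
   proportional to its abundance. One caveat worth knowing: when
   $d_i = -1$ and $m_i < 1$, the "shrinking" direction actually inflates
   the abundance ($m^{-1} > 1$); the formula is applied literally.

3. **Distances.** The size of a taxonomic perturbation, $t$, is the
   weighted UniFrac distance between original and perturbed composition
   (phylogeny-aware, so swapping abundance between close relatives counts
   less than between distant ones). The functional shift, $f$, is the
   cosine dissimilarity between the two functional profiles — invariant
   to overall scale, which is why the choice of profile normalization
   does not propagate into robustness values.

4. **Response curve.** The relationship between the two is modeled as a
   power law,
   $$f = \frac{1}{e^{a}}\, t^{\, b},$$
   log-transformed to $\ln f = -a + b \ln t$ and fitted by ordinary least
   squares. The intercept gives the **attenuation** $a$: the larger it
   is, the smaller the functional shift at any given taxonomic distance
   (a more robust community). The slope gives the **buffering** $b$: the
   larger it is, the more strongly small perturbations are suppressed
   relative to large ones.

## The simulation sweep and its defaults

`generate_perturbation_set()` perturbs a community at 45 maximum
magnitudes $M$ evenly spaced from 1.2 to 10 inclusive, 100 perturbations
each — 4500 per community. The sweep oversamples large distances, so
before fitting, `window_subsample()` splits the observed range of
$\ln t$ into 50 non-overlapping windows and keeps at most 50 records per
window. Records with $t = 0$ or $f = 0$ cannot enter a log-log fit; they
are dropped beforehand and counted (`n_dropped`). A community whose
shifts are all below $10^{-12}$ — as happens when every genome is
functionally identical — is flagged unfittable rather than fitted.

All randomness is seeded explicitly. The sweep draws its uniforms and
signs as a single fixed-order block under the seed, so a perturbation set
is a pure function of (profile, seed, grid) and does not depend on
iteration order.

## Summaries across communities

Attenuation and buffering distributions are skewed, so group locations
are summarized by the Hodges–Lehmann **pseudomedian** (the median of all
pairwise Walsh averages $(x_i + x_j)/2$), with a 95% interval obtained by
inverting the one-sample Wilcoxon signed-rank statistic under its normal
approximation. For $n = 1$ the interval degenerates to the point.

Per-function robustness replaces the cosine shift by the relative change
$|b_j - a_j| / a_j$ of a single function, fitted through the same
window-subsample + log-log pipeline. To ask *where* a function is most
robust, medians of its attenuation across environments are compared with
Mood's median test (counts above vs. not-above the pooled grand median;
ties count as "not above"; chi-square without continuity correction). A
set of environments qualifies as "most robust" when every member is
significantly above every non-member and no two members differ. The
definition constrains the answer but not the search; we scan prefixes of
the environments ordered by decreasing median and return the smallest
qualifying prefix, which is the natural greedy reading and returns the
full set when all environments are exchangeable.

## Gene-distribution features

Five descriptors of how functions are spread across member genomes:

* **Average functional redundancy** — per function, the Shannon evenness
  of contributions $s_i c_i$ from the species that encode it; averaged
  over functions weighted by functional-profile share. The contribution
  products are normalized to proportions before the entropy; the printed
  products themselves are only a valid Shannon argument when they happen
  to sum to 1, so the normalized "evenness" reading is the default and a
  `literal` mode computes the raw form for comparability.
* **Average functional similarity** — mean pairwise cosine similarity of
  genome-content vectors over present species.
* **Average genome size** and **genome-size variability** — unweighted
  mean of per-species total content, and its coefficient of variation
  (population SD over mean; with a single present species the CV is
  undefined and returned as `NA` with a warning).
* **Unique-function abundance** — profile share of functions encoded by
  exactly one present species.

"Present" means non-zero abundance in the (possibly rarefied) profile.
GDFs use species abundances as given, without 16S correction — they
describe the community as observed, whereas the mapping's correction is a
sequencing artifact fix; both behaviors are arguments if the other
convention is wanted. When a pathway hierarchy is supplied, the content
matrix is collapsed to pathway level first (the even split is linear, so
this equals summarizing every profile), keeping features at the same
functional level as fitted curves. `gdf_pca()` z-scores the features and
reports scores, loadings, and explained-variance fractions.

## Robustness from paired real communities

Simulated multipliers need genome content; with paired real communities
(e.g. two same-subsite metagenomes) robustness can be estimated without
it. `mix_communities()` forms convex combinations of both taxonomic and
functional profiles at fraction $m$; `find_mixing_fraction()` binary
searches $m$ so the mixed community sits at a chosen weighted UniFrac
distance from the original (tolerance $10^{-9}$); and
`mixing_based_curve()` does this along a grid of target distances
(default 0.01–0.10 in steps of 0.01) and fits the standard response
curve to the resulting records. Mixed profiles are not renormalized:
convexity preserves sum-to-one exactly. The binary search relies on the
distance being non-decreasing in $m$; this monotonicity is verified as a
package property, and if a bracket violation ever occurs the search
falls back to a fine grid scan with a warning. Targets beyond the
pair's $m = 1$ distance are unreachable and raise an error (or are
dropped from a grid with a warning).

## The synthetic-data generator

Testing every stage without reference downloads requires synthetic
inputs that span the regimes that matter. `generate_scenario()` builds:

* a random rooted bifurcating tree with exponential branch lengths;
* a genome-content matrix with a single **redundancy knob**
  $\rho \in [0, 1]$: one shared single-copy marker family, a core of
  $\lfloor \rho\,(n_{\mathrm{fun}} - 1) \rfloor$ families present in
  every genome with identical copy numbers (the shared core genome), and
  the remaining accessory families assigned to single taxa round-robin.
  $\rho = 1$ gives identical genomes (functional shifts vanish);
  $\rho = 0$ gives disjoint repertoires over the marker (unique-function
  load near 1). Copy numbers are drawn from {1, 2, 3} and 16S copies
  from {1, ..., 5} — arbitrary small ranges whose only job is to
  exercise the normalization code;
* lognormal$(0, \sigma)$ relative abundances ($\sigma = 1$ by default),
  the standard long-tailed shape of community profiles.

Defaults are 40 taxa and 200 gene families per community — richness at
the scale of a modest 16S profile, large enough that perturbations move
dozens of lineages. What the generator does **not** emulate: real
phylogenetic signal in gene content (relatives sharing accessory genes),
realistic pathway structure, compositional sequencing noise, or the
taxon inventories of any real habitat. Passing tests therefore
demonstrate the machinery's correctness and the direction of the
redundancy–robustness association, not quantitative agreement with any
real ecosystem.

## Numerical choices and edge cases

* Both raw and normalized weighted UniFrac are available; the default is
  the normalized variant (bounded in [0, 1], comparable across trees).
  The implementation is a sparse branch-by-leaf incidence product,
  verified against a naive per-branch oracle on every rooted binary
  topology with up to 5 leaves and against an independent reference
  implementation.
* Profiles are aligned on the union of identifiers with implicit zeros;
  mismatched identifier sets are not an error, but a profile taxon
  missing from the tree or the content matrix is, and the offending ids
  are named.
* Rarefaction is sampling without replacement (multivariate
  hypergeometric), the standard reading of "rarefied to a depth"; it is
  single-draw per seed.
* Chloroplast filtering is a case-insensitive substring match on the
  lineage string, label configurable.
* Weighted OTU subsampling draws successively with renormalized weights.
* Uniform multipliers on $(0, M]$ are realized as $M(1 - U)$,
  $U \sim [0, 1)$, so 0 is excluded and $M$ attainable.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data: communities of 10–50 taxa
with 60–200 gene families; full 4500-perturbation sweeps where the
default grid itself is under test, reduced grids (5–15 magnitudes,
10–40 perturbations each) where only correctness of the chain matters;
a 30-community redundancy sweep at $\rho \in \{0.2, 0.5, 0.9\}$ for the
redundancy–attenuation association; 100 noisy replicates for parameter
recovery; and 200 planted simulations for the most-robust-environment
search. These sizes make the whole suite run in well under a minute
while keeping every statistical check comfortably powered.

## Limitations

* The linear mapping ignores gene regulation, expression, and
  interactions; it measures *genomic potential* only.
* The power law is assumed, not selected; alternative response families
  are out of scope.
* Perturbations exclude migration and invasion by construction.
* The most-robust-environment procedure applies no multiple-testing
  correction across functions beyond its configurable $\alpha$.
* Mixing-based estimates inherit whatever normalization the supplied
  functional profiles carry; only scale-invariant comparisons are safe.
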