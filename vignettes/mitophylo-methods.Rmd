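---
title: "Methods: single-locus mtDNA phylogeography with mitophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-locus mtDNA phylogeography with mitophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylo)
```

## What the package models

`mitophylo` analyses a single aligned mitochondrial fragment — the kind of
marker used to resolve maternal lineages in structured mammal populations,
such as the wild (W) versus domestic-associated (D) ND5 lineages of
European cats. mtDNA is treated throughout as haploid, maternally
inherited and non-recombining, so "effective population size" always means
the female effective size, and one locus means one shared genealogy: every
statistic downstream inherits the large evolutionary variance of that
single tree, which is why inference here is comparative (scenarios,
permutations, simulations) rather than parametric.

The pipeline mirrors the standard workflow of a continental mtDNA survey:

1. collapse aligned sequences into haplotypes and compute diversity,
2. build a distance-based tree and date its splits under a strict clock,
3. draw a median-joining haplotype network,
4. quantify spatial structure with AMOVA / SAMOVA,
5. test for demographic expansion (Tajima's D, Fu & Li, mismatch),
6. compare explicit demographic scenarios by ABC.

## Haplotypes and diversity

Haplotypes are distinct sequence strings; sequences containing `N`
collapse only on exact string identity (no wildcard matching), which keeps
collapsing deterministic. Pairwise comparisons skip sites where either
base is uncalled (`N`/gap) — pairwise deletion, the common default in
population-genetic software. Haplotype diversity uses Nei's unbiased
estimator with his sampling variance; nucleotide diversity is the mean
proportion of differing sites over all pairs with Nei's total variance.
Diversity tables report per-site values; a `pi_x100` column gives the
100-fold scaled display form some surveys print, because per-site
proportions at a 669-bp fragment are otherwise awkward to read. Both
segregating (`S`) and parsimony-informative (`PI`) sites are counted over
unambiguous states only.

## Distances, trees and strict-clock dating

The workhorse distance is Kimura's two-parameter closed form
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, with an optional
gamma-rate correction (shape configurable). Saturated pairs (non-positive
log argument) are flagged, never silently clamped. TN93 — of which HKY is
a special case — and JC69 are available through ape for comparison;
per-codon partitioned model fitting is deliberately out of scope: at the
shallow divergences of an intraspecific fragment the distances differ
negligibly and a single substitution model keeps the dating transparent.

Trees are neighbor-joining with site-bootstrap support. Node ages come
from the strict molecular clock: the age of a split is
$t = \bar d / (2r)$, with $\bar d$ the mean between-subclade K80 distance
and $r$ the substitution rate per site per year (default
$2.28\times10^{-8}$, a felid ND5 estimate). Confidence intervals are
percentile intervals over site-bootstrap replicates. This replaces a full
Bayesian MCMC: it estimates the same quantity (node age under a strict
clock) at desk scale, but the bootstrap CI is an analog of, not a
replication of, a posterior HPD — no equivalence is claimed. Ages are
clamped to be monotone (a parent at least as old as its children) so the
dated tree is ultrametric. `calibrate_root()` rescales all ages so the
root hits the midpoint of a calibration interval (e.g. 173–230 kya for
the deepest wild/domestic split), preserving relative node depths exactly
and reporting the implied effective rate.

## Median-joining networks

`mj_network()` follows the median-joining construction: an
epsilon-relaxed minimum spanning network (an edge is kept when its cost is
within epsilon of the bottleneck cost between its endpoints — at
epsilon = 0 this is the strict MSN, which provably contains every minimum
spanning tree), plus iterative insertion of quasi-medians (site-wise
majority consensus) for mutually connected triplets. Substitutions are
cost-weighted: transitions 1, transversions 3 by default, the weighting
conventional for mtDNA. Two numerical guards keep the construction
tractable: a candidate median is only added when it connects its triplet
more cheaply than direct edges do (a Steiner-point gain — without this the
construction explodes combinatorially at the large epsilon values used in
practice), and new medians per iteration are capped (default 1000).
Median vectors of degree ≤ 2 are pruned at the end; removing such a node
can never disconnect the network because the weighted Hamming cost obeys
the triangle inequality. Node frequencies and carrier categories are
attached for plotting but never affect topology. Diagnostic-site lineage
assignment (`assign_lineage()`) takes the site panel as an *input*: panels
of diagnostic positions are survey-specific and the synthetic generator
records its own panel as ground truth.

## AMOVA and SAMOVA

AMOVA follows the squared-distance decomposition of molecular variance;
the inter-haplotype distance is the unweighted count of nucleotide
differences (pairwise deletion), squared in the sums of squares — the
common default when no distance is specified. All sums are computed from
population-level cross-sums ($S = F D^2 F^\top$ with $F$ the
population-by-haplotype count matrix), which makes evaluating one grouping
$O(P^2)$ and is what makes the SAMOVA search fast. Permutation schemes
are the conventional ones: individuals among populations for
$\Phi_{ST}$, individuals within groups for $\Phi_{SC}$, whole populations
among groups for $F_{CT}$; p-values use +1 smoothing. Negative variance
components are reported with a flag, not truncated.

SAMOVA searches for the K-group partition of populations maximizing
$F_{CT}$ by simulated annealing: Voronoi initialization around K random
seed populations, proposals that move one population to a group containing
one of its Delaunay neighbors (with a 10% chance of a fully random move,
so contiguity is encouraged, not enforced; a flag makes it strict),
geometric cooling calibrated from a pilot sample of move deltas so that
roughly 80% of adverse moves are initially accepted, and a greedy
single-move polish after each restart. The Delaunay graph is computed by
the direct empty-circumcircle test — adequate at the tens of populations
of a survey — with a nearest-neighbor fallback that guarantees
connectivity. K selection takes the largest significant $F_{CT}$, ties
broken toward smaller K. The annealing effort (restarts × steps) is
configurable; the original method's 10,000 restarts are far beyond what
the search needs on survey-sized problems — the test suite verifies the
annealer attains the exhaustive-search optimum on ≤ 12 populations.

## Neutrality tests and mismatch distributions

Tajima's D and Fu & Li's statistics are computed from the standard
constants (the starred, outgroup-free variants by default; D and F from
derived singletons when an outgroup is supplied — both are reported
because which variant a survey used is often ambiguous). Significance
comes from neutral constant-size coalescent simulation conditioned on the
sample size and on theta (Watterson's estimate unless given), not from
approximation tables; a precomputed null table can be shared across
datasets, which the calibration tests exploit. Mismatch distributions
are summarized by Harpending's raggedness index computed on relative
frequencies with a trailing empty class; no parametric expansion-curve
fit is attempted — the index is the quantitative stand-in for reading the
plot's shape.

## The coalescent simulator and ABC

`simulate_coalescent()` is a Hudson-style single-locus simulator:
exponential coalescence within demes of constant haploid size, lineage
movement at backward-time merge and admixture-pulse events, finite-site
K80 mutations with gamma site rates (shape 4 by default) laid on
branches. A vectorized fast path handles the single panmictic deme case.
"Gene flow" origins of a cluster are modelled as a single admixture
pulse — a choice made once and encoded in the built-in scenario library —
rather than continuous migration, which would add a rate parameter the
single locus cannot resolve.

The built-in libraries encode four wild-lineage scenarios over four
geographic clusters (sequential vs simultaneous splits, with or without
an admixture origin of the Iberian cluster) and three discordant-lineage
scenarios over three clusters (recent simultaneous split; sequential;
sequential with longer time priors). Priors are uniform — sizes up to
$10^5$, split times up to $6\times10^4$ generations (generation time 2
years) — spanning the plausible range for late-Pleistocene carnivore
divergences; published surveys of this design do not print their prior
bounds, so these are package defaults, configurable per scenario.

ABC summary statistics are fixed and documented rather than mimicking any
particular tool's internal menu: per deme, haplotype count, segregating
sites, haplotype diversity, nucleotide diversity, Tajima's D and singleton
count; per deme pair, $\Phi_{ST}$ and mean between-deme differences.
Undefined entries (e.g. Tajima's D without variation) are 0 by
definition, keeping vectors comparable. Statistics are standardized by
the pooled median absolute deviation; the closest 1% (configurable) by
Euclidean distance are retained. Scenario choice fits a multinomial
logistic regression of the scenario label on the retained statistics
evaluated at the observed point; parameter posteriors use local-linear
regression with Epanechnikov weights on logit-transformed parameters
(relative to the prior bounds, so adjusted draws always respect them),
reported as weighted medians with 5–95% quantiles in generations and
years. One numerical choice matters here: before either regression the
centred statistics are projected onto their leading principal components
(≥ 95% variance, at most 8, at most retained/10). With a few hundred
retained simulations and ~30 statistics, the unreduced regressions
overfit badly — in testing, the unreduced adjustment saturated parameter
posteriors at the prior bounds; the projection restores well-posedness
while preserving evaluation at the observed point (which maps to the
origin). Posterior predictive checks simulate from posterior draws and
report two-sided tail probabilities per statistic with Bonferroni flags.

## The synthetic-data generator

`generate_dataset()` emulates the structure of a continental two-lineage
survey with known ground truth: 430 wild, 213 domestic, 72 admixed
samples (the composition of the motivating survey), a 669-bp fragment, 12
sub-regions in 6 macro-regions, W-lineage geography simulated under a
4-cluster simultaneous-split scenario (splits at 32,100 generations ≈
64,200 years; cluster sizes 5,000–25,000, ancestor 50,000 — values chosen
once to land in the realistic range of tens of haplotypes among ~700
samples), a D lineage simulated as one panmictic deme of 60,000, and
mito-nuclear discordance: exactly `round(0.414 × n_wild)` nuclear-wild
samples carry D-lineage mtDNA, and admixed samples carry it with
probability 61/72. The two lineage root sequences differ at a
diagnostic-site panel (7 sites, held mutation-free within lineages so the
inter-lineage Hamming distance can never fall below the panel size) plus
additional clock-expected substitutions for a 197,500-year root-sequence
divergence. Note that the tip-level age of the deepest split exceeds this
parameter: each lineage's internal coalescent depth (driven by the deme
sizes) adds to tip-to-tip distances, exactly as it would in real data —
the clock-dated root of the haplotype tree is the haplotype TMRCA, not
the root-sequence divergence.
Coordinates are jittered around sub-region centroids (SD 0.3°) because
SAMOVA needs distinct per-population coordinates.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and alignment artifacts,
recombination-free but heteroplasmic individuals, uneven opportunistic
sampling within sub-regions, site-specific selective constraint beyond
gamma rate variation, and any nuclear signal (class labels are taken as
given, as in the motivating design where they come from prior
microsatellite assignment).

## Reproducibility and problem sizes

Every stochastic routine takes a seed; the pipeline derives per-stage
seeds from one global seed through a fixed affine map, so disabling one
stage never shifts another stage's randomness, and identical
configuration plus seed reproduces every output file hash. Default
problem sizes in the shipped tests and acceptance script are chosen at
desk scale: e.g. $10^4$ replicates for closed-form simulator checks, 1000
datasets for neutrality calibration, $10^4$ simulations per scenario with
1–2% retention for ABC self-consistency, 100 seeded runs against
exhaustive search for the annealer. Scenario libraries and annealing
effort scale up by configuration when more compute is available.

## Known limitations

* One locus, one genealogy: scenario posteriors and parameter intervals
  are wide by nature; the ABC machinery quantifies, not eliminates, this.
* Bootstrap CIs on clock ages are sampling intervals under the strict
  clock; rate misspecification shifts all ages multiplicatively (which is
  exactly what `calibrate_root()` absorbs).
* The median-joining Steiner-gain pruning can omit medians that the
  unpruned construction would add for very large epsilon; observed-node
  connectivity and MST containment are unaffected (and tested).
* AMOVA assumes the squared-difference distance; other distances can be
  supplied but are not defaults.
* The exhaustive SAMOVA reference is limited to ≤ 13 populations by
  combinatorics; beyond that only the annealer is available.
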