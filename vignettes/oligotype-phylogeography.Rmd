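---
title: "Oligotype-based population genetics and phylogeography: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligotype-based population genetics and phylogeography: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligophylo)
```

## The problem this package addresses

Community-level marker-gene surveys (16S rRNA metabarcoding) resolve
bacterial diversity to operational taxonomic units (OTUs, ~97% identity),
a grain too coarse for population-level questions: whether an oceanic
front acts as a dispersal barrier, whether a current corridor homogenizes
populations, and which ecological processes generate the turnover of
within-taxon variants across sites. `oligophylo` treats the sub-OTU
sequence variants of one OTU — *oligotypes*, resolved by minimum-entropy
decomposition of positionally homologous reads — as haplotypes, and then
applies the standard phylogeographic toolbox of macro-organism population
genetics to their per-site frequencies: diversity indices, AMOVA fixation
indices with permutation tests, Hudson's nearest-neighbour statistic,
median-joining networks, ecological process partitioning, and matrix
regression on geographic and environmental distances.

Every stage is exercised end-to-end on a bundled structured-coalescent
simulator with known migration truth, so the statistical machinery is
testable without any sequencing data.

## The simulator and its conventions

`scenario_config()` describes a deme layout; the default emulates a
four-site, three-province Southern-Ocean-style design (one Antarctic site,
two Patagonian sites, one Kerguelen site; host sample sizes 31/15/10/14; a
370 bp V4–V5-length amplicon; 0.1% per-base sequencing error).
`scenario_barrier()` adds a hard dispersal barrier between two province
groups and an eastward-biased within-group corridor, emulating a polar
front and a circumpolar current.

**Time scale.** `simulate_genealogy()` runs the structured coalescent
backward in time with, in deme $i$ holding $n_i$ lineages, total
coalescence rate $n_i(n_i-1)/\theta_i$ and per-lineage migration rate
$M_{ij}/2$ from $i$ to $j$ (backward rates: the probability flow of
ancestry). A pair of lineages in one deme therefore coalesces at rate
$2/\theta$, giving an expected pairwise time of $\theta/2$.
`drop_mutations()` then drops $\mathrm{Poisson}(\tfrac{\theta}{2}\,t)$
mutations on a branch of length $t$ under a finite-sites,
uniform-substitution model. Under this convention two tips joined at
depth $t$ differ at $\mathrm{Poisson}(\theta t)$ sites, and at the
package default $\theta = 2$ the expected mean pairwise difference of a
panmictic deme equals $\theta$ — the regime in which the amplicon-scale
diversity printed by the worked examples (mean pairwise differences of
roughly 0.1–2 over 370 bp per site after decomposition) is realistic.
Finite sites (rather than infinite sites) keeps alignments fixed-length
and lets the entropy decomposition encounter recurrent-hit columns, which
is what real amplicon data presents.

**Hard barriers and vicariance.** A coalescent over demes with *no*
migration path between two groups can never produce a single connected
genealogy: within-group events keep occurring forever while the groups
remain mutually unreachable. The simulator therefore detects
migration-graph components, coalesces each component internally, and
joins the component ancestors at a fixed `isolation_divergence` above the
deepest root (default 5 coalescent units — deep enough that cross-barrier
differentiation approaches fixation without saturating every site of a
370 bp amplicon at $\theta = 2$). This is an explicit vicariance model:
the divergence across a hard barrier is a parameter, not an estimate.
Setting `isolation_divergence = NULL` restores a strict error on
unconnectable histories. One consequence worth knowing: vicariant
divergence inflates phylogenetic turnover between cross-barrier
communities, which the null-model framework below reads as "variable
selection" — an identifiability limit of that framework, not a bug in
either component.

**Read sampling.** Reads are drawn per deme multinomially from the
lineage haplotype frequencies, then corrupted site-wise at the configured
error rate (substitutions only; no indels, so positional homology is
preserved by construction). Read headers follow the `SAMPLE_READN`
labelling dialect. The simulator does not model recombination, selection,
demographic change, or quality scores.

**What passing tests do and do not show.** The generator produces
neutral, panmictic-within-deme populations with iid sequencing error.
Real gut-tissue amplicon data adds chimeras, contamination, PCR bias,
within-host population structure and selection — none of which are
emulated. Green tests certify the statistical machinery (formulas, nulls,
calibration), not robustness to those artefacts.

## Minimum-entropy decomposition

`column_entropy()` computes per-position Shannon entropy
$H_p = -\sum_b f_b \log_2 f_b$ over the five residue states A, C, G, T
and gap; `N` is missing data, excluded from the denominator (an all-`N`
column has entropy 0, with a warning). `med_decompose()` recursively
splits a node at its highest-entropy position (ties toward the lowest
index; `d` positions per split, default 1) while that entropy exceeds the
threshold `m`, then filters terminal nodes below the minimum substantive
abundance.

Parameter choices:

* `m = 0.0965` bits by default — the conventional decomposition default.
  The dynamic threshold rule used by external oligotyping software is not
  re-derived here; `m` is exposed and the monotonicity property
  (raising `m` never increases the number of oligotypes) is tested.
* `min_abundance = 0.01` (1% of the OTU's reads; an absolute count when
  ≥ 1). A published convention of 2% exists but is internally
  inconsistent with decomposition outputs of ~100 oligotypes per OTU
  (100 × 2% > 100%), so the default here is deliberately lower and
  configurable; per-OTU read counts in the tens of thousands make 1%
  still a strong noise filter.
* Noise reads are reassigned to the surviving oligotype at minimal
  Hamming distance from the read (default) or discarded
  (`policy = "discard"`). Reassignment ties resolve toward the more
  abundant oligotype.
* A read with `N` at a split position follows the majority child.
* The representative sequence of an oligotype is its most abundant
  unique read sequence, ties broken lexicographically — determinism over
  faithfulness to any particular published implementation.

With zero sequencing error and `min_abundance = 1` the decomposition is
exactly sequence deduplication; this identifiability property is tested,
as is recovery of every ≥ 5%-frequency true haplotype at 0.1% error and
depth $10^4$.

## Population-genetic statistics

All statistics are frequency-weighted: they are computed from
oligotype × site counts and Hamming distances between representatives,
never by materializing individual reads, so $N \approx 10^5$ costs the
same as $N = 10$. Equality with brute-force per-sequence expansions is
asserted on random instances.

* Diversity per site: $k$ (oligotypes), $S$ (polymorphic positions among
  the oligotypes present), $H = \frac{n}{n-1}(1 - \sum p_i^2)$,
  $\Pi = \frac{n}{n-1} \sum_{i<j} 2 p_i p_j d_{ij}$ (mean pairwise
  differences, in differences per amplicon, not per site — the scale on
  which values of 0.1–2 over 370 bp are the expected magnitude).
  `rarefied_indices()` repeats every index on `B` multivariate
  hypergeometric subsamples at the smallest site's depth (the composite
  bootstrap; default `B = 1000`), reporting means and 2.5/97.5
  percentiles.
* `amova_structure()` runs a two-level AMOVA on squared distances per
  site pair — identity metric for $F_{st}$, Hamming for $\Phi_{st}$ —
  with negative variance components truncated to 0 (the standard
  convention). Note that the sample-size corrections make the estimator
  only asymptotically invariant to scaling all counts; the tests check
  convergence under scaling rather than exact invariance.
* Permutation nulls reshuffle the 2 × k count table with fixed margins
  (Patefield's algorithm, i.e. the multivariate hypergeometric law of a
  label permutation), never expanded reads. P-values use the add-one
  estimator $p = (\#\{null \ge obs\} + 1)/(P+1)$, so a reported 0.001 at
  $P = 999$ means "below resolution", never exactly zero.
* `snn_statistic()` is Hudson's nearest-neighbour statistic with ties
  shared proportionally and identical copies counting as neighbours at
  distance zero, again computed from counts.
* `nm_island()` converts $F_{st}$ to effective migrants per generation
  under the haploid island model, $Nm = (1-F_{st})/(2F_{st})$ — a
  deliberately simple, clearly labelled surrogate for coalescent
  likelihood estimation of directional gene flow, which is out of scope.
  Its only asserted property is monotonicity in simulated migration.

## Median-joining networks

`median_joining()` iterates: build the $\varepsilon$-relaxed minimum
spanning network (with $\varepsilon = 0$, exactly the union of all
minimum spanning trees); for every connected triplet compute the
position-wise majority median (a three-way tie keeps the state of the
lexicographically first sequence); add the cost-reducing median that most
lowers the total MST cost; repeat to a fixed point; prune inferred
medians of degree ≤ 2. The algorithm asserts at every iteration that
adding a median never raised the connection cost. Nodes with zero weight
are treated as unsampled medians, which makes the procedure idempotent on
its own output. Node weights follow the frequency-sum convention: counts
are normalized within each site and summed across sites, so circle areas
are comparable between deeply and shallowly sequenced sites.

## Ecological process partitioning

Communities are individual hosts (`pooled = FALSE`, pseudo-hosts drawn
uniformly from each site's reads) or site pools; both modes exist because
per-sample turnover and site-pooled turnover answer slightly different
questions, and the right grain for gut-tissue data is genuinely open.
The phylogeny is a neighbour-joining tree on oligotype Hamming distances
(negative branches clamped to 0) — a desk-scale substitute for
likelihood tree inference, which is deliberately out of scope.

$\beta MNTD$ is abundance-weighted mean nearest-taxon distance;
$\beta NTI$ its z-score against `reps = 999` tip-label shuffles on the
fixed tree (a degenerate null with zero variance yields $\beta NTI = 0$,
the drift-compatible reading, with a warning). $RC_{Bray}$ draws each
null community's observed richness with probability proportional to
occupancy, seeds one individual per drawn taxon, distributes the
remaining abundance multinomially by metacommunity relative abundance,
and scales $\Pr(BC_{null} < BC_{obs})$ to $[-1, 1]$. Classification uses
the conventional thresholds: $\beta NTI < -2$ homogeneous selection,
$> 2$ variable selection, otherwise $RC < -0.95$ homogenizing dispersal,
$> 0.95$ dispersal limitation (+ drift), else ecological drift.
Calibration is tested: self-null $\beta NTI$ has mean ≈ 0 and sd ≈ 1, and
neutral simulations classify predominantly into the stochastic classes.

## Isolation by distance and environment

Geographic distances are haversine great circles ($R = 6371.0088$ km).
Following the workflow this package standardizes, the geographic
*distance matrix* is then Hellinger-transformed row-wise — an unusual
step (the transform was designed for community tables), kept as the
literal convention but disableable via `hellinger_geo = FALSE`; the
transformed matrix is re-symmetrized by averaging. The environmental
distance is the absolute difference of PC1 scores of the
column-standardized site × variable table (constant variables dropped
with a warning; PC1 variance explained is reported). The response is
Bray–Curtis dissimilarity of oligotype composition. Predictors are not
internally standardized — coefficients stay on the supplied scales — and
site-level predictor matrices are expanded to sample pairs by site
membership (within-site pairs at distance 0) when the response is
per-host.

`mmrr()` fits OLS on the vectorized lower triangles and obtains
per-coefficient and model-level p-values by jointly permuting rows and
columns of the response (`perms = 9999` by default, giving p-value
resolution of 1/10,000 with the add-one estimator). Collinear predictors
abort with the offending pair named. With a single predictor the fit
reduces exactly to OLS on the unfolded vectors, which is tested.

## Reproducibility machinery

Every stochastic function takes a `seed` argument applied to a local RNG
scope (the caller's stream is never perturbed); `run_pipeline()` fans a
single master seed out to per-stage seeds with a counter-based scheme
(`derive_seed()`), so any stage can be re-run in isolation and full runs
are byte-identical. The manifest records package and R versions,
parameters, the seed, per-stage seeds and input digests — and no
timestamps, precisely so that repeated runs are byte-identical. Tables
are UTF-8 TSVs with floats rounded to 4 decimals.

## Problem sizes used in the test-suite

The suite favours many small seeded replicates over few large ones: the
coalescent checks use 500–2000 two-lineage replicates against closed
forms; oracle equivalence uses 100 random instances with $N \le 50$;
type-I calibration uses 200 simulated datasets with 99 permutations each;
barrier recovery uses 100 replicate datasets at the default host sample
sizes; the noisy identifiability check uses one seeded dataset at depth
$10^4$; null-model calibration uses 200 self-null z-scores at 199
randomizations. These sizes put every Monte-Carlo tolerance at 3–4
standard errors of its estimate.

## Known limitations

* The island-model $Nm$ is an equilibrium summary; it cannot resolve
  directionality, unlike coalescent likelihood methods.
* $\beta NTI$ reads deep vicariant divergence as "variable selection"
  (see above); interpret the partition jointly with the fixation indices.
* The AMOVA estimator is not exactly invariant under scaling all counts;
  comparisons between OTUs with very different sequencing depths inherit
  the usual small-sample caveats.
* The entropy threshold `m` is a constant default, not the dynamically
  computed value of external oligotyping software; for published-data
  comparability set `m` explicitly.
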