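# oligophylo

Population-level phylogeography for bacteria from marker-gene amplicons.

Community 16S rRNA surveys stop at the OTU (~97% identity) — too coarse
to ask the questions population geneticists ask of macro-organisms: does
an oceanic front block dispersal? does a current corridor homogenize
populations? which ecological processes drive the turnover of
within-taxon variants among sites? `oligophylo` resolves the
*microdiversity* inside one OTU — oligotypes, obtained by
minimum-entropy decomposition of positionally homologous reads — and
treats oligotype frequencies per site as haplotype frequencies in a
classical phylogeographic analysis. It is aimed at microbial ecologists
with aligned per-OTU read sets in hand (or none at all: a bundled
structured-coalescent simulator generates read sets with known migration
truth, so the whole pipeline runs and is tested without external data).

## What it computes

* **Oligotyping** — recursive partition of reads at their
  maximal-entropy columns, `H_p = -Σ_b f_b log2 f_b` over A/C/G/T/gap,
  until residual entropy ≤ `m`; low-abundance nodes reassigned to the
  nearest surviving oligotype by Hamming distance.
* **Diversity** — per site: N, k, segregating sites S, oligotype
  diversity `H = n/(n-1) (1 - Σ p_i²)` and mean pairwise differences
  `Π = n/(n-1) Σ_{i<j} 2 p_i p_j d_ij`, with composite bootstrap
  rarefaction to the smallest site (means and 95% intervals).
* **Structure** — pairwise AMOVA `F_st` (identity metric) and `Φ_st`
  (Hamming metric), `Φ = σ_a² / (σ_a² + σ_w²)` with negative components
  truncated at 0; permutation p-values from margin-preserving count
  reshuffles; Hudson's nearest-neighbour `Snn`; island-model surrogate
  `Nm = (1 - F_st) / (2 F_st)`.
* **Networks** — median-joining haplotype networks (ε-relaxed minimum
  spanning network + majority-median Steiner points), node weights as
  per-site frequencies summed across sites.
* **Assembly processes** — abundance-weighted βMNTD, its tip-shuffle
  z-score βNTI, abundance-weighted Raup–Crick `RC_Bray`, classified into
  homogeneous/variable selection, homogenizing dispersal, dispersal
  limitation and ecological drift at the ±2 / ±0.95 thresholds.
* **IBD vs IBE** — multiple matrix regression with randomization of a
  Bray–Curtis response on great-circle geographic distance
  (Hellinger-transformed) and environmental PC1 distance.

## Worked example

Simulate the four-site barrier scenario (two Patagonian sites, one
Antarctic, one Kerguelen; hard barrier between the {KGI, KER} and
{PAT1, PAT2} groups), decompose, and test structure:

```r
library(oligophylo)

cfg    <- scenario_barrier(seed = 7)
gen    <- simulate_genealogy(cfg, seed = 7)
truth  <- drop_mutations(gen, theta = 2, seq_length = 370, seed = 8)
reads  <- sample_reads(truth, cfg, seed = 9)

catalog <- med_decompose(reads, min_abundance = 1)
counts  <- build_count_matrix(catalog)
seqs    <- catalog_seqs(catalog)

diversity_indices(counts, seqs)
#>   site      n     k     s     h    pi
#> 1 KER      14     9    13 0.901  3.56
#> 2 KGI      31    15    22 0.791  1.70
#> 3 PAT1     15     7     7 0.838  1.68
#> 4 PAT2     10     9     8 0.978  2.13

struct <- pairwise_structure(counts, seqs, perms = 999, seed = 10)
struct$phist
#>   site_a site_b statistic p_value mode
#> 1 KER    KGI       0.0649   0.058 phist
#> 2 KER    PAT1      0.973    0.001 phist
#> 3 KER    PAT2      0.968    0.001 phist
#> 4 KGI    PAT1      0.988    0.001 phist
#> 5 KGI    PAT2      0.987    0.001 phist
#> 6 PAT1   PAT2      0.0860   0.087 phist
glance(struct)
#>     snn snn_p_value mean_fst mean_phist
#> 1 0.714       0.001    0.109      0.678
```

Reading the output: the four cross-barrier pairs show near-complete
nucleotide-level differentiation (Φst ≈ 0.97–0.99, p = 0.001 — the
smallest value 999 permutations can resolve), while the two within-group
pairs are statistically indistinguishable from panmixia (Φst < 0.09,
p > 0.05). The significant Snn of 0.71 (1 = perfect phylogeographic
sorting, ~0.5 under free mixing of the four sites) confirms geographic
structure overall — exactly the truth the simulator planted.

`median_joining(seqs, node_weights(counts)$weight)` builds the haplotype
network (`autoplot()` draws it); `beta_nti()` + `rc_bray()` +
`partition_processes()` quantify assembly processes; `mmrr_site_level()`
regresses composition on geography and environment. `run_pipeline()`
chains everything and writes TSV/FASTA/Newick/GraphML outputs plus a
manifest; `inst/cli/oligophylo` exposes the same stages as shell
subcommands.

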