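---
title: "Methods: TE evolution as networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE evolution as networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEnet)
```

# The three network views

## Sequence-similarity network

Nodes are individual annotated TE copies; an edge connects two copies that
produce a local nucleotide alignment, with weight equal to the alignment
bitscore (bits). Bitscores are log-scaled likelihood-ratio scores, so the
weight is additive evidence of shared sequence; working at the nucleotide
level (rather than on encoded proteins) lets the network capture similarity
that is *not* homology, such as two subfamilies independently co-opting the
same host-gene segment.

Construction (`buildSSN`) makes three normalisations:

* **Max symmetrisation.** Alignment hit tables are directed and may contain
  several local alignments per pair. All hits for one unordered pair are
  collapsed to the maximum bitscore. The maximum (rather than sum or mean)
  is order-independent, insensitive to how an aligner fragments one match
  into several HSPs, and keeps the "best evidence" semantics of a bitscore.
* **Isolated copies are retained** as degree-0 nodes. Dropping them would
  silently change denominators in enrichment and flag comparisons; both
  totals are visible to the caller.
* **Optional filters** reproduce the preset needed for dense young
  retrotransposon families (e.g. human L1): minimum copy length 500 bp and
  e-value ceiling 1e-30. The default network applies no filter.

Two cluster statistics are provided: weighted Louvain modularity at
resolution 1 (`louvainPartition`) and connected components
(`componentPartition`). Louvain clusters always nest within components, so
their rand index measures sub-partitioning only. Louvain's node-visiting
order is random; the partition is pinned by an explicit seed (default 0) so
identical inputs give identical output. The modularity value of the chosen
partition is reported alongside.

The rand index is computed from the co-membership contingency table, which
is algebraically identical to the all-pairs definition (fraction of node
pairs grouped concordantly) but scales to large networks; the test suite
verifies the identity against a literal pair-enumeration oracle.

*Mixed clusters* are clusters containing two or more annotated subfamilies
(`clusterComposition`). These are the interesting ones: either the
annotation is wrong, or the subfamilies share real sequence. Whether a
shared segment explains a mixed cluster is probed two ways: enrichment of a
per-copy flag (e.g. "best protein hit is host gene X") inside the cluster
vs the rest of the network, with a two-sided Fisher exact test
(`crypticHitEnrichment`; the test choice is ours — the underlying 2×2 table
is small and exact inference is cheap); and *persistence* — rebuild the
network with the segment masked and measure the best Jaccard overlap
between the old cluster and any new cluster (`clusterPersistence`). We call
the cluster persistent at overlap ≥ 0.5: the majority of the original
membership survives as a unit. The 0.5 default is a reporting threshold
only; the raw overlap is always returned.

"Connectivity" of flagged vs unflagged nodes (`connectivityByFlag`, e.g.
DDE3-transposase carriers vs the rest) is unweighted degree by default —
the number of distinct copies a node aligns to — with weighted degree
(strength) behind a flag. Degree was chosen as the default because the flag
comparisons ask *how many* partners a copy has, not how strong its best
alignments are; both variants are one argument apart.

## Bipartite content network

Genome nodes vs TE-family nodes; family identity is the consensus/library
name, assumed harmonised across genomes by a shared repeat library.
Edge weight between genome $g$ and family $f$ is one of four abundance
metrics: copy count, total bp ("TE length", the default focus), % of
genome size, or % of the genome's total TE bp. Node sets are identical
across metrics by construction — only weights differ — so metric
concordance (`metricConcordance`) is the rand index between the Louvain
partitions of the *genome* nodes under two metrics. Louvain is the default
partition statistic here (components are available via a flag): the
modularity partition is the one used for all downstream cluster colourings,
so it is the relevant object for a concordance claim.

Per-genome statistics: degree (number of families = TE diversity),
weighted degree (sum of incident weights = TE load under the metric) and
singletons (incident family nodes of total degree 1, i.e. families private
to the genome). Singleton membership is metric-invariant. Group
comparisons between silencing regimes use two-sided Wilcoxon rank-sum
tests.

Perturbation experiments fix the clustering parameters and seed, remove a
target (whole family/superfamily, or a random 10% of its nodes, repeated),
and report node/edge/cluster/modularity/component deltas plus the rand
index between baseline and perturbed genome partitions. Knockout is the
exact set-difference network: rebuilding from filtered copies and deleting
nodes from the built network agree (asserted in the tests), except that a
genome losing its last family disappears from a rebuild but remains as an
isolated node under deletion.

## Orthonetwork

To control for phylogenetic pseudo-replication (ten flies are not ten
independent observations of "piRNA+"), genome–genome edges are added from
shared-orthogroup counts and the mixed network is Louvain-clustered, so
closely related species collapse into one group node.

* Genome–TE weights use the length-adjusted metric
  $\mathrm{LengthAdj} = \log(\text{TE bp}) / \log(\max \text{TE bp})$.
  The ratio is invariant to the logarithm base and lies in (0, 1]. The
  maximum is taken over **all** genome–family edges (global scope) by
  default: the stated purpose of the adjustment is to bring TE weights onto
  the same (0, 1] scale as the orthogroup weights, which a global
  normalisation does exactly; per-family scope is implemented behind
  `maxScope = "family"` for sensitivity analysis. Totals of ≤ 1 bp are
  rejected (their log is ≤ 0) with an explicit error.
* Genome–genome edges exist for pairs sharing at least τ = 4,500
  orthogroups (sparsification against noise; raising τ can only remove
  edges) and are weighted by count / max over retained pairs.
* Genome–genome and genome–TE edges enter Louvain with their normalised
  weights as-is; no extra rescaling beyond the two (0, 1] normalisations is
  applied, since putting both on that common scale is precisely what the
  weight definitions are for.

Each genome-containing cluster becomes a group: degree = distinct families
incident to any member, weighted degree = sum of members' TE-edge weights,
singletons = families whose entire genome neighbourhood lies inside the
group. A one-genome group therefore reproduces that genome's bipartite
degree and singleton count exactly (asserted in the tests). Silencing
labels are majority votes over members with the agreement fraction
reported — on real inputs groups need not be uniform, and a silent
majority label would hide that.

# Activity classification and the singleton bootstrap

A TE is called *potentially active* iff it has at least one domain hit to
the six transposition-associated Pfam profiles: DDE_1 (PF03184), DDE_2
(PF02914), DDE_3 (PF13358), retrotransposon gag (PF03732), integrase core
(PF00665), retroviral aspartyl protease (PF00077); no hit means inactive.
The whitelist is configurable. Domain tables are consumed in the HMMER
per-domain dialect with a configurable independent-e-value ceiling
(default 1e-5 — the upstream search threshold is not part of the table
format, so a conventional profile-search cutoff is applied and logged).

The singleton bootstrap resamples 30 genomes from a group 1,000 times and
tests active vs inactive singleton counts within each resample. Both
counts come from the same genome, so the default test is the *paired*
Wilcoxon signed-rank on the within-genome differences; an unpaired
rank-sum variant is available behind `paired = FALSE` for comparison.
Groups smaller than the sample size are resampled with replacement, with a
warning.

# Statistical kernels

All tests funnel through three wrappers that fix the exact-vs-approximate
policy and record it in the result object:

* rank-sum: exact enumeration when the smaller sample has ≤ 25
  observations and no ties; tie-corrected normal approximation with
  continuity correction otherwise.
* signed-rank: zeros dropped (and reported); exact for ≤ 20 non-zero
  differences without tied magnitudes.
* Fisher 2×2: always exact (two-sided hypergeometric tail sum).

The crossovers keep desk-scale analyses fully deterministic and were fixed
before any power analysis; at the crossover the approximation agrees with
enumeration to < 0.01 (asserted in the tests). Two degenerate cases are
defined explicitly: samples with a single common value, and all-zero
difference vectors, both give p = 1 (no evidence). No multiple-testing
correction is applied anywhere — the analyses report a small number of
pre-specified comparisons — and results carry their sample sizes so a
caller can adjust if they run many.

# The synthetic landscape generator

`simulateLandscape` emulates the statistical structure of a multi-genome
TE survey; it is the package's test bed, not a sequence simulator.

Generative model (all draws seeded; the output is a pure function of the
config):

* Species are split evenly into clades arranged on a balanced topology.
  Silencing regimes (piRNA, DNMT) are assigned independently per species
  by default, or clade-uniformly (`regimeByClade`) for group-level
  analyses.
* Each species draws clade-shared families (≥1-truncated Poisson, mean 8
  for piRNA−) from its clade pool, plus species-private singleton families
  (Poisson, mean 2); DNMT+ species add extra *inactive* singletons
  (Poisson, mean 3) — the planted analogue of old, degenerate,
  methylation-tolerated copies.
* Copies per family are ≥1-truncated Poisson (mean 6 for piRNA−); lengths
  are log-normal (meanlog log 800, sdlog 0.45, floored at 50 bp),
  a standard right-skewed model for interrupted/fragmented repeat copies.
* The piRNA effect multiplies family richness by 2 and copies/family by
  0.5, so expected total TE bp is matched between regimes and the planted
  signal is the degree/weighted-degree *dissociation*, not a content
  confound. (Truncation at ≥ 1 and the 50 bp floor shift totals by a few
  percent; the totals test budgets for that explicitly.)
* Superfamily labels are sampled with one dominant label (default
  "Gypsy", weight 4) to reproduce the node-count imbalance that makes one
  superfamily structurally dominant in knockout experiments.
* Shared-orthogroup counts start at 9,000 within clades and decay
  exponentially (rate 0.8 per unit of between-clade tree distance) with
  Gaussian noise (sd 150), so the default τ = 4,500 retains exactly the
  within-clade pairs.

`simulateHits` plants alignment structure at the hit level: within-family
pairs get bitscores ~ Normal(300, 25) at density 0.7 (density 1 and DDE3
domain hits for designated "recently active" families); optional
between-family background; an optional convergent segment linking two
designated families at mean 150 / density 0.5 (the enforced ordering
within > convergent > between mirrors full-length homology vs a shared
segment); `plantHorizontalTransfer` adds donor-labelled copies to a
recipient genome, which the hit model then ties to the donor family.

What the generator does **not** emulate: real bitscore distributions
(heavy-tailed, length-dependent), nested/fragmented annotations,
annotation error, library incompleteness, shared families *between*
clades, and any sequence-level process. Passing tests therefore show that
the statistics recover planted effects under a clean generative model —
they do not certify behaviour on real annotation noise.

# Problem sizes and determinism

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen to make the planted effects detectable without waste:
planted-partition recovery uses 10 families × 20 copies over 20 seeds;
mixed-cluster and transfer detection use 8×8 and 6-species landscapes over
20 seeds; the degree/weighted-degree power study uses 40 species × 100
seeds per condition (significant degree effect expected in ≥ 80% of
seeds, weighted-degree in < 30%, both near 5% under the null). Every
random stage takes an explicit seed, the full pipeline writes a manifest
(config hash, input digests, seeds, version), and reruns with one config
are byte-identical — asserted at file level in the acceptance tests.

# Known limitations

* Family harmonisation across genomes is assumed (one shared library);
  nothing detects two names for one family.
* Overlapping or nested annotations are kept as distinct copies; no
  merging is attempted, so interrupted elements count twice.
* Louvain is a greedy heuristic: the seeded run is reproducible but not
  provably optimal, and resolution 1 is a convention, not an inference.
* The orthonetwork mixes two edge semantics (content, phylogeny) in one
  modularity objective; the relative influence of the two edge classes is
  set entirely by the two normalisations.
* Group-level comparisons inherit the small-n behaviour of rank tests:
  with a handful of groups per side only large effects are detectable.
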