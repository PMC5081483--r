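---
title: "Methods: gene-centered PDI network analysis with pdinet"
author: "pdinet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centered PDI network analysis with pdinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdinet)
```

# The problem

Gene-centered protein–DNA interaction (PDI) screens — enhanced yeast
one-hybrid (eY1H) assays foremost — start from a promoter of interest and
identify, in one experiment, the repertoire of transcription factors (TFs)
able to bind it. Screening thousands of promoters against most of an
organism's TFs yields a bipartite TF→promoter network that can serve as a
backbone for functional inference: which TFs activate and which repress
their targets, which biological processes a TF is wired to, and which TFs
are likely redundant because they bind overlapping target sets.

`pdinet` implements that analysis framework end to end as reusable,
seed-deterministic R functions: network construction and bait-quality
filtering, degree statistics, degree-preserving randomization nulls,
energy-based motif scanning and elementary-motif discovery,
co-expression-based activator/repressor inference, cofactor-based sign
classification, TF–GO association scanning, and a TF association
(redundancy) network. A synthetic-data generator with planted ground truth
(`generateWorld()`) stands in for a screen so that every stage is testable
at desk scale.

# The data model

The central object is the `PDINetwork`: a set of unique, unweighted
TF→promoter edges plus a promoter→gene map, a bait-quality label per
promoter, and the *tested* screen dimensions. Two modelling commitments are
made here:

* **Edges are binary.** A PDI either was or was not detected; repeated
  detections collapse (the collapse count is logged). All downstream
  statistics treat the network as a 0/1 incidence structure.
* **Fractions use the tested denominator.** A TF's out-degree as a
  fraction of "promoters tested" divides by `nTestedPromoters`, not by the
  promoters that happened to interact, because screens report coverage of
  the assayed space.

Bait quality takes exactly four values (`clean`, `moderate_background`,
`high_background`, `no_interactions`); unknown labels are rejected rather
than coerced, since silent coercion would hide upstream file errors.
`filterBaits()` restricts the network to an allowed quality set — the
high-quality analysis network is `filterBaits(net, "clean")` — and is
idempotent.

Genomic intervals (ChIP peaks, promoter coordinates) follow the 0-based
half-open convention of BED files. A peak is assigned to a promoter when
`floor((start + end) / 2)`, its midpoint, lies inside the promoter
interval; a midpoint exactly at the interval end is outside. The floor
rule is a deterministic tie-break for odd-length peaks; the alternative
(ceiling) moves assignments by at most one base and only for midpoints
exactly on a boundary.

# Randomization nulls

All "is this overlap/count surprising?" questions are answered against
degree-preserving edge-switch randomizations (`edgeSwitch()`): two edges
(t1,p1), (t2,p2) are drawn uniformly and rewired to (t1,p2), (t2,p1) iff
neither rewired edge exists. Every TF keeps its out-degree and every
promoter its in-degree exactly, so hub structure — the dominant confounder
in heavy-tailed networks — is held fixed. No mixing schedule is standard
for this procedure; `pdinet` uses `swapAttemptsFactor = 100` proposals per
edge by default, which on the networks used here (hundreds to thousands of
edges) is far past the point where summary statistics of the randomized
ensemble stop changing. The proposal chain is a symmetric random walk with
rejection on the space of degree-matched simple bipartite graphs, so its
stationary distribution is uniform on the swap-connected class.

`overlapSignificance()` compares an observed shared-edge count with the
null ensemble and reports the z-score, the one-sided upper-tail normal p
(the enrichment direction), and an empirical p `(1 + #null ≥ obs)/(1 + n)`.
**Limitation:** the normal-tail p is only calibrated when the null overlap
count is far from zero. On very sparse comparisons (null mean of a few
counts) the discrete, right-skewed null makes the normal upper tail
anti-conservative; the empirical p does not have this problem and is
reported alongside. The calibration tests therefore run on comparisons
with a large null mean, which is also the regime the method is used in
(genome-scale networks, 20,000 randomizations).

# Motif scanning and discovery

`pwmEnergyScore()` maps a k-mer and a position weight matrix to a score in
(0, 0.5]: the mismatch energy is the summed log-ratio of each column's
maximal probability to the probability of the observed base, and the score
is the logistic transform `1/(1 + exp(dE))`. The consensus has `dE = 0`
and scores exactly 0.5; every substitution toward a lower-probability base
lowers the score. This realizes the published description of energy-based
PWM scoring (score range (0, 0.5], perfect match 0.5) without reproducing
any fitted chemical-potential variant, for which no fitting data exist
here. A pseudocount of 0.001 per cell (added at `PWMotif()` construction)
avoids infinite energies on zero entries and is negligible elsewhere.

`scanPromoter()` scores every window of the proximal promoter — the
3'-most 500 bp by default, since promoterome clones end at the start
codon and most in vivo binding in compact genomes is proximal — on both
strands by default (the convention is configurable; scanning one strand
can only remove hits). Binding is binary: multiple matches count once.
`predictedNetwork()` assembles the motif-predicted PDI network and removes
TFs hitting more than 50% of promoters as non-specific, mirroring the
filter used with screen-scale PWM collections.

`discoverMotifs()` is a deliberately elementary motif finder: it counts
per-promoter *presence* (both strands) of every k-mer (k = 8 by default,
configurable 6–10) in bound vs unbound proximal windows, applies a
one-sided hypergeometric test per k-mer, Benjamini–Hochberg FDR (< 0.05)
and an enrichment ratio (> 2, with a +0.5 pseudo-frequency guard on the
negative side), and greedily aligns the surviving k-mers (best ungapped
overlap ≥ k−2, at most one mismatch, both orientations) into probability
matrices. Presence/absence rather than occurrence counts matches the
binary interaction semantics of the network. Discovery refuses positive
sets smaller than 50 promoters, where k-mer statistics are too unstable to
yield useful motifs. No clustering/extension refinement or motif–motif
comparison is attempted.

# Co-expression integration and sign inference

Published compendium scores for the organism are not reproducible from
equations, so `buildCoexpression()` documents its own, swappable
integration: per dataset, Pearson correlation of `log2(x + 1)` expression
across samples (the log stabilizes profiling-scale data); per gene pair,
Fisher-z transformed correlations averaged across the high-confidence
datasets (≥ 4 experiments) containing both genes, weighted by `n − 3` (the
inverse variance of Fisher z; 3-sample datasets carry zero weight and are
skipped), then back-transformed. Genes in fewer than 25 high-confidence
datasets, or ranking in the bottom 10% of expression in more than half of
them, are removed as noise.

`predictSign()` calls a TF an activator (repressor) when its co-expression
scores with its network targets are stochastically higher (lower) than
with the scored non-target genes, by a two-sided Mann–Whitney U test at
alpha 0.05 with at least 10 scored targets. Two ambiguities are resolved
as follows: the test is two-sided with the direction read from the rank
sum (the framework calls both directions, so a one-sided choice per TF
would be circular), and the non-target universe is the scored genes that
appear as promoter genes in the network (not the whole compendium), so
targets and non-targets share the selection into the screen. Bifunctional
TFs are structurally uncallable by this contrast and appear as `none`.

`rankSumTest()` enumerates the exact permutation distribution of the
midrank statistic when both groups have ≤ 8 observations and otherwise
uses the midrank normal approximation with tie correction and no
continuity correction. `shuffleNull()` re-runs the calling rule on
permuted score-to-gene assignments (equivalently, resampled target sets —
the implementation resamples indices against precomputed ranks, which is
the same test) to give the expected number of activator/repressor calls by
chance and a z-score for the observed counts.

Spatiotemporal overlap uses the Pearson correlation of TF and target
expression across the 11 tissue–stage conditions; pairs above the 75th
percentile of all pair correlations count as overlapping. The cutoff is
recomputed from the data supplied — on the study's inputs it would be a
data value, never a constant of the package. Odds ratios compare overlap
among interacting vs non-interacting pairs (chi-square without continuity
correction); per-TF classes use the same contrast on targets vs
non-targets with a Haldane–Anscombe 0.5 correction, flagged, when a cell
is zero.

# Cofactor signs, GO associations, gene-set enrichment

`classifyByCofactors()` labels a TF activator/repressor/bifunctional/
unclassified from the roles of its protein–protein interaction partners
(co-activator only / co-repressor only / both / neither). Concordance
across evidence sources treats bifunctional as compatible with either
sign. `cofactorFractionStats()` compares co-activator partner fractions
between predicted activators and repressors by an unpaired two-tailed
Student's t-test.

`tfGoEnrichment()`/`associationScan()` test TF target sets against GO
biological-process terms with a one-sided Fisher (upper-tail
hypergeometric) test over the **network gene universe** — the genes whose
promoters are in the filtered network — not the genome. Using the genome
would conflate screen composition with biology; the in-network universe is
also what the detox-enzyme enrichment uses. The filter cascade is applied
in order: TFs with out-degree < 10 (underpowered) or > 150 (non-specific
hubs) dropped; terms with < 10 or > 200 annotated in-network genes
dropped; among terms annotating identical target sets a single
representative is kept by a seeded random draw (the association count is
invariant to which one, since identical sets give identical p-values).
Associations are reported at p < 0.001 — the framework controls
multiplicity by this hard cutoff plus a randomized-network null (the same
scan on edge-switched networks), with a Benjamini–Hochberg column emitted
alongside for reference. GO terms are treated as flat gene sets; no
ontology-graph propagation is performed. `geneSetEnrichment()` applies the
same Fisher machinery to arbitrary user-supplied families (e.g. CYP/GST/
UGT/SDR-like detoxifying enzymes), and `familyBindingEnrichment()` adds
the pooled two-proportion comparison of a TF family's share of binding.

# TF association network

`buildAssociationNetwork()` connects TFs whose target-profile Jaccard
similarity is **at least** 0.2 (inclusive at the boundary), restricted to
TFs with PDI out-degree ≥ 3. "Proportion comparison test" statistics are
implemented as a pooled two-proportion z-test (`proportionTest()`), with a
Fisher exact p alongside for small counts. The high-connectivity boundary
for the essentiality comparison defaults to association degree ≥ 1
(connected vs isolated) — the distribution itself is returned, and the cut
is configurable, since no canonical cut exists for this display.

# The synthetic world

`generateWorld()` emits every input the pipeline consumes, from a single
root seed that fans out to per-component child seeds (so stages can be
regenerated independently). The standard world, used throughout the test
suite, is sized for desk-scale verification, not to imitate any genome:

* **Screen**: 50 TFs × 400 promoters of 1 kb. Intended out-degrees follow
  `rank^(-1.4)` capped at 60% of promoters (~1,600–1,700 edges), giving
  the hub-dominated tail gene-centered screens show: the top decile of
  TFs carries > 50% of edges.
* **Motifs**: one 8-bp PWM per TF with consensus-base probability 0.92
  (~12 bits). An NHR-like family of 12 TFs carries perturbed copies of a
  shared motif and draws targets from a shared promoter pool; 4 paralog
  pairs get near-copies of one motif and ~70% shared targets.
* **Sequences**: order-0 uniform background (GC content configurable);
  one sampled motif instance per planted edge, inserted at a uniform
  position inside the proximal 500 bp with probability 0.85.
* **Screen noise**: 5% dropout of placements, 5% false-positive edges,
  and bait-quality artifacts — 7% of promoters are `high_background` with
  Poisson(8) spurious extra in-edges, 8% `moderate_background` — so that
  `filterBaits()` measurably changes the statistics. Edge-less baits are
  labelled `no_interactions`.
* **Signs**: 8 activators + 8 repressors among the highest-degree TFs,
  each with ≥ 30 intended targets. Expression: 50 datasets of 3–8
  samples; a gene regulated by k signed TFs receives an additive effect
  `±0.5/sqrt(k)` per regulator on the log scale (unit total variance), so
  a singly-regulated target correlates with its TF at 0.5. Each dataset
  omits a random 10% of genes; 5% of genes sit at a planted noise floor
  to exercise the bottom-decile filter. Tissue profiles (11 conditions)
  use the same coupling at effect 0.8.
* **Cofactors/GO/essentiality**: signed TFs draw cofactor partners with
  the matching role at fidelity 0.9; 4 GO terms over-sample 70% of a
  planted TF's targets (plus random terms and one duplicated term to
  exercise the dedup rule); paralog and NHR-like TFs are essential with
  probability 0.1 vs 0.45 elsewhere, so redundancy anti-correlates with
  essentiality.

What the world does **not** emulate: real promoter composition and length
variation, dataset-specific normalization artifacts, correlated screen
errors, TF heterodimers, or the study's actual dataset count — passing the
planted-recovery tests shows the estimators read the structure they are
designed for at realistic noise, not that they would reproduce any
particular organism's numbers.

Two scale notes (both are package design choices for the desk-scale
world): the co-expression-vs-profile-similarity display excludes TFs
binding ≥ 5% of tested promoters by default, which at 400 promoters would
exclude every signed TF, so planted-module analyses use 15% at this
scale; and sign precision/recall are scored pooled over both signed
classes (a call is correct iff it matches the planted sign), because with
~6 tested unsigned TFs a single expected 5%-level false positive would
dominate any per-class precision.

# Numerical choices and degenerate inputs

* Jaccard of two empty profiles is `NA`, never 0/0.
* A zero null SD (no legal swaps) sets a `degenerate` flag instead of a z.
* A zero non-target median makes the median-ratio display `NA` with a
  flag; zero-variance tissue vectors are skipped and counted.
* Fisher p-values come from `phyper` (exact); the test suite checks them
  against `fisher.test` and an independent `choose()`-sum enumeration.
* All randomized procedures take explicit seeds; nothing reads global RNG
  state that the caller did not set.

# Problem sizes in the checks

The test suite and `scripts/acceptance.R` size their simulations for a
single CPU: the standard world (50×400, 50 datasets); 1,000 (tests) or
200 (script) randomizations for degree-preservation checks on a 500-edge
network; 500 repetitions × 100 nulls for type-I calibration of the
overlap p; 500 simulated TFs for sign-null calibration; 200 edge-switch
randomizations for the GO null (the framework's reference analysis uses
1,000, and 20,000 for overlap significance; both are configuration
fields).

# Running the pipeline

```{r, eval = FALSE}
cfg <- pipelineConfig(seed = 1L,              # synthetic mode by default
                      nRandomizationsOverlap = 100,
                      nRandomizationsNull = 100)
report <- runPipeline(cfg)
report
```

Every threshold of the framework is a field of `pipelineConfig()` with its
standard default (scan threshold 0.09, window 500 bp, non-specific cutoff
0.5, ≥ 10 targets at alpha 0.05, GO bounds [10,150]/[10,200] at p <
0.001, association similarity 0.2 at out-degree ≥ 3, overlap percentile
0.75, 20,000/1,000 randomizations); `validateConfig()` lists violations.
`runPipeline()` executes the stages in dependency order, records failures
per stage without aborting downstream stages whose inputs exist, and is
reproducible from the configuration and seed.

# Known limitations

* The co-expression integration is a documented stand-in, not a
  reproduction of any published compendium's scores; the interface
  isolates it so another scorer can be swapped in.
* The energy scanner matches the published score-range description but is
  not guaranteed numerically identical to fitted-energy implementations;
  counts that depend on the exact scanner (e.g. how many TFs the
  non-specific filter removes) are data-dependent.
* The normal-tail overlap p is anti-conservative for near-zero null
  means; use the empirical p there.
* Sign inference cannot detect bifunctional TFs by construction.
* GO terms are flat sets; annotation propagation is out of scope.
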