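---
title: "Detecting and typing isomerase-reductase gene clusters"
author: "gagcluster authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and typing isomerase-reductase gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagcluster)
```

## The biological problem

Glycosaminoglycans (GAGs) and pectins are polysaccharides whose bacterial
breakdown converges on a single linear intermediate,
4-deoxy-L-threo-5-hexosulose uronate (DHU). Two unrelated protein families
isomerize DHU — KduI (a cupin-like isomerase) and DhuI (an RpiB/LacA/LacB
family isomerase) — and their product is reduced by KduD or DhuD, two
divergent members of the short-chain dehydrogenase-reductase (SDR) family.
KduI and DhuI are *nonhomologous isofunctional enzymes*: same reaction, no
sequence homology. In many genomes the isomerase and reductase genes sit
next to each other as a two-gene cluster, and the four gene contents can be
combined and oriented in different ways.

`gagcluster` mines annotated bacterial genomes for these clusters: it finds
the gene families by profile search, pairs isomerase and reductase genes by
genomic distance, classifies each pair into one of 16 possible
configurations, detects three-gene tandem arrangements, and aggregates
possession, co-occurrence, taxonomic, abundance and habitat summaries at
the strain level. A first-class synthetic-data module generates annotated
genomes with planted clusters and ground truth, so the entire pipeline is
testable without any downloads.

## The 16-type configuration scheme

A cluster is one isomerase gene (kduI or dhuI) and one reductase gene (kduD
or dhuD) on the same contig with an intergenic gap of at most
`cluster_gap_bp` (default 500 bp). Four gene contents, two transcription
orders and two relative orientations give 16 distinct configurations:

* **Parallel types A-H** (both genes on the same strand), named by content
  and transcription order with the upstream gene first: A `kduI-kduD`,
  B `kduD-kduI`, C `dhuI-dhuD`, D `dhuD-dhuI`, E `kduI-dhuD`,
  F `dhuD-kduI`, G `dhuI-kduD`, H `kduD-dhuI`.
* **Antiparallel types Ac-Hc** (opposite strands). For a content pair whose
  parallel letters are X (isomerase first) and Y (reductase first), we
  render the divergent arrangement (adjacent 5' ends, genes pointing away
  from each other) as X^c and the convergent arrangement (adjacent 3' ends)
  as Y^c. This convention is isolated in `classify_pair()` so it can be
  flipped in one place; antiparallel clusters are rare in practice, so
  downstream counts are insensitive to it.

Classification is invariant under reverse-complementing a contig
(coordinates reflected, strands flipped): a property test over randomized
genomes enforces this, and brute force over all 32 raw
content/order/strand configurations confirms that they collapse pairwise
onto exactly the 16 labels.

**Gap definition.** With u the gene with the smaller start and v the other,
`gap = max(0, v$start - u$end - 1)` in 1-based inclusive coordinates.
Abutting genes (v starts immediately after u ends) have gap 0, and
overlapping genes are clamped to 0. The ≤ 500 bp rule is applied to this
end-to-start distance; the off-by-one ambiguity inherent in any such
convention sits exactly at the boundary and is documented rather than
hidden. Pairing does **not** require adjacency — a small unrelated gene may
sit inside the gap (type H clusters often carry a cupin-domain gene between
kduD and dhuI) — and one gene may serve in several calls.

**Tandem clusters.** Three genes such as kduI-kduD-dhuI form two
overlapping pair calls sharing the middle gene. `merge_tandem()` reports
maximal same-direction chains of length ≥ 3 *in addition to* the pair
calls, never instead of them: a tandem strain stays positive for each
constituent type. Antiparallel calls never join chains.

## The search engine

The family-membership contract is: a gene is a family member when its complete
sequence matches the family model at E < 1e-5. The package implements this
with an internal engine so that no external binaries are needed:

* **Pairwise alignment** — affine-gap Smith-Waterman (local) and
  Needleman-Wunsch (global) in compiled code, BLOSUM62 with gap open 11 /
  extend 1 (a gap of length k costs open + k·extend). Percent identity
  counts every alignment column, including gaps, in the denominator.
  Residues outside the 20-letter alphabet map to X, which scores 0 against
  everything. An independent full-matrix DP oracle in the test suite checks
  both modes on hundreds of random pairs.
* **Profiles** — match columns are alignment columns with < 50% gaps;
  emissions are pseudocount-smoothed log2-odds against Robinson-Robinson
  background frequencies. Scoring is glocal: the whole profile must align,
  the target sequence has free flanks, internal insertions and deletions
  pay affine costs (open 3, extend 0.3 bits — the absolute scale is
  irrelevant because the statistics are calibrated empirically).
* **E-values** — because the internal scorer's statistics are not BLAST's,
  Gumbel parameters are fitted by the method of moments to the scores of
  200 shuffled-sequence decoys drawn from the target database (seeded,
  deterministic), giving `E = K·m·N·exp(-λS)` with N the database size in
  residues. Doubling N doubles E, and the top decoy score lands at E of
  order one against its own decoy set, by construction.

Multiple alignment of query sets uses an internal center-star progressive
aligner (center = highest total pairwise score, ties by id), which is
deterministic and order-invariant; any external aligner can be plugged in
through the `aligner` argument of `family_profile()`.

## Iterative query selection

Starting from one seed protein per family, each round searches the current
query against the remaining protein pool at E < 1e-5; among hits whose
global identity to **every** already-selected query is below 97%, the hit
with the lowest E-value is selected (ties: higher score, then lexicographic
id), removed from the pool, and becomes the next query. Twenty rounds give
up to 21 queries per family; early exhaustion is recorded, not an error.
Two genuinely open procedural choices are resolved as follows:

* the identity ceiling is enforced against all previously selected queries,
  not only the current one — this matches the stated non-redundancy goal
  and prevents near-duplicate accumulation;
* each round considers the current round's hits only (no cumulative
  candidate pool across rounds).

**What profile broadening does and does not show here.** The synthetic
family generator produces point-substituted variants of a seed. Such
variants keep a full-length ungapped alignment to the seed, so pairwise
search alone already detects members far below the selection ladder —
there is no identity at which the seed fails but the profile succeeds, and
the package does not pretend otherwise. The tested property is therefore
that the 21-query profile retains full-sequence sensitivity (E < 1e-5) for
held-out members at 35% identity and for further-diverged descendants of
the most remote selected query, while rejecting composition-matched
shuffled decoys. Demonstrating a profile *advantage* would need indel-rich,
domain-structured families that the generator deliberately does not
attempt to emulate.

## Inventories

Family profiles cross-react (KduD and DhuD are both SDR enzymes), so
`assign_families()` applies a best-hit rule: per gene, the family with the
minimum E-value wins (ties: higher score, then the fixed priority kduI,
dhuI, kduD, dhuD, ugl, ogl, yteR, kdgA, kdgK, kdgF). Copy counts are
deliberately uncapped — extreme paralog expansions are reported as-is and
left to the analyst, since capping would silently hide likely false
positives instead of exposing them.

The possession matrix records, per strain, boolean possession of the 10
families, the 16 labels and `any_cluster`, plus per-family copy counts.
Co-occurrence ratios (fraction of cluster-positive strains also carrying
ugl/ogl/yteR/kdgA/kdgK/kdgF) report numerator and denominator alongside
each ratio and are computed per strain by default, with a per-cluster
variant (`unit = "cluster"`). Separate-loci accounting restricts to
cluster-negative strains and cross-tabulates isolated isomerase/reductase
possession.

## Abundance aggregation and its null

Per sample, the abundance of a cluster type is the summed relative
abundance of the strains positive for that type; a strain positive for two
labels contributes to both (the same double-counting used for per-type
strain totals). `abundance_by_type()` runs a Kruskal-Wallis omnibus test
and two-sided pairwise Wilcoxon rank-sum tests on these sums — and, in
parallel, on *per-carrier-strain* abundances (the sum divided by the
number of positive strains).

The second scale exists for a statistical reason worth spelling out. Types
differ in how many strains carry them; summed abundance therefore differs
between types even when every strain's abundance is drawn from one common
distribution. A rank test on raw sums "detects" this prevalence difference,
which is real but is not abundance enrichment. On the per-strain scale the
no-enrichment null is exchangeable across types, so the compound
enrichment flag the package raises (`top_label`, `top_significant`: the
top type is higher than *all* others with the omnibus and every pairwise
test below α = 0.01) is calibrated: across 20 fold-1 replicates of the
default synthetic cohort it fires at most once, while a planted 3× type-E
enrichment is detected in every replicate. Both scales' statistics are
returned; the raw sums remain the quantity to plot.

Habitat summaries average per-strain habitat preference scores (supplied
as inputs) over label-positive strains, flag each label/category cell
against the across-label mean, and keep categories whose mean exceeds 10
for at least one label.

## Representative 16S selection

Greedy centroid clustering at 90% global nucleotide identity
(match 1 / mismatch -1 / gap open 2 / extend 1): sequences are processed
length-descending (ties by id); each joins the first centroid at ≥ 90%
identity, else founds a cluster. The centroid of the largest cluster is
the representative; a size tie goes to the longer centroid. A brute-force
re-implementation of the rule serves as the oracle in the tests.

## The synthetic-data module

Generators are pure functions of their seed and emit ground truth
consistent with the data:

* `mutate_protein()` substitutes uniformly chosen positions (preferring
  positive-scoring BLOSUM62 replacements) to hit a target ungapped
  identity within one percentage point; `synth_family()` builds identity
  ladders around a seed.
* `synth_genome()` realizes planted cluster plans (label, gap, optional
  intervening decoy genes), self-checking every planted pair with
  `classify_pair()` at generation time; decoys are shuffled-then-mutated
  family seeds, i.e. composition-matched negatives verified ≤ 30% identity.
  Gene lengths follow the family seed proteins (typical bacterial CDS
  sizes); intervening decoys are small (270-360 bp), cupin-like. Planted
  loci are spaced 5 kb apart so no unplanned pair can satisfy the cutoff.
* `synth_cohort()` draws per-strain cluster types and auxiliary families
  as independent Bernoulli variables (defaults: the seven commonly
  observed parallel types at equal frequency 0.15; kdgA/kdgK near-universal
  at 0.98, ugl 0.5, kdgF 0.4, ogl/yteR 0.3), plants gaps uniformly in
  0-99 bp (clusters are overwhelmingly sub-100 bp), assigns phylum labels,
  and gives a fraction of cluster-negative strains an isolated kduI + kduD
  pair at separate loci.
* `synth_abundance()` draws per-strain, per-sample lognormal abundances
  (sdlog 2 by default — the heavy-tailed regime typical of gut
  metagenomes), shifts the log-mean by log(fold) for enriched strains, and
  normalizes each sample to sum 1.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no nucleotide-level codon structure (proteins are
the functional payload), no indels or domain rearrangements within
families, no phylogenetic correlation between strains, no annotation
errors (missed or mis-called CDS), and no compositional biases beyond
residue shuffling. Recovery results on synthetic genomes certify the
pairing/typing logic and the search contracts, not the field performance
of profile search on real divergent families.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
deliberately modest sizes: 200 single-plan genomes for planted-cluster
recovery, 100 random genomes for the reverse-complement property, one
60-member family (plus 40 background proteins) for query selection, 500
random pairs of length ≤ 30 for the aligner oracle, and one 200-strain
cohort with 50 samples for the abundance analyses. These sizes give exact
or near-exact expectations while keeping a full run in tens of seconds.

Deterministic tie-breaks are used throughout: gene sorting by (contig,
start, id); hit sorting by (E-value, -score, id); family assignment by the
fixed priority above; center selection by (total score, id); 16S clusters
by (size, centroid length, id). Degenerate inputs have defined behavior:
empty databases yield empty hit sets, empty strains yield all-false
possession rows, a zero denominator yields an undefined (NA) ratio rather
than zero, and a degenerate decoy score distribution is a calibration
error rather than a silent λ = 0.

## Limitations

* The internal search engine honors the E < 1e-5 full-sequence contract
  but is not BLAST/HMMER; absolute E-values differ from those tools, and
  real-data family assignments near the threshold may differ too. The
  engine interfaces (`engine` in `select_queries()`, `aligner` in
  `family_profile()`) accept external backends where exactness matters.
* Cluster calls are genomic-distance claims only; no operon or
  co-transcription inference is attempted.
* Lineages, abundance tables and habitat scores are inputs; the package
  does not compute taxonomy, process reads, or query habitat databases.
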