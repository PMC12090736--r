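---
title: "Phage host families: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phage host families: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phf)
```

## The problem

Gut viromes are dominated by bacteriophages that are highly diverse and
individual-specific at the nucleotide level. Two people rarely share a
viral OTU (vOTU), so vOTU-level abundance tables are nearly disjoint
across individuals, ecological distances between their samples saturate
near 1, and disease signals drown in inter-individual noise. Phages do,
however, share something ecologically meaningful: their bacterial hosts.
This package implements the *Phage Host Family* (PHF) framework — label
every viral contig with the bacterial **family** of its predicted host,
agglomerate abundances to those families, and compare communities at that
level.

The family rank is not arbitrary. Host predictions can be scored against
Hi-C proximity-ligation sequencing, which physically crosslinks phage DNA
to host DNA in situ and is treated here as the experimental reference.
Prediction-vs-Hi-C concordance stays high from phylum down to family and
drops sharply at genus, so family is the deepest rank at which predicted
hosts can be trusted for community-level work.

## Concordance between predicted and Hi-C-assigned hosts

For every contig with a host from *both* sources, hosts are compared at
each rank from phylum to genus under three stringencies:

* **strict** — the most confident prediction matches the top-ranked Hi-C
  hit;
* **top_vs_any** — the most confident prediction matches *any* Hi-C hit;
* **any_vs_any** — *any* prediction matches *any* Hi-C hit.

Percent concordance is `100 * n_concordant / n_total`, where `n_total` is
the number of contigs with hosts from both sources — the same denominator
at every rank and mode. The accepted match sets are nested, so
`strict <= top_vs_any <= any_vs_any` always holds; with internally
consistent lineages, concordance is also non-increasing from phylum to
genus within a mode. Both properties are asserted on every synthetic
cohort in the test suite, and the whole engine is checked for exact
equality against a brute-force enumerator on a thousand random small
instances.

Three deliberately conservative rules:

* Name comparison is exact and case-sensitive. Taxonomy names are a
  controlled vocabulary; fuzzy matching would fabricate concordance.
* A missing name at a rank is never concordant. By default such contigs
  stay in the denominator and count as discordant; whether the original
  analyses dropped them per rank is not knowable from the outside, so
  `concordance_report(..., drop_unranked = TRUE)` exposes the other
  reading.
* Ties in prediction confidence (and in Hi-C linkage strength, when ranks
  must be derived from strengths) are broken by the lexicographically
  smallest serialized lineage, so "most confident" is deterministic.

## From vOTU tables to PHF tables

`assign_phf()` keeps the single most confident prediction per contig;
contigs with no prediction (or no family name in their best prediction)
become `"Unknown"`. The downstream pipeline is:

1. `to_relative_abundance()` — per-sample proportions; zero-sum samples
   are an error, not a silent NaN.
2. `filter_unknown_fraction()` — retain samples whose unknown-host mass
   is strictly below 30%. Samples dominated by unassigned contigs would
   be compared on a small, unrepresentative slice of their community.
   "Less than 30%" is read literally as a strict inequality.
3. `agglomerate_phf()` — sum member contigs per family. Per-sample totals
   are conserved exactly and the operation is idempotent.
4. `drop_unknown()` — the `"Unknown"` pseudo-family participates in
   relative abundance and in the 30% filter, but is excluded (and the
   table renormalized) before distance and prevalence analyses: those
   analyses compare communities of *assigned* contigs. A flag restores
   the other behaviour.

Supporting operations follow the conventions of the upstream tools they
replace at desk scale: presence calling uses length-banded breadth
thresholds (50% below 5 kb, 30% from 5 to 20 kb, 10% at and above 20 kb,
with the boundary belonging to the deeper band); `goods_coverage()` is
`1 - singletons/N`; `filter_low_depth()` drops samples below 1,500
length-normalized read counts, where "length-normalized" defaults to
reads per kilobase summed over features — the conventional normalization,
left pluggable because the convention is not universal;
`dereplicate()` clusters contigs at 95% ANI over 85% alignment fraction
of the shorter sequence using the standard greedy longest-first rule
(membership is only granted against cluster representatives, never
transitively); `prevalence()` counts individuals, not samples, with
"prevalent" meaning strictly more than 50% of individuals.

## Distances, stability, and tests

Bray-Curtis dissimilarity is `sum|x - y| / sum(x + y)`; matrices are
computed through `vegan::vegdist()`, and the package's own pairwise
formula is cross-checked against that route in the tests. UniFrac over a
rooted host tree comes in two variants:

* unweighted — branch length leading to taxa of exactly one sample,
  divided by branch length leading to taxa of either;
* weighted (normalized) —
  `sum(L_b |p_b(x) - p_b(y)|) / sum(L_b (p_b(x) + p_b(y)))`, with `p_b`
  the proportion of a sample's abundance descending from branch `b`.

Both are computed from a single edges-by-samples mass matrix accumulated
in postorder, and both are verified to 1e-10 against an exhaustive
branch-enumeration oracle on a thousand random small trees, and against
phyloseq on a random table. UniFrac is computed on the filtered,
renormalized table (the composition actually being compared), not the
unfiltered one. When only a genome-level reference tree is available,
`prune_tree_to_families()` collapses it to one representative tip per
family — the first matching tip in a deterministic preorder traversal —
so results do not depend on traversal accidents; a purpose-built
family-level tree can be supplied instead.

A structural fact makes "PHF distances are smaller" more than an
empirical observation: for any sample pair, Bray-Curtis on grouped sums
is at most Bray-Curtis on the original features (triangle inequality
applied within groups). The tests assert this to 1e-12 on hundreds of
random tables; the biological content of the PHF framework is *how much*
smaller distances get, which the synthetic cohorts make visible.

Longitudinal stability is `1 - distance` between consecutively collected
samples of one individual — consecutive in collection order, not
calendar time. Matched metric comparisons (e.g. contig-level Bray-Curtis
vs PHF-level Bray-Curtis vs PHF-level weighted UniFrac on the same
sample pairs) use a Friedman test followed by pairwise two-sided Wilcoxon
signed-rank tests with Bonferroni correction (multiplying by the number
of post-hoc comparisons actually performed, capped at 1). All-tied
degenerate inputs get statistic 0 and p = 1 rather than NaN. PHF-host
abundance associations use Spearman's rank correlation across shared
samples, with names bridged between taxonomy namespaces by a
fraction-mapping table at threshold 0.6 and Benjamini-Hochberg adjustment
across tested pairs; constant vectors are flagged and excluded rather
than given a fabricated correlation.

## The synthetic cohort generator

Real cohorts at this scale are sequencing projects; the generator
reproduces the statistical structure the analyses assume, with ground
truth, so every stage is testable from a seed:

* a cohort-level family profile is drawn once, and each individual's
  family profile from a Dirichlet centred on it — individuals resemble
  each other at family level;
* each family's vOTU pool is mostly private to each individual, with a
  configurable cohort-shared slice — contig-level overlap is low while
  family-level structure is conserved;
* within-individual dynamics are a stationary AR(1) process on log
  abundances; counts are negative-binomial draws under the depth model,
  and zeros are real zeros;
* predictions corrupt the true lineage with per-rank error rates using a
  *nested* model: the shallowest wrong rank is drawn, and the lineage is
  wrong from there down, by swapping in a sibling taxon's sub-lineage
  under the same parent. This is what keeps generated lineages
  population-consistent (equal at a rank implies equal at every
  shallower rank) — splicing an arbitrary foreign lineage below the
  wrong rank would silently break the rank-monotonicity property the
  concordance analysis relies on;
* confidence scores fall with corruption depth plus small noise; only
  their ordering matters downstream;
* Hi-C links are error-free by default (the experimental reference),
  with a small multi-host rate.

Key defaults and why: 10 individuals with 14 samples each and 74 host
families match the cohort shapes the framework was developed on;
`p_predicted = 0.863` matches observed host-prediction sensitivity in
human gut data; per-rank error rates (phylum 0.02, class 0.03, order
0.04, family 0.07, genus 0.33) reproduce the observed concordance
profile — high and flat down to family, collapsing at genus; the 20%
multi-prediction and 2% multi-host rates reproduce the observed ratios
of pairings to phages (about 1.28 and 1.02). Desk-scale choices: 4 vOTUs
per family per individual with a 0.25 shared fraction (exactly one
cohort-shared vOTU per family — pools mostly private without being
artificially disjoint), negative-binomial depth with mean 5e4 and size
10, AR(1) persistence 0.7 with unit log-scale variance. Test problem
sizes (5,000 contigs for rate-recovery checks, 1,243 contigs by 20 seeds
for the concordance calibration, cohorts of 4-10 individuals elsewhere)
were chosen so the full suite exercises every property at comfortable
Monte-Carlo resolution.

What the generator does **not** emulate: sequence-level artifacts
(assembly fragmentation, chimeras), compositional coupling between
families beyond the shared Dirichlet, diagnosis-dependent effect sizes
(diagnosis and dysbiosis labels are drawn independently of abundances),
or prediction errors that correlate with abundance. Passing tests
therefore demonstrate that the *operations* are correct and that the
pipeline recovers planted structure — not that any particular biological
effect size in real data is reproduced.

`plant_prevalence()` sidesteps the abundance model entirely and plants an
exact number of features above 50% prevalence (present in all samples of
strictly more than half the individuals, at most half for the rest), so
the prevalence logic can be checked against exact ground truth.

## Numerical choices and degenerate inputs

* Strict inequalities where the rules say "less than" / "more than"
  (30% unknown filter, 50% prevalence); boundary presence thresholds use
  the quoted inequalities exactly (a 20 kb contig is in the >= 20 kb
  band).
* All tie-breaks are lexicographic on serialized lineages or ids — no
  result depends on input row order.
* Zero-sum samples, empty host lists, negative branch lengths, duplicate
  time indices, and metadata/matrix id mismatches are hard errors naming
  the offender, never silent coercions.
* Abundance write/read round-trips are exact to 15 significant digits.
* Percentages are stored at full precision and printed to one decimal.

## Limitations

The framework inherits the sensitivity of the host-prediction tool: a
contig with no prediction is invisible to PHF-level analysis, and the
unknown fraction differs between samples (hence the 30% filter). Family
is the finest usable rank — phage-host specificity below family is out of
reach by construction. Concordance calibration rests on fecal samples;
other environments may behave differently. And the generator's scope
means empirical claims about real cohorts should be re-derived on real
tables, which the io module reads directly from the upstream tools'
exports.
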