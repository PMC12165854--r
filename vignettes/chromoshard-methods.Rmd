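---
title: "Models and methods behind chromoshard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromoshard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoshard)
```

`chromoshard` re-implements, as a tested pipeline, the computational
chain used to characterise chromothripsis-associated focal amplification
of chromosome 21q22 in blast-phase myeloproliferative neoplasms: from
raw breakpoint junctions and copy-number (CN) segments, through
complex-event classification, to cohort recurrence, clonal ordering and
candidate-gene prioritisation. This vignette documents the models, the
parameters that matter, the design choices made where the design was
genuinely open, and what the bundled simulator does and does not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The rearrangement model

A *derivative arrangement* describes the rearranged content of one
region of one chromosome on **one haplotype** — focal amplifications of
this kind are single-allele events, and the package models the second
allele as always intact. Fragments are 0-based half-open source
intervals in derivative order, each with an orientation and a
`copy_index` distinguishing repeated uses.

**Chromothripsis** (`simulate_chromothripsis`) cuts the region at
`n_breakpoints` uniform positions, retains each fragment independently
with probability `retention_prob`, shuffles the retained fragments
uniformly, inverts each with probability 1/2, and reattaches the result
between the intact flanks. The mechanism is described qualitatively in
the literature; uniform permutation with independent 50% inversion is
the maximum-entropy reading and makes the fragment-join test's null
(equal D/TD/HH/TT representation) true by construction. A draw retaining
zero fragments is rejected with a classed condition
(`chromoshard_degenerate_draw`). With `amp_multiplicity > 1` a
contiguous sub-block is emitted multiple times, modelling chromothripsis
with fragment amplification (the route by which a shattered chromosome
yields a high-CN core).

**Breakage–fusion–bridge** (`simulate_bfb`) iterates break–invert–
duplicate: each cycle breaks the current derivative, mirrors the
retained prefix onto itself (sister-chromatid fusion; a fold-back HH/TT
junction with co-located breakends) and thereby doubles copy counts. The
break is drawn uniformly on the **distal half** of the derivative. This
is a deliberate restriction: an unrestricted uniform break can excise
the amplified block, in which case the maximum copy number is *not*
monotone in cycle count. Breaking distal of the fold corresponds to the
dicentric bridge snapping between its two centromeres, and it makes two
properties theorems of the model: max CN ≤ 2ⁿ + (ploidy − 1), and max CN
non-decreasing in *n* at a fixed seed prefix. After the last cycle the
product is re-anchored to the distal flank; the stabilising rejoin
(telomere capture etc.) is abstracted into a single ordinary junction.

**Junction derivation** emits one junction per non-contiguous adjacent
fragment pair. Strand conventions follow the BEDPE dialect in which `+`
retains sequence left of the breakpoint (deletion `(+,-)`, tandem
duplication `(-,+)`, HH `(+,+)`, TT `(-,-)`). Every junction carries an
insertion length drawn uniformly from 0–6 bp — the short non-templated
scar of non-homologous end joining; templated insertions are
deliberately never emitted, matching the repair signature reported for
these events. **CN derivation** adds fragment coverage on the affected
allele to `ploidy − 1` and returns maximal constant-CN segments; a
per-base oracle in the test suite verifies copy-mass conservation
(Σ(CN − ploidy)·length = bases gained − bases lost) on 10-kb toys.

## 2. Clustering and the chance model

Junction clustering answers "are these SVs too close to be independent?"
With `N` breakends over a genome of length `G`, the probability that two
independent breakends fall within `d` is approximated by the
nearest-neighbour formula `p = 1 − exp(−2Nd/G)`. Clusters merge while
the closest pair (minimum same-chromosome breakend distance;
translocations bridge their two partner chromosomes) has `p < alpha`.
Because `p` is monotone in `d`, this agglomeration is single-linkage and
the fixpoint equals the connected components at
`d* = −G·log(1 − alpha)/(2N)`; the implementation uses a union–find over
sorted breakends, with deterministic tie-breaking by leftmost coordinate
then id. One candidate is tested per merge step, so no multiplicity
correction beyond `alpha` itself is applied.

This chance model is a documented re-derivation, not a claim of
bit-compatibility with published clustering tools, which use richer
joint models. Two consequences matter:

* `G` should be the **whole genome** (the null concerns genome-wide
  breakend density); `default_genome()` is therefore full GRCh38.
* At the default `alpha = 1e-3`, chains only survive when consecutive
  breakends sit well inside `G·alpha ≈ 3.1 Mb`; an isolated event's ~24
  breakends must therefore be focal. The canonical simulated event scale
  (`default_event_region()`, 200 kb) was chosen from this analytic
  constraint — a 20-breakpoint shatter of a multi-megabase region would
  be fragmented by this simplified null even though real tools (whose
  nulls condition on the full genome-wide SV complement) keep it
  together. Green round-trip tests therefore establish internal
  consistency of simulator and caller at the focal scale, not calibration
  against any published tool's cluster boundaries.

## 3. The four chromothripsis criteria

* **Cluster size** ≥ 5 junctions.
* **Fragment join** *p* ≥ 0.05: a goodness-of-fit test of the four
  intrachromosomal orientation counts against equal proportions
  (¼,¼,¼,¼). The quantity the original pipeline thresholds at 0.05 is
  not fully specified in print; reading it as the p-value of the
  equal-representation test is the interpretation implemented here
  (configurable threshold), because random rejoining predicts equal
  classes and a *high* p is then evidence for chromothripsis. Exact
  multinomial enumeration is used for n ≤ 40 (the p-value is the summed
  probability of outcomes no more probable than observed), chi-square
  with 3 df beyond; the two agree within 0.02 around the switch point.
* **Interleaving** ≥ 4: a junction is interleaved when its span crosses
  another's (exactly one breakend strictly inside — nesting and
  disjointness do not count). Counting is per junction, matching the
  "interleaved events" phrasing; the pairwise crossing count is exposed
  as an attribute for diagnostics.
* **CN oscillation**: longest run of consecutive segments in which every
  adjacent pair differs, using ≤ 2 states (run ≥ 4) or ≤ 3 states
  (run ≥ 5). Runs are measured in **segments**, not transitions (a
  transition count is always the segment count minus one, so the choice
  only shifts the threshold's meaning; segments match the printed
  thresholds). CN values are rounded to integers and segments shorter
  than `min_seg_len` (default 10 kb — array-scale resolution) are
  dropped first.

A cluster is *complex* at ≥ 3 junctions and *chromothripsis-like* when
≥ 3 criteria are met. When no CN data overlap the footprint the
oscillation criterion is **unknown and leaves the denominator** — the
verdict then needs all 3 remaining criteria. Counting unknown as failed
would make missing array data mimic evidence against chromothripsis;
the conservative rule was preferred and is visible in the call object
(`n_criteria_known`). Cluster size is treated as an ordinary criterion,
not a gate: the printed rule is "three of four", and making size
mandatory would be an undocumented strengthening.

Fold-backs are HH/TT junctions with breakends within `max_gap`
(default 5 kb; no published figure exists, and 5 kb comfortably covers
fold-back breakend pairs while excluding ordinary inversions).

## 4. Cohort analysis

CNA typing uses a symmetric ±0.5 CN margin around the baseline ploidy
(arrays report smoothed, purity-attenuated CN; 0.5 is half a copy and is
configurable); copy-neutral LOH additionally requires a *positive* LOH
flag — an unassayed flag (`NA`) can never produce a CNN-LOH call, which
is why segment I/O never silently converts missing LOH to `FALSE`.

A sample carries the amplification when ≥ 1 gain segment
(CN ≥ 2.5) overlaps the target region; its amplified intervals are the
union of such segments, excluding intervening normal-CN gaps of
oscillating profiles. The MAR is the **strict intersection** of those
unions across carriers. Whether the published MAR allowed boundary
tolerance is not stated; strict intersection is implemented, with
`min_support = k` as an escape hatch reporting the region amplified in
at least *k* samples when the full intersection is empty. Gene
membership defaults to full containment (matching "contained N genes"
semantics), with an overlap mode available.

The recurrence scan is explicitly a *GISTIC-like, simplified* stand-in:
per-bin amplification G-scores (`Σ max(0, log2(CN/2))`, overlap-
weighted) with an empirical null from per-sample, per-chromosome
circular shifts of the score track (offsets quantised to whole bins),
preserving each sample's within-chromosome segment structure. With ~3000
genome-wide bins, Benjamini–Hochberg q-values saturate unless `n_perm`
is large; rank bins by (p, score) when hunting the top peak. Lesion
associations use an in-package exact Fisher test (vectorised
hypergeometric; validated against full enumeration for every table with
N ≤ 40) plus the Pearson φ, with BH across pairs. CNA burden counts one
event per merged non-neutral run (gap ≤ 1 bp) outside chr21 and compares
groups by Wilcoxon rank-sum (exact for small untied groups).

## 5. Single cells and prioritisation

Clone sizes are apportioned by largest remainder, so stated fractions
are hit exactly at zero dropout; allele dropout (ADO) sets each call
independently to `missing` — it never fabricates wild-type calls, a
simplification relative to real single-cell genotyping where dropout of
the mutant allele masquerades as WT. Event ordering uses mutant-set
containment: lesion A precedes B when the fraction of B-mutant cells
lacking A (among cells informative for both) is ≤ the contradiction
tolerance (default 1%, absorbing residual dropout). Contradictory or
tied containment yields an *ambiguous* result with per-pair violation
counts, not an exception; only all-missing input raises
`chromoshard_insufficient_data`.

Expression follows a negative-binomial model (dispersion 0.5 — mid-range
for UMI-less single-cell counts) whose mean scales as
`(CN/2)^dosage_factor` for dosage-responsive genes; `dosage_factor = 1`
is pure dosage, and the amplified copy number defaults to 4 (the printed
carrier medians span ~3.5–6.5). Only 5 of the 24 panel genes respond to
dosage by default, emulating the observation that a minority of genes in
an amplified region are dosage-sensitive in expression. Allelic reads
for a SNP in an amplified gene are Binomial(depth, (CN−1)/CN) toward the
amplified allele. DE/DA model fitting itself (DESeq2-class) is
deliberately **not** re-implemented — those tables are inputs; the
package owns the integration rule (MAR membership ∧ DE-up ∧ significant
DA promoter peak, ranked by promoter then DE fold change) and, when no
promoter flag is provided, derives one from a TSS window of −2000/+500
bp (a common promoter definition; configurable).

The ASE test combines per-SNP two-sided exact binomial tests by
Stouffer's method on direction-signed z-scores (equal weights;
single-SNP genes keep their SNP p-value). At depth 30 the attainable
two-sided level of the binomial test is 0.043, so the calibration check
asserts a type-I rate near that discrete level rather than exactly 5%;
likewise the Fisher test is conservative by construction and its
empirical size under independence sits below nominal.

## 6. What the simulator emulates — and what a green test does not show

The generator reproduces the *statistical structure* of the motivating
study: a 64-sample cohort with 25% carriers of a 21q22 gain sharing a
planted 2.7-Mb core (carrier count exact by rounding, not Bernoulli), a
third of carriers amplified via chromothripsis and the rest via tandem
duplication, heavier non-chr21 CNA burden in carriers (Poisson means
6.5 vs 1.3, medians ≈ 6/1), TP53 alteration enriched in carriers, the
linear clonal hierarchy WT → JAK2 → JAK2+TP53 → +amp with clone
fractions 107/179/162/1455 of 1903, and dosage-driven expression with
allelic skew. It does **not** emulate: sequence context (no reads, no
microhomology), ecDNA or any circular structure, multi-allele events,
interchromosomal re-integration of lost fragments (an optional mode was
considered and dropped — it touches no downstream statistic in this
pipeline, and single-chromosome arrangements keep the CN algebra
exactly verifiable), array noise or purity attenuation, and clinical
covariates. Green tests therefore establish that the implementations
agree with their independent oracles and that the pipeline recovers
planted truth under its own generative assumptions — not that it
reproduces any published patient-level call set.

## 7. Numerical and reproducibility choices

* Coordinates are 0-based half-open internally; BED/BEDPE output is
  0-based, VCF breakends 1-based. Dialect conversion happens only at
  file boundaries and is its own inverse.
* Exact-test tie handling adds a 1e-9 relative tolerance when summing
  "no more probable" outcomes, protecting against floating-point ties.
* Every stochastic function takes one mandatory integer seed; derived
  child seeds stay below 2³¹. Identical configs give byte-identical
  pipeline outputs, and the run manifest (parameters + md5 checksums,
  no timestamps) is itself reproducible.
* Clustering tie-breaks (coordinate, then id) make cluster identities
  stable across runs.

## 8. Known limitations

The proximity null ignores the joint improbability of many co-located
breakends, so isolated broad events fragment at the default `alpha`
(section 2). The recurrence scan's bin-quantised circular-shift null is
coarser than semi-parametric recurrence callers and its q-values are
conservative at genome scale. Event ordering assumes a single linear
hierarchy per donor; branched clonal structures are reported as
ambiguous rather than reconstructed. The fragment-join reading of the
0.05 threshold is an interpretation (section 3) and is configurable for
users who prefer a different statistic.
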