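# chromoshard

Simulation and classification of chromothripsis-associated chromosome
amplification, modelled on the genomics of blast-phase myeloproliferative
neoplasms (BP-MPN).

Catastrophic chromosome shattering (chromothripsis) and
breakage–fusion–bridge (BFB) cycles can amplify a focal region of
chromosome 21q22, and the dosage of the genes inside the shared amplified
core — above all the kinase gene *DYRK1A* — is a candidate driver of
leukaemic transformation. Analysing such events end-to-end requires a
chain of small, well-defined computations: grouping breakpoint junctions
into clusters that are unlikely to co-locate by chance, scoring each
cluster against the four chromothripsis criteria, calling regional
amplification per sample, intersecting carriers' amplified intervals into
a minimally amplified region (MAR), tabulating single-cell clonal states
to order lesion acquisition, and filtering MAR genes by expression,
chromatin accessibility and allelic skew. `chromoshard` implements that
chain for R users, together with a ground-truth rearrangement simulator
so the whole pipeline can be exercised and validated without restricted
patient data.

## The statistics at the core

* **Junction clustering.** Breakends are points on the genome. With *N*
  breakends over genome length *G*, the chance that two independent
  breakends land within distance *d* is approximated by
  *p* = 1 − exp(−2*N·d*/*G*); clusters are merged while the closest pair
  satisfies *p* < α (default α = 10⁻³).
* **Chromothripsis-like classification.** A cluster is *complex* with ≥ 3
  junctions and *chromothripsis-like* when at least 3 of 4 criteria hold:
  ≥ 5 junctions; fragment-join goodness-of-fit *p* ≥ 0.05 (orientation
  classes D/TD/HH/TT equally represented, as random rejoining predicts);
  ≥ 4 interleaved (span-crossing) junctions; and a copy-number
  oscillation run of ≥ 4 segments between 2 states or ≥ 5 between 3
  states.
* **Fold-back inversions.** Intrachromosomal HH/TT junctions with
  breakends within 5 kb — the BFB hallmark.
* **Cohort statistics.** Gain/loss/CNN-LOH typing with a ±0.5 CN margin,
  MAR as the strict interval intersection across carriers, a simplified
  GISTIC-like permutation recurrence scan, exact Fisher lesion
  associations and Wilcoxon rank-sum CNA-burden comparison.
* **Single cells.** Exact 2×2×2 clonal state tabulation and event
  ordering by mutant-set containment with an allele-dropout tolerance.
* **Prioritisation.** Rank-sum single-cell DE screen, the
  DE ∩ DA-promoter integration rule, and binomial allele-specific
  expression tests against the dosage expectation (CN−1)/CN.

## Worked example

```r
library(chromoshard)

arr <- simulate_chromothripsis("chr21", default_event_region(),
                               n_breakpoints = 20, retention_prob = 0.5,
                               seed = 42, chrom_length = 46709983)
arr
#> <derivative_arrangement> chromothripsis on chr21:37500000-37700000 (11 fragment(s), one allele)

jx <- derive_junctions(arr, seed = 43)
table(classify_orientation(jx))
#>  D HH TD TT
#>  5  2  3  2

calls <- classify_sample(jx, derive_cn_profile(arr))
calls[, c("cluster_id", "n_junctions", "verdict", "n_criteria_met",
          "oscillation_run2", "frac_small_insertions")]
#>    cluster_id n_junctions             verdict n_criteria_met oscillation_run2
#> 1:       C001          12 chromothripsis_like              4                6
#>    frac_small_insertions
#> 1:                     1
```

Of the 21 shattered fragments, 11 were retained, shuffled and randomly
inverted; the 12 resulting junctions mix all four orientation classes
with short (0–6 bp) NHEJ-style insertion scars, cluster together, and
meet all four criteria (here a 6-segment two-state oscillation run), so
the event is called chromothripsis-like.

```r
cells <- simulate_single_cells(sim_params(seed = 1))$cells
tabulate_states(cells)
#> <clonal_states> 1659 usable cell(s), 244 unusable
#>   WT                     92
#>   JAK2                   152
#>   JAK2_TP53              141
#>   JAK2_TP53_chr21amp     1274
infer_event_order(cells)
#> <hierarchy_result> JAK2 -> TP53 -> chr21amp
```

At the default 5% allele dropout, 244 of 1903 cells are unusable, but
mutant-set containment still recovers the linear hierarchy: every
TP53-mutant cell is JAK2-mutant and every amplified cell is
JAK2/TP53-mutant, so the amplification is the last event.

## Command line

```sh
inst/cli/chromoshard run --config config.yaml --out results/ --seed 42
```

Subcommands `sim | cluster | classify | cohort | clones | prioritize |
run` all accept `--config` (JSON or YAML), `--out`, `--seed` and `-v`;
outputs include per-sample junctions/segments, per-cluster
chromothripsis calls, `mar.bed`, `recurrence.tsv`, `associations.tsv`,
`burden.tsv`, clone-state and event-order reports, ranked candidate
genes and a manifest with md5 checksums (identical configs reproduce
byte-identical outputs).

## BEDPE strand convention

Readers and writers use the dialect in which a breakend with strand `+`
retains the sequence to the **left** of the breakpoint, so after
normalisation a deletion is `(+,-)`, a tandem duplication `(-,+)`,
head-to-head inversion `(+,+)` and tail-to-tail inversion `(-,-)`.
Tools disagree on this; convert before importing junctions from callers
with the opposite convention.

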