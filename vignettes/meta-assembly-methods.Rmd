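---
title: "Meta-assembly of selection signatures: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-assembly of selection signatures: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepmeta)
```

## The model

sweepmeta aggregates published selection-signature calls — intervals (or
points) a study declared significant under some neutrality test — into a
consensus score per population. The model has three layers.

**DNA score.** Studies are not independent evidence when they genotype
the same animals. For study $i$ among the $k$ studies of an analysis
scope, with sample counts $n_i$ and pairwise shared counts $n_{ij}$,

$$d_i = \frac{1}{\sum_{j=1}^{k} \dfrac{n_{ij}}{n_i + n_j - n_{ij}}},$$

the reciprocal of the summed pairwise Jaccard sample overlaps. The sum
runs over all $k$ studies *including* $j = i$, whose term is always 1.
Self-inclusion is the only convention under which a fully independent
study gets exactly $d_i = 1$ (excluding it would divide by zero), and it
gives the natural limits: two studies on identical samples get $d = 1/2$
each, $m$ full re-uses $1/m$ each. $d_i$ is recomputed per analysis
scope — the same study can be weighted differently in a breed-wise and a
group-wise analysis, keyed by `scope_id`.

A deliberate simplification: only *shared-sample counts* enter. Partial
relatedness between different animals (half-sibs across studies, breed
structure) is not modelled; published scans rarely report enough to
estimate it.

**SNP score.** Reporting thresholds differ across studies (top 5% to
top 0.1% of various statistics). Result sets are bucketed into tiers
$s \in \{1, 2, 3\}$ for thresholds at the top 5%, 1% and 0.1%. The
buckets are half-open on the stringent side (`pct <= 0.1` → 3,
`0.1 < pct <= 1` → 2, `1 < pct <= 5` → 1): the three published anchors
fix the bucket values and the stringent-side closure makes the anchors
themselves unambiguous. Thresholds outside $(0, 5]$% are rejected rather
than extrapolated. Only percentage thresholds (or explicit tiers) are
accepted: mapping p-values or q-values onto tiers depends on the test's
null distribution and is the user's call, made *before* input, never
silently inside the IO layer. Each record then carries
$SS_{il} = d_i \times s_i \le 3$.

**Meta-selection-score.** At locus $l$,
$MSS_l = \sum_{i=1}^{k} SS_{il}$ over a sliding window centred on $l$.
Evaluation loci are the unique *reported positions* (`rep_pos`, the
top-score position, defaulting to the span midpoint rounded down) —
spans do not create loci, but any record whose span overlaps the window
contributes to it. These are two distinct roles and keeping them
distinct is what makes profiles sparse (one value per reported position)
yet complete (wide spans still count wherever they reach). Within a
window each study contributes only its maximum qualifying SS, so a study
reporting many overlapping intervals — or the same samples through
several tests — counts once. Multiple result sets of one study share one
$d_i$ (same samples); the per-study maximum is what prevents
double-counting, including when a study's breed-level and group-level
records are pooled into the same group analysis.

Since one fully independent top-tier study contributes at most 3,
**MSS strictly above 3** is the validation criterion: the signal cannot
come from a single study-equivalent. The threshold is a fixed analytic
constant of the scoring scheme, not a significance level; no null model
for MSS is attempted.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_bp` | 5,000,000 | bp | ~2.5 Mb each side of a locus; wide enough that studies localising the same sweep with different tests/panels co-align. 2 Mb is the fine-mapping alternative for densely studied populations. |
| `threshold` | 3 | MSS | the maximum single-study contribution; strictly exceeded means independent replication. |
| `min_studies` | 2 | studies | populations with a single study cannot be validated; the pipeline skips them (their records still count in group-level analyses). |
| `min_overlap_bp` | 1 | bp | regions sharing at least one base are grouped into a hotspot; abutting regions are not. |
| `scope` | breed | — | breed-wise analyses use `population_id` as the weighting scope; group-wise analyses pool all records of an archetype (breed- and group-level) and weight by archetype scope. |

## Coordinate harmonisation

Records on older assemblies are lifted onto the reference via marker
anchors: if a marker shared by both assemblies sits exactly at the
position, its target coordinate is used; otherwise the nearest shared
source marker (absolute bp distance) is used and the position *becomes
that marker's target coordinate* — deliberately no interpolation, since
panel-anchored published coordinates are only as precise as the nearest
marker anyway (offset-preserving interpolation exists behind
`interpolate = TRUE`). Ties go to the lower source coordinate, making
lifts deterministic. Start, end and reported position lift
independently; inverted endpoints are swapped and flagged, anchors on a
different target chromosome are allowed (assemblies do reassign
scaffolds) and flagged, and a record with any unmappable or
chromosome-inconsistent endpoint is dropped and logged rather than
approximated. Lifting is idempotent: marker positions are fixed points.
Chain-file liftover is out of scope by design.

## Numerical and degenerate-input choices

- Internal coordinates are 1-based inclusive everywhere; bedGraph output
  converts to 0-based half-open at the boundary, and BED gene input is
  converted on read. Windows are inclusive and clipped at chromosome
  ends, never wrapped.
- Peak boundaries are the first and last *loci* of a run with MSS > 3;
  an isolated qualifying locus yields a degenerate `start == end`
  region.
- Valley splitting: within a run, every internal strict local-minimum
  plateau of the locus-ordered MSS sequence is a cut; the left region
  ends at the plateau's first locus and the right region begins at its
  last, so single-locus valleys are shared boundary points and the
  pieces jointly cover the run. Equal-valued plateaus are one minimum.
  A run with a single maximum is returned intact.
- `pos_of_max` ties break to the lowest coordinate; per-study SS ties
  break to the earlier record; all outputs are sorted — the pipeline is
  invariant to input row order.
- Empty windows give MSS 0; empty inputs give empty (header-only)
  outputs and a manifest recording zero counts, not errors.
- Gene density counts a gene in *every* 1 Mb bin its span overlaps
  (midpoint assignment available behind a flag), so bin sums can exceed
  the gene count; with point genes they are equal.

**Window narrowing.** Shrinking the window can only shrink MSS at every
locus (fewer records qualify and per-study maxima cannot grow), so every
peak *cluster* (maximal run before valley subdivision) found at 2 Mb
lies inside a cluster found at 5 Mb. The package states and tests this
containment at cluster level: valley cut points move with the window
scale, so post-split sub-regions need not nest even though their parent
clusters always do.

## The synthetic corpus generator

`simulate_corpus()` emulates the *structure* of a published-scan corpus,
not genotypes: a panel of $k$ studies with block-structured sample
re-use (blocks of animals shared by sets of studies — mirroring
consortium-panel reuse and guaranteeing a feasible overlap matrix),
planted hotspots that each study detects independently with some
probability (span centred uniformly within the hotspot width), tiered
thresholds, and uniformly placed background signatures. All draws
follow one seed in a documented order, and outputs are byte-identical
across runs.

Defaults represent a scaled-down corpus: two 50 Mb chromosomes, ten
hotspots at 10 Mb spacing (about the hotspot density a genome-wide
cattle consensus map shows), hotspot width 1 Mb, log-normal span lengths
(median 1 Mb, sdlog 1, so spans run from sub-kb to tens of Mb),
detection probability 0.8 and a background of 0.05 spurious signatures
per Mb per study. The recovery benchmark (`benchmark_recovery()`) uses
ten independent top-tier studies over 50 seeds.

What the generator does *not* emulate — and what passing tests therefore
do not show about real corpora: linkage disequilibrium and correlated
test statistics between nearby loci, correlated detection across studies
sharing samples (sharing only affects the weights, not the simulated
calls), heterogeneous per-study genome coverage and panel density,
assembly errors, or curation noise beyond the invariant checks in the
readers. Recovery numbers on synthetic corpora are a check of the
scoring/calling machinery, not an estimate of field performance.

With provenance-labelled records, a validated region is counted as a
*false (background-only) region* when no hotspot-derived record
contributes to its MSS anywhere in the region; sensitivity counts a
planted hotspot as recovered when its centre ± width/2 interval overlaps
a validated region of its population by ≥ 1 bp.

## Problem sizes in the test suite

The suite cross-checks the vectorised MSS engine against a brute-force
reference on 200 seeded corpora (up to 500 records, 10 studies), the
segmentation against an exhaustive oracle on 1,000 random profiles (up
to 200 loci), and runs the 50-seed recovery benchmark; the whole suite
completes in a few minutes on one CPU. These sizes were chosen to cover
the combinatorics (plateaus, ties, degenerate spans, chromosome-end
clipping) densely while keeping the suite quick to iterate on.

## Known limitations

- Tier bucketing of non-percentile significance descriptions (p/q
  values) is the user's responsibility.
- The DNA score sees only shared-sample counts; pedigree overlap between
  distinct animals is invisible to it.
- Marker-anchored lifting cannot be better than the marker map; sparse
  maps coarsen coordinates, and unmappable records are dropped, not
  imputed.
- The validation threshold is analytic, not inferential: MSS has no
  p-value, and densely studied populations will validate more regions
  simply because more studies exist.
- Gene-density comparisons depend entirely on the annotation version
  supplied; the package treats them as descriptive context.
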