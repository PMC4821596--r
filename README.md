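# sweepmeta

Meta-assembly of selection signatures from published genome scans.

## The problem

Genome scans for selection signatures — regions where allele-frequency or
haplotype patterns depart from neutrality because of historical selection —
have been published for many livestock populations, using different tests
(F<sub>ST</sub>, iHS, XP-EHH, CLR, ROH, ...), different SNP panels,
different significance thresholds, and different reference assemblies.
Worse, many studies re-analyse the *same* DNA samples (consortium panels
are re-used constantly), so naively counting how often a region was
reported badly overstates the evidence. Conventional effect-size
meta-analysis cannot be applied to such outputs.

sweepmeta combines heterogeneous published scan *results* (not genotypes)
into a consensus per-population score track and calls validated hotspot
regions from it. It is aimed at researchers compiling published
selection-signature catalogues — in cattle or any other species — who want
a principled consensus map rather than a union of intervals.

## The method

For each study *i* in an analysis scope (a breed, or an archetype group of
breeds), with sample sizes *n<sub>i</sub>* and pairwise shared-sample
counts *n<sub>ij</sub>* over the *k* studies of the scope, the **DNA
score** down-weights repeated samples by the summed Jaccard overlap:

> d_i = 1 / Σ_{j=1..k} [ n_ij / (n_i + n_j − n_ij) ]

The sum includes the self term (always 1), so a fully independent study
has d<sub>i</sub> = 1, and two studies on exactly the same animals get
d = 1/2 each. The **SNP score** standardises reporting thresholds:
result sets declared at the top 5%, 1% and 0.1% of their test statistic
are weighted s = 1, 2, 3. Each published signature then carries a
weighted score **SS = d × s ≤ 3**.

The **meta-selection-score** at a locus *l* (every unique reported
position) is the windowed sum

> MSS_l = Σ_{i=1..k} SS_il

over a sliding window (5 Mb by default, i.e. ~2.5 Mb each side; 2 Mb for
fine mapping), where a signature qualifies if its span overlaps the
window and each study contributes only its highest qualifying SS.
Because one independent top-tier study contributes at most 3, **MSS > 3
means a region was detected more than once independently**: maximal runs
of loci with MSS strictly above 3 become validated regions, merged peaks
are split at the span of lowest MSS between them, and regions from
different populations are grouped transitively by overlap into hotspots,
classified *unique* (one population) or *shared*.

Coordinates from older assemblies are harmonised onto the reference by
the common-or-nearest shared marker, not by chain files, matching how
published tables anchored to SNP-panel markers are best reconciled.

## Worked example

Simulate a two-chromosome, eight-study corpus with planted hotspots and
two studies sharing half their animals, then run the scoring chain:

```r
library(sweepmeta)

cfg <- sim_config(seed = 7,
                  studies = data.frame(study_id = sprintf("S%02d", 1:8),
                                       n_samples = 100),
                  sharing = list(list(studies = c("S01", "S02"),
                                      n_shared = 50)))
sim <- simulate_corpus(cfg)
dir <- file.path(tempdir(), "corpus"); write_corpus(sim, cfg, dir)

genome  <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
sigs    <- read_signatures(file.path(dir, "signatures.tsv"), genome)
m       <- read_overlap_matrix(file.path(dir, "samples.tsv"),
                               file.path(dir, "overlaps.tsv"),
                               scope_id = "SIMPOP")
weights <- compute_study_weights(m)
head(weights, 3)
#>   study_id scope_id    d
#> 1      S01   SIMPOP 0.75
#> 2      S02   SIMPOP 0.75
#> 3      S03   SIMPOP 1.00
```

S01 and S02 share 50 of 100 animals, so each is down-weighted to
1/(1 + 50/150) = 0.75; the other six stay at 1.

```r
w    <- weight_signatures(sigs, weights, scope = "breed")
prof <- compute_mss_profile(w, genome, window_bp = 5e6)
prof
#> <mss_profile> SIMPOP: 101 locus/loci, window 5.0 Mb, max MSS 18.2
#>    chrom     pos mss n_studies
#> 1      1 2608725  10         6
#> 2      1 2625661  10         6
#> 3      1 4508705  16         8
#> ...

regions <- call_peaks(prof, threshold = 3)
head(regions[, 1:8], 3)
#>   population_id chrom    start      end max_mss pos_of_max n_studies n_loci
#> 1        SIMPOP     1  2608725  9362212   16.00    4508705         8     13
#> 2        SIMPOP     1 11168721 31467518   18.25   14407830         8     17
#> 3        SIMPOP     1 31467518 42566870   15.00   34043081         7     11

recovery_metrics(regions, sim$truth, prof)$pooled
#> $sensitivity
#> [1] 1
#> $false_fraction
#> [1] 0
```

All ten planted hotspots are overlapped by a validated region and no
called region is supported by background signatures alone. The max MSS
of 18.25 at 14.4 Mb reads as "about six independent top-tier
study-equivalents agree here" (8 studies, two down-weighted, mixed
tiers). `classify_regions()` then groups regions across populations into
unique/shared hotspots, and `run_pipeline()` / the `inst/cli/sweepmeta`
script chain every stage (lift → score → MSS → peaks → classify →
annotate) from TSV inputs to `regions.tsv`, `hotspots.tsv`, bedGraph
tracks and a JSON manifest of per-stage record counts.

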