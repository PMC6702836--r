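---
title: "Linking taxonomic and functional differentiation in shotgun metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking taxonomic and functional differentiation in shotgun metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxfunlink)
```

## The problem

Shotgun metagenomes of a host-associated microbial community -- here, the gut
microbiota of male and female ticks -- can be profiled along two independent
axes: *who is there* (taxonomic composition, e.g. genus-level abundance) and
*what they can do* (functional composition, e.g. abundance of EC/KEGG enzyme
annotations). The two axes need not move together. A gene function lost from
one genus may persist in the community because other genera carry it
(functional redundancy), and the genera that drive taxonomic differences
between groups need not be the genera that drive functional differences.

`taxfunlink` implements the full comparison pipeline: read QC, annotation
filtering and best-hit classification, abundance aggregation and
normalization, community statistics, exact differential-abundance tests, and
-- the analytical core -- the taxon-function linkage layer that connects
differentially abundant enzymes to the genera harboring them. A
synthetic-data generator with planted ground truth makes every stage
testable end to end.

## Pipeline model and assumptions

### Annotation records

The central input is a per-feature annotation table: one row per annotated
protein-coding feature per sample, carrying a hit count, alignment-quality
fields (e-value, percent identity, alignment length), a six-rank bacterial
lineage, and a four-level functional hierarchy whose leaf is the EC/KEGG
identifier. Taxonomic and functional annotations of the same read share a
row; the linkage join therefore never pairs a genus from one read with an
enzyme from another, which would inflate the apparent redundancy.

### Filtering and best-hit classification

Records are retained when e-value `<= 1e-5`, alignment length `>= 15` bp,
and percent identity reaches the mode-specific floor: 60% for taxonomic and
80% for functional profiling. All comparisons are inclusive on the keep side;
the cut-offs are conventionally stated without a direction of equality and
the inclusive reading is the one we fix and test. Non-bacterial domains
(eukaryote, archaeon, virus hits) are removed at this stage, *after* the
domain composition has been summarized, so the percent-bacteria bookkeeping
of an annotation run can still be reported.

Best-hit classification keeps one record per feature and sample: smallest
e-value, ties broken by largest identity, then longest alignment, then
lexicographically smallest subject identifier. The final tie-break makes the
reduction fully deterministic, which matters for byte-reproducible outputs.

### Read QC

Quality trimming follows the dynamic-trim idea with a budget formulation:
each read is trimmed to its longest contiguous window containing at most
`max_below = 5` bases under the Phred floor of 15, and reads whose best
window falls below `min_len` are discarded. The published description of
the trimming step does not pin down the algorithm; the
longest-admissible-window formulation is transparent, testable against a
brute-force all-windows oracle, and idempotent. `min_len = 50` bp and a
50 bp dereplication prefix are our defaults (the source workflow does not
state them); both are parameters of `qc_params()`. Dereplication keeps the
longest read among those sharing a prefix, first-encountered on ties.
Host-genome screening requires an external reference and aligner and is
deliberately not implemented; the QC driver records that the step was
skipped.

### Abundance and normalization

Counts aggregate by summing best-hit record hits at any lineage rank or
functional level; records missing the label pool into `unclassified`, so
totals are conserved. Size factors use the median-of-ratios estimator
(geometric-mean reference over features positive in all samples), rescaled
to geometric mean 1 so factors are comparable across runs.

One split we enforce explicitly: **exact tests always consume raw integer
counts**. Fisher's exact test is only defined for integers, so size-factor
normalization feeds ordination and heatmap-style outputs only. Upstream
descriptions of similar workflows apply normalization globally without
making this distinction; we document and test the split.

### Community statistics

* Expected rarefaction richness uses the closed-form hypergeometric
  expression evaluated with log-gamma terms, so large totals do not
  overflow; it is checked against Monte-Carlo subsampling and an
  independent reference implementation.
* Alpha diversity: the index behind the original summaries is not named, so
  both observed richness and Shannon entropy (natural log) are provided,
  with Shannon as the default report.
* Bray-Curtis dissimilarity and ANOSIM: the ANOSIM statistic uses mid-ranks
  for ties; the permutation p-value is one-sided with the
  `(exceedances + 1) / (n_perm + 1)` convention, and when the number of
  distinct label assignments is no larger than the permutation budget the
  full set is enumerated instead of sampled -- with six samples in two
  groups of three that is 20 assignments, so the smallest attainable p is
  fixed by design, not by sampling noise.
* PCA centers features across samples without unit-variance scaling
  (relative abundances are already on a common scale). The sign of each
  component is fixed by making its largest-magnitude loading positive.
* Venn partitions report exclusive intersection regions with percentages of
  the union, rounded to one decimal, for up to three sets.

### Differential abundance

Per-feature two-sample comparisons form the 2x2 table of feature hits
against all other hits in each sample. The two-sided Fisher p-value uses the
minimum-likelihood convention (sum of all margin-fixed tables no more likely
than the observed one), with a relative tie tolerance of `1e-12`; p-values
are floored at the smallest positive double so downstream step-up
adjustment stays in its domain. Benjamini-Hochberg adjustment is applied
within one comparison and one hierarchy level at a time -- the conservative
scoping when a global statement ("correction applied in all analyses")
leaves it open. Confidence intervals for the proportion difference use the
Newcombe-Wilson hybrid score method, the standard choice for exact-test
workflows.

Multi-group comparisons use one-way ANOVA with eta-squared
(`SSB / SST`) as effect size and Tukey-Kramer post hoc tests whose
p-values come from the studentized range distribution. A zero within-group
mean square with positive between-group variation is reported as an
infinite F with p = 0; an all-constant feature is degenerate and rejected
(the per-feature scanner reports it as F = 0, p = 1 instead of failing).

### The linkage layer

Given the set of enzymes differential at `q < 0.05`, the linkage layer
builds one edge per (enzyme, genus, group) with summed hits. From the edges:

* the **redundancy spectrum** counts, per enzyme, the number of distinct
  genera harboring it (pooled over groups -- one spectrum bar per enzyme,
  not per sex), binned as {1, 2--4, 5--10, >= 11}. Bin edges express the
  verbal classes "single genus", "a few", "five to ten", "widespread", and
  are configurable; the per-enzyme counts are always returned so any other
  binning can be recomputed. The ambiguity of "more than two" for the
  exactly-two case is resolved by exposing the raw counts.
* **genus contributions** give each genus its share of all linkage hits,
  its distinct-enzyme count and per-group split, plus the cumulative share
  of the top-k genera and the fraction of genera carrying exactly one
  enzyme.
* the **dual-role partition** intersects the genera with differential
  abundance against the genera providing differential functions, yielding
  taxonomic-only, functional-only and overlap (dual-role) classes.

Merged-group analyses (e.g. pooling two congeneric species per sex) sum
hits over the merged samples before any of the above; the redundancy
spectrum is invariant to that merging by construction.

## The synthetic-data generator

The generator stands in for the real sequencing data, which are not
recomputable at desk scale. Its defaults encode the study conditions the
pipeline is validated under:

* 3 host species, sexes `f`/`m`, one pooled sample per species and sex
  (6 samples) -- matching the single-pool-per-group design typical of
  field-collected tick metagenomes; replication `n_replicates > 1` is
  supported but not the default.
* 30 genera under a deterministic nested lineage spanning 2 phyla, so
  aggregation is exercised at every rank; heavy-tailed per-species base
  abundances (gamma weights, shape 0.7) mimic the dominance structure of
  real communities.
* 25 EC-style enzymes with spectrum targets 12% single-genus, 27% in five
  to ten genera, none in eleven or more, remainder in two to four --
  the redundancy structure reported for differential enzymes in tick gut
  microbiomes. Targets are realized by largest-remainder rounding, which
  makes small configurations exactly checkable; with 25 enzymes the
  realized bins are 3/15/7/0 (12%/60%/28%/0%).
* 5 affected genera, each fixed at base proportion 0.02 and given an
  8-fold sex effect. The affected genus receives proportion
  `base x fold` in its enriched sex and the unaffected mass is rescaled to
  the remainder, so the planted between-sex proportion ratio equals the
  fold change exactly. (Renormalizing the whole vector instead would
  shrink the realized ratio -- e.g. to about 5.9 for an 8-fold effect on a
  5% genus -- and make "planted fold change" a misnomer; the exact-ratio
  semantics is what the recovery tests assert.)
* 10,000 reads per sample, the order of magnitude of post-QC feature
  counts in the motivating datasets; 10% of reads functionally
  unannotated; 10% of records drawn from a "fail" population violating all
  annotation thresholds at once, so the filter removal count is known.

Genus-enzyme repertoires are sampled uniformly per enzyme at the planted
genus count; a repair pass then swaps uncovered genera into slots held by
multiply-covered ones, preserving every per-enzyme count (hence the
spectrum) while ensuring each genus carries at least one enzyme whenever
the total incidence allows -- without this, noiseless runs with
`p_unannotated_function = 0` could request a function from a genus that has
none.

The FASTQ generator plants exact QC outcomes: low-quality reads are
entirely below the Phred floor (so no admissible window reaches `min_len`),
replicates copy a kept read's prefix while being shorter (so the original
wins dereplication), and all other reads pass untouched. What the generator
does **not** emulate: sequence-level realism (no genomes, no alignments --
quality fields are distributional stand-ins), chimeras, contamination,
strain-level variation, or compositional covariance between genera. Passing
recovery tests therefore demonstrates correctness of the statistical
machinery under the stated model, not robustness to every artifact of real
sequencing data.

## Numerical choices

* Fisher tie comparison at relative tolerance `1e-12`; reference
  implementations use `1e-7`, and the two agree on the validation grids to
  `1e-8`.
* BH adjustment delegates to the standard step-up implementation; a manual
  step-up oracle pins its behavior in the tests.
* Studentized-range p-values come from the stock distribution function,
  verified against a `1e6`-draw Monte-Carlo simulation of the studentized
  range.
* Degenerate inputs fail loudly: empty margins give p = 1, all-zero
  columns and vectors are errors, infeasible spectrum targets (a positive
  bin that cannot fit in `n_genera`) are rejected at construction.
* Validation problem sizes: the null error-control study uses 200
  replicates of 100 features at 5,000 reads per sample; the power study
  uses 50 seeds at 20,000 reads per sample with one 8-fold genus at 5%
  base abundance; the oracle grid covers all 2x2 tables with cells up to 9
  (10^4 tables). These sizes give Monte-Carlo error well inside the
  asserted bounds.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
truth <- build_ground_truth(cfg)
sim <- simulate_annotation_tables(truth)

fun <- best_hit_classification(
  apply_annotation_filters(sim$annotations, mode = "functional"))
counts <- aggregate_counts(fun, "func_l4")
diff <- two_sample_feature_test(counts, "Sp1f", "Sp1m")

edges <- build_linkage_edges(fun,
  diff_enzymes = setdiff(diff$feature[diff$enriched_in != "none"],
                         "unclassified"))
redundancy_spectrum(edges)
genus_contributions(edges, top_k = 5)
```

The numbered drivers under `analysis/` run this workflow end to end on the
default synthetic dataset and write all tables under `results/synthetic/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch.

## Known limitations

* The pipeline consumes annotation tables; producing them (alignment
  against protein databases, taxonomic assignment) is upstream and out of
  scope, as is host-read screening.
* With one pooled sample per group, Fisher tests compare sequencing
  proportions, not biological replicates; at high depth even small
  compositional shifts -- including the mechanical shrinkage of unaffected
  genera when an affected genus expands -- reach significance. This is a
  property of the design, not of the implementation.
* The alpha-diversity index of the motivating analyses is unnamed there;
  our Shannon values are therefore not comparable to any published number.
* Venn percentages are rounded to one decimal per region, so they can sum
  to slightly off 100.
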