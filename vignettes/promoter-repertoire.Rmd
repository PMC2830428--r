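---
title: "Methods: promoter-repertoire association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-repertoire association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdiver)
```

## The question and the design

Many human genes carry several alternative promoters (APs): distinct
transcription-initiation regions within one locus, each with its own
cis-regulatory composition. `promdiver` tests whether a richer promoter
repertoire goes together with other gene-level properties — more frequent
differential expression, membership in disease or cancer-driver gene
sets, longer gene structure, higher duplicability, and higher degree in
a protein-interaction network.

The design is deliberately simple and uniform. Genes are binned into
four promoter classes (SP, AP2, AP3_4, AP5plus) and every trait is
compared across classes with the same fixed four-rung ladder:

1. pooled AP vs SP,
2. AP2 vs SP,
3. AP3_4 vs AP2,
4. AP5plus vs AP3_4.

Continuous traits use the Wilcoxon rank-sum test and are summarised by
class medians; boolean traits use Fisher's exact test on 2×2 tables and
are summarised by class percentages. The ladder order and labels are
fixed regardless of input order, so reports are comparable across runs.

## Defining promoters from TSS evidence

A promoter here is a cluster of experimentally supported TSS positions.
`cluster_tss()` clusters each gene's positions per strand and
chromosome with a **gap parameter of 500 bases** (units: genomic bases;
default 500). Two clustering dialects exist because gap-based clustering
is ambiguous at chain boundaries:

* `linkage` (default): single-linkage chaining — adjacent sorted
  positions join iff their distance ≤ gap. Order-independent and
  parameter-faithful; a run of 500-bp steps forms one cluster, however
  long.
* `window`: a new cluster opens when a position lies more than one gap
  beyond the current cluster's *first* position, bounding cluster width
  at the cost of chain splitting.

The boundary is inclusive (distance exactly 500 joins). Duplicate
positions are collapsed before clustering, since cDNA clone redundancy
should not change architecture. A gene with evidence on both strands
(or two chromosomes) is clustered per group and its counts summed, with
a warning: opposite-strand TSSs cannot share one promoter's directional
architecture. Coordinates are 0-based half-open BED throughout; a 1-bp
interval encodes each TSS base.

## The DER statistic

The Differential Expression Ratio of gene $g$ over a collection of
expression datasets is

$$\mathrm{DER}_g = \frac{\#\{\text{datasets where } g \text{ called DE}\}}
                       {\#\{\text{datasets where } g \text{ measured}\}} \in [0, 1].$$

DE calling itself is upstream of this package: the input is the
tri-state call matrix. Genes measured in fewer than
$\lceil f \cdot n_\mathrm{datasets} \rceil$ datasets are excluded
(default $f = 0.05$). The ceiling-with-≥ rule implements "at least 5%"
semantics on an integer count; with 476 datasets the threshold is 24.
Because "at least" could also be read with a floor at the boundary, an
absolute-count override (`measured_min_count`) is exposed. Genes absent
from the DE matrix are excluded from DER comparisons only — they keep
their promoter class and participate in every other analysis.

## Gene-structure metrics

Eight metrics are computed from BED12 models: genomic length (span),
CDS length (spliced), 5′ and 3′ UTR lengths, total exon and intron
lengths, exon and intron counts. Conventions that matter:

* **Representative transcript**: the longest of a gene's transcripts,
  by spliced (mature) length by default, since the length table concerns
  transcript structure; `longest = "span"` switches to genomic span.
  Ties break by larger span, then lexicographically smallest transcript
  id, so selection is deterministic.
* **UTR lengths** are genomic coordinate differences — on the plus
  strand, 5′ UTR = CDS start − transcript start and 3′ UTR = transcript
  end − CDS end, swapped on the minus strand. This is the transcription-
  boundary reading of UTR length; `utr_mode = "spliced"` counts exonic
  bases only.
* Non-coding transcripts (thickStart = thickEnd) report missing CDS/UTR
  fields but full genomic/exon/intron metrics, and are therefore part of
  length comparisons but not CDS/UTR comparisons.

Invariants enforced by construction and re-checked in the tests:
genomic = total exon + total intron; introns = exons − 1; reflecting a
model about any coordinate (with strand flip) changes no metric.

## Annotations, duplicability, and the network

Gene lists (disease, cancer-driver, duplicate, singleton) are plain
text, merged by set union where multiple sources exist. Duplicability is
**tri-state**: duplicate, singleton, or unknown; unknown genes are
excluded from duplicability denominators rather than counted as either
side. A gene listed as both duplicate and singleton is an input error.

All inputs must share one gene-identifier namespace; the pipeline does
no cross-database id mapping. If an input's overlap with the profiled
genes falls below 50%, the run stops and points at an id-mapping
problem rather than silently comparing mismatched cohorts.

The interaction network is cleaned before degree computation:
self-interactions dropped, orientation unified, duplicates collapsed.
Degree is the number of distinct partners. Genes absent from the edge
list get a **missing** degree by default (network coverage is partial;
comparisons should use mapped proteins only); `absent_degree = "zero"`
treats absence as isolation instead.

## The statistical core

Both tests are implemented from scratch and cross-checked in the test
suite against independent enumeration oracles and against
`fisher.test()` / `wilcox.test()`.

**Fisher's exact test** enumerates the hypergeometric distribution over
all tables with the observed margins, in log space (`lchoose`) so
margins in the tens of thousands do not overflow. The two-sided p-value
follows the point-probability rule: the total mass of tables whose
probability is at most the observed table's, within a relative
tolerance of 1e-7 to absorb floating-point noise at mass ties.

**Wilcoxon rank-sum** uses pooled midranks. For pooled $n \le 30$
without ties the p-value is exact, from the full null distribution of
the rank sum built by dynamic programming over ranks. Otherwise a
normal approximation with tie correction and a 0.5 continuity
correction is used (identical to `wilcox.test(exact = FALSE, correct =
TRUE)`). The approximation's worst-case absolute error against the
exact distribution, enumerated over every achievable statistic for
pooled sizes 11–30, is 0.039 (at $n_x = 2$, pooled 11); it shrinks
quickly with sample size and is irrelevant at cohort scale, where group
sizes are in the thousands.

Sidedness defaults to two-sided for both tests — the sign of every
association is left to the data — and is overridable. Raw p-values are
reported without multiplicity correction; the report states the number
of tests so readers can apply their own. Displayed p-values floor at
`<2.2e-16` (the conventional printed floor) while stored values keep
full precision. Percentages round half-up, not to even.

## The synthetic cohort generator

`generate_cohort()` emulates the five input kinds with planted
class-dependent effects, so that the whole chain — parsing, clustering,
filtering, testing — can be validated against known truth. Defaults are
the reference human cohort's conditions: 15,180 genes in classes
7,291 / 3,772 / 2,941 / 1,176; 476 expression datasets with per-cell
measurement probability 0.6 (so a typical gene is measured in ~285
datasets); DER class medians (0.50, 0.52, 0.54, 0.56); driver fractions
(2.9, 4.3, 6.2, 9.7)%; disease fractions (16.4, 19.9, 21.7, 26.6)%;
duplicate fractions (67, 74, 78, 85)%; total-intron length medians
(14,370 / 25,162 / 43,650 / 87,204 bases); mean degrees 6.5 (SP) and
10.5 (AP5plus).

Generative laws, and why:

* **TSS placement** is constructive, not statistical: cluster anchors
  are spaced 2,000 bases apart with within-cluster scatter ≤ 300 bases,
  so gap-500 clustering recovers the intended promoter count *exactly*
  — promoter-class recovery is a deterministic guarantee, letting every
  downstream discrepancy be attributed to the trait models.
* **DE rates** are Beta with the class target median and shared
  concentration 20 (α + β). Beta is the natural bounded unimodal law
  with two interpretable knobs; the median (not the mean) is matched,
  by root-finding on the Beta quantile, because medians are what the
  ladder summarises. Concentration 20 gives a per-class DER spread
  (s.d. ≈ 0.11) wide enough that classes overlap heavily, as real DER
  distributions do.
* **Lengths** are lognormal with class-specific scale calibrated so the
  class medians of total intron length reproduce the targets; exon
  counts are 1 + Poisson with class means (5, 8, 11, 16).
* **Degrees** are negative binomial (dispersion 1.0) — interaction
  degree is strongly overdispersed — realized as an edge list by
  configuration-model stub matching; an odd stub total is repaired by
  one extra stub. Only the two extreme class means are anchored to the
  reference values; the intermediate means (8.0, 9.0) are linear
  interpolations, not reference values. Note that a degree-0 gene
  cannot appear in an edge list, so under the default
  `absent_degree = "missing"` policy the recovered class means are the
  zero-truncated means (≈ 7.5 for a mean-6.5 geometric-tailed law).
* **Traits are independent given class.** The generator plants marginal
  class effects only; within a gene, DER, lengths, flags and degree are
  conditionally independent. Real genes correlate these traits (long
  genes are older, older genes are duplicated and connected), so the
  synthetic cohort validates each marginal analysis, not joint or
  partial-correlation claims.

Determinism: one master seed; each output component draws from a fixed
labeled substream (seed + fixed offset), so adding a component never
perturbs the others, and the same seed yields byte-identical files. A
JSON manifest of the true parameters accompanies every bundle.

## What the validation shows — and what it cannot

The test suite validates, at fixed seeds:

* clustering against a connected-components oracle on random inputs;
* both tests against exhaustive enumeration (all 2×2 tables with total
  ≤ 40; all rank assignments for pooled n ≤ 10) and against the stock R
  implementations;
* structure metrics against interval-arithmetic invariants on random
  models, and the BED12 reader against `rtracklayer`;
* end-to-end recovery on the full default cohort — exact class sizes,
  DER medians within ±0.01, flag fractions within three binomial
  standard errors;
* calibration under a null cohort (equal parameters in all classes,
  400 genes/class, 500 replicates): per-rung rejection at α = 0.05
  stays near nominal, in [0.03, 0.07].

Problem sizes were chosen to make these checks sharp but quick: the
full 15,180-gene cohort runs once; the null calibration uses the
generator's DE-rate law directly (1,600 genes per replicate) rather
than writing 500 file bundles.

Passing on synthetic data shows the pipeline computes what it claims on
inputs that obey its assumptions. It does not show that real TSS
evidence is unbiased (promoter catalogs over-represent well-studied
tissues), that real DE calls are exchangeable across datasets, that
promoter counts are measured without error, or that the traits'
real-world correlations leave the single-trait ladders confounder-free.
Promoter-rich genes are longer *and* older *and* better annotated;
any causal reading of a ladder needs designs beyond this package.

## Known limitations

* No cross-database identifier mapping: all inputs must already share a
  namespace.
* The ladder is a fixed contrast chain, not a trend test; no
  multiplicity correction is applied.
* UTR metrics follow transcription-boundary arithmetic by default,
  which counts intronic bases lying between the CDS and the transcript
  end; use `utr_mode = "spliced"` for mature-transcript UTRs.
* The configuration-model network has calibrated degrees but no
  clustering, modularity or assortativity structure.
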