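# promdiver

Association analysis between a gene's **alternative-promoter (AP)
repertoire** and its other genome-scale properties: differential-expression
frequency, disease and cancer-driver gene membership, gene-structure
length, duplicability, and protein-interaction degree.

Roughly half of human genes initiate transcription from more than one
promoter. `promdiver` is for computational biologists who want to ask, on
their own TSS evidence and gene-level annotations, whether promoter-rich
genes differ systematically from single-promoter genes — and to validate
that whole analysis chain on a synthetic cohort with known planted
effects before trusting it on real data.

## What it computes

**Promoter classes.** Each gene's experimentally supported transcription
start sites (TSS, BED6) are clustered per strand by single-linkage
chaining with a 500-bp gap (two adjacent sorted positions join iff their
distance ≤ 500; a fixed-window dialect is also available). The cluster
count *k* bins the gene into one of four classes:

| class | promoters |
|---|---|
| SP | 1 |
| AP2 | 2 |
| AP3_4 | 3–4 |
| AP5plus | ≥ 5 |

**DER.** From a tri-state gene × dataset matrix of differential-expression
calls (1 = DE, 0 = measured not-DE, NA = not measured), the per-gene
Differential Expression Ratio is

```
DER_g = (# datasets where g is DE) / (# datasets where g is measured)
```

with genes measured in fewer than ⌈5% × n_datasets⌉ datasets excluded.

**The comparison ladder.** Every trait is compared across classes with the
same fixed four rungs — AP (pooled) vs SP, AP2 vs SP, AP3_4 vs AP2,
AP5plus vs AP3_4 — using a from-scratch exact statistical core:
Wilcoxon rank-sum (exact enumeration up to pooled n = 30, tie- and
continuity-corrected normal approximation beyond) for continuous traits
(DER, lengths, degree), and Fisher's exact test (two-sided by the
point-probability rule, computed in log space) for boolean traits
(disease, cancer-driver, duplicate).

**Gene structure.** Eight metrics per gene from BED12 models of the
longest (spliced) transcript: genomic length, CDS length, 5′/3′ UTR
lengths (genomic-coordinate convention, strand-aware), total exon and
intron length, exon and intron counts.

**Synthetic cohort.** `generate_cohort()` writes all five input kinds
(TSS BED6, DE matrix, BED12 models, gene lists, edge list) for a seeded
cohort of 15,180 genes in classes of 7,291 / 3,772 / 2,941 / 1,176 with
planted class effects — DER medians (0.50, 0.52, 0.54, 0.56),
cancer-driver fractions (2.9–9.7%), disease fractions (16.4–26.6%),
duplicate fractions (67–85%), rising interaction degree and
length scaling — so the full pipeline can be validated end to end.

## Worked example

```r
library(promdiver)

cfg <- synthetic_config(seed = 42, class_sizes = c(400L, 300L, 200L, 100L),
                        n_datasets = 60L)
paths <- generate_cohort(cfg, file.path(tempdir(), "demo"))
report <- ap_analyze(tss = paths$tss, de_matrix = paths$de_matrix,
                     driver = paths$driver,
                     duplicate = paths$duplicate, singleton = paths$singleton)
print(report)
```

```
Alternative-promoter association report
  genes profiled: 1000 
  class sizes:    SP=400, AP2=300, AP3_4=200, AP5plus=100 
  DER medians:    SP=0.50, AP2=0.50, AP3_4=0.56, AP5plus=0.53 
  driver    %:    SP=4.0, AP2=5.3, AP3_4=6.0, AP5plus=5.0
  duplicate %:    SP=66.0, AP2=69.0, AP3_4=78.5, AP5plus=86.0
  skipped stages: disease, structure, degree 
```

The class sizes are recovered exactly from the TSS evidence by
clustering. At this small size the planted DER and driver gradients are
visible but noisy; `summary(report)` lists every ladder rung with its
test, group summaries and p-value, e.g.

```
 analysis            label     kind  n1  n2 summary1 summary2   p_value
      der         AP_vs_SP rank_sum 600 400   0.5263   0.5000 0.0002255
duplicate     AP3_4_vs_AP2   fisher 200 300  78.5000  69.0000 0.0238259
```

— pooled AP genes have a significantly higher DER than SP genes (rank-sum
p ≈ 2e-4), and the duplicate-gene percentage climbs with promoter count.
Stages without input files are reported as skipped, not failed.
`render_report(report, dir)` writes the per-analysis TSVs (including an
8-metric × 4-class median table when gene models are supplied) and a JSON
document; displayed p-values floor at `<2.2e-16` while stored values keep
full precision.

A thin command-line wrapper with the same options ships in
`inst/cli/promdiver.R` (`generate` and `analyze` subcommands).

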