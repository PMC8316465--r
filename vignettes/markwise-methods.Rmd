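---
title: "Methods: integrating histone-mark occupancy with expression, and calling super-enhancers"
author: "markwise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating histone-mark occupancy with expression, and calling super-enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markwise)
```

## The problem

In inflammatory liver disease, chemokine genes (the CXCL family among them)
are strongly induced, and their induction is coordinated by changes in the
chromatin around them: active histone marks (H3K4me3 at promoters, H3K4me1 and
H3K27ac at enhancers) rise, the Polycomb-associated repressive mark H3K27me3
falls, clusters of enhancers behave as super-enhancers, and distal elements
physically contact the promoters they drive. markwise implements the analysis
chain that connects these observations: two-condition differential expression,
TSS-window differential mark occupancy, a congruence classification linking
the two, ROSE-style super-enhancer calling, NF-κB-type motif scanning,
gene-set and regulator enrichment, and 4C/3C/ChIP-qPCR interaction
quantification. Every component runs end-to-end on a seeded synthetic study in
which the expected structures are planted, so each claim the pipeline makes is
checked against a known truth.

## Coordinate conventions

All internal coordinates are 0-based half-open (BED convention); GTF input
(1-based inclusive) is converted at the boundary. The TSS of a `-` strand gene
is `end - 1`, the last covered base. Multi-transcript genes collapse to the
first-listed TSS with a warning, since all downstream analysis is per gene.
Signal tracks are fixed-bin vectors of reads per bin with a library size;
reads-per-million (RPM) scaling is applied on demand, and windowed sums
prorate partial bins linearly so results do not depend on the bin size.

## Differential expression

`test_two_group()` implements a self-contained negative-binomial Wald test:

* **Normalization** — median-of-ratios size factors against the per-gene
  geometric-mean reference (genes with a zero in any sample are excluded from
  the reference). This is the standard count normalization and is verified in
  the tests against an independent reference implementation.
* **Dispersion** — a per-gene method-of-moments estimate
  $\hat\alpha = \max(0, (v - \mu)/\mu^2)$ from pooled within-group variances,
  shrunk toward a fitted mean-dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$
  with a prior weight of `prior_df = 10` residual degrees of freedom. The
  shrinkage stabilizes small-sample moment estimates without importing another
  engine's internals.
* **Test** — Wald statistic on the log2 fold change with a delta-method
  standard error from the NB variance $\mu + \alpha\mu^2$, referred to the
  standard normal; the reported point estimate uses normalized group means
  plus a 0.5 pseudocount. With the t reference at the naive degrees of
  freedom the test was markedly conservative under the null, while the normal
  reference together with moderate trend shrinkage calibrates close to the
  nominal level; the acceptance suite measures the type-I error at p < 0.05
  on a 2000-gene, 4 vs 4 null with NB(μ = 200, α = 0.1) across 500 replicates
  and requires it inside [0.035, 0.065].
* **Calls** — `classify_de()` labels a gene `up` when FDR ≤ 0.01 and
  log2FC ≥ 1.5, `down` symmetrically, otherwise `ns`. Note the threshold is on
  the **log2** scale: 1.5 log2 units is about a 2.8-fold change. All-zero
  genes are dropped before testing and before the BH correction.

## Differential occupancy and congruence

Occupancy is quantified in TSS windows (default ±2 kb; ±5 kb available for
broad aggregates), reconstructing window read counts from the replicate
tracks and re-using the NB-Wald engine. Two numerical choices matter:

* **Size factors come from the window counts (median-of-ratios), not from
  library sizes.** A strongly amplified region in one condition inflates that
  condition's library size and, under pure RPM normalization, makes every
  other window look depleted — a composition artifact that produced a clear
  excess of spurious "decreased" calls on the synthetic study. The reported
  `rpm_control` / `rpm_case` columns remain library-size RPM; the reported
  `log2_ratio` is the pseudocounted RPM ratio, and the p-value comes from the
  count model.
* **Peak-to-gene assignment** uses the peak summit when the narrowPeak file
  provides one, otherwise the midpoint, and takes the nearest TSS with ties
  broken toward the smaller coordinate (deterministic and verified against an
  exhaustive search).

A differentially expressed gene is **congruent** when at least one mark
changes concordantly at occupancy FDR ≤ 0.05 (a separate, looser knob than
the expression FDR, since mark changes are noisier): for an up gene, any
active mark increased or H3K27me3 decreased; mirrored for down genes.
Requiring agreement of *all* marks would be far stricter than the roughly
half-congruent fractions such integrations typically report, so the
"≥ 1 concordant significant mark" rule is the default and the count is a
documented knob (`min_supporting_marks`). Non-significant occupancy never
supports a call. Gene-body occupancy is not part of the default rule.

## Super-enhancer calling

The ROSE procedure with its published constants as defaults: peaks fully
contained within ±2.5 kb of a TSS are removed (containment, not overlap — the
convention of the original algorithm), the rest are stitched across gaps of
up to 12.5 kb, and stitched regions are scored by input-subtracted RPM,
floored at zero. For the cutoff the ranked signals are min-max scaled to the
unit square and the curve is cut at the first point where the forward
difference slope exceeds 1 — the discrete version of the "tangent with slope
one" geometry, chosen because it is exactly reproducible and directly
testable: the constructed vector `[1, 1, 1, 1, 10]` yields exactly one
super-enhancer, and the called set is invariant under scaling and shifting of
all signals. Ties in signal sort by (signal, chrom, start) so ranks are
deterministic. Degenerate inputs (fewer than three regions, or no signal
range) yield zero super-enhancers rather than an arbitrary cutoff.

## Motif scanning

Position probabilities are `(count + 0.8 · bg) / (colsum + 0.8)` — the
pseudocount split by background follows common JASPAR tooling — and entries
are log2-odds against the background. The **relative score**
`(raw − min) / (max − min)` operationalizes "> 95 % consensus": a threshold
of 0.95 on the min-max-scaled score. Scanning covers both strands (the
reverse strand via the reverse-complemented matrix on the forward sequence),
skips windows containing N, and reports 0-based half-open coordinates on the
forward strand. The scanner is validated window-by-window against a
brute-force rescorer.

## Enrichment

`gsea_es()` is the classic weighted running sum (hit increments
$|m|^p / \sum_{hits} |m|^p$, miss decrements $1/(N - N_h)$, ES = signed
maximum deviation; p = 1 by default). Significance uses a **gene-label**
permutation null per set size — the artifact consumes a ranking, not
sample-level data, so phenotype permutation is not available; this deviation
from sample-permutation GSEA is deliberate and documented. NES divides the ES
by the mean |ES| of same-sign permutations, the one-sided p carries a +1
continuity correction, and the FDR follows the sign-stratified NES procedure.
Over-representation is the right-tailed hypergeometric test with BH across
sets. The upstream-regulator activation z-score is the simplified unit-weight
form $z = (n_{conc} - n_{disc})/\sqrt{n_{conc} + n_{disc}}$ over informative
targets; the output labels this simplification, since the weighted commercial
variant is proprietary and unpublished.

## Viewpoint interactions

4C profiles mask the viewpoint fragment ±2 fragments (self-ligation and
undigested artifacts; the standard exclusion, exposed as `exclude_k`), scale
the remaining counts to one million (cis normalization), and fit a power-law
background $a \cdot d^{-b}$ by least squares of `log(count + 1)` on
`log(distance)` over unmasked positive-count fragments. The power law was
chosen over monotone splines because it has the fewest parameters and is
exactly recoverable in tests; note the `+1` regularizer biases the slope when
expected counts approach 1, so profiles should be scaled such that informative
fragments carry at least ~10 counts (the synthetic study's defaults do).
Enriched interactions are maximal runs of ≥ 3 consecutive fragments with
residual z ≥ 2, merged to intervals. 3C quantification normalizes each site
to a control locus (ratio 1 at the control by construction), and ChIP-qPCR
percent input is $100 \cdot 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$ with
input fraction $f$.

## The synthetic study

`simulation_config()` defaults describe the study design the recovery tests
assume: 4 control vs 5 case samples, 2000 genes on a single 10 Mb toy
chromosome, NB counts with mean 500 and dispersion 0.05, 5 % of genes planted
up and 5 % down at |log2FC| = 3, and half of the planted genes given
concordant promoter-mark changes (|log2| = 2 in amplitude, inverted for
H3K27me3). Promoter peaks are Gaussian (σ = 300 bp) on Poisson background;
enhancers are 1.5 kb peaks in a 15 % gene desert laid out deterministically:
isolated "typical" enhancers, three constitutive strong decoy clusters, and
one planted cluster of eight members that is amplified 3-fold in the case
condition — so the planted cluster outranks the decoys only when amplified,
reproducing a rank rise under stimulation. The 4C profile follows
Poisson(a·d⁻¹) over ~4 kb fragments with a 5-fold bump on six fragments over
the planted cluster in the case condition, and the promoter sequence around
the target gene carries three planted copies of the consensus GGGACTTTCC.
One global seed drives a fixed stream order (annotation, truth, counts,
tracks by mark then condition, 4C, sequence), so identical configs are
byte-identical.

What the generator does **not** emulate: GC and mappability bias, fragment
length effects, replicate-specific batch structure, mixtures of cell types
(the situation that dilutes super-enhancer signal in bulk tissue),
multi-chromosome genomes, and trans interactions. Passing recovery tests
therefore demonstrate internal correctness of the methods under their own
model assumptions, not robustness to the full messiness of real ChIP-seq.

## Problem sizes

Unit and property tests run on deliberately small instances (hundreds of
genes, 4 Mb genomes, ≤ 1000 permutations); the calibration check uses 500
null replicates of 2000 × 8 counts, and `scripts/acceptance.R` runs the full
default study (2000 genes, 10 Mb) plus a 100-replicate null calibration —
each chosen as the smallest size at which the measured quantity is stable to
the tolerance being asserted.

## Known limitations

* The DE engine supports exactly two groups; no covariates or multi-factor
  designs.
* Occupancy inference is TSS-window-based; peak-level differential binding
  and gene-body occupancy are not part of the congruence default.
* The 4C module fits a global decay; domain-aware backgrounds and replicate
  statistics are out of scope, so two-condition comparisons are descriptive
  (ratios), not inferential.
* Super-enhancer calling operates on one signal track per condition; a
  differential-SE statistic beyond rank comparison is not provided.
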