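---
title: "Characterising clonal heterogeneity from multi-omic tumour profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising clonal heterogeneity from multi-omic tumour profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonehet)
```

## The setting

A polyclonal tumour (here, a glioblastoma) is deconstructed into single
cells, each expanded into a clonal line. Together with the bulk tumour and a
matched normal from the same patient, the cohort is profiled on several
platforms: whole-genome sequencing (somatic SNVs/indels, structural
variants, allele-specific copy number), capture bisulfite sequencing (CpG
methylation), RNA-seq (expression), and SNP arrays (genotypes and LogR
intensity). `clonehet` implements the downstream analysis: it consumes
caller outputs (never re-implements alignment or calling) and asks how the
clones relate to one another and to the bulk.

The package's synthetic-cohort generator emits the same file formats with a
fully known clonal architecture, so every stage is testable against ground
truth.

## Models and procedures

### High-confidence somatic filter

Candidate variants carry per-sample read-level evidence. A call is
high-confidence when **all** of the following hold: control depth $\ge 8$;
tumour depth $\ge 12$; $\ge 5$ variant-supporting reads **and** $\ge 5$
distinct alignment start positions among them (duplicates sharing a start
are not independent support); the variant sits more than 5 bases from
either end of its supporting reads (scored on the minimum over supporting
reads); support on both strands; more than 5 bp from a mononucleotide run
of $\ge 7$ bases; and $< 3\%$ variant evidence in the control ($0.03$
itself fails). All rules are evaluated without short-circuiting so every
violated rule is reported, and a variant enters the cohort's
high-confidence set when it passes in at least one tumour sample. When a
`callers` column is present, only variants reported by $\ge 2$ callers are
eligible, mirroring a dual-calling strategy.

Two readings of the read-end and strand clauses are defensible (per
supporting read vs per variant aggregate); this package scores the
aggregate: the minimum read-end distance must clear the bound, and the
strand rule needs at least one forward and one reverse supporting read.

### VAF matrix and trunk/shared/private classification

For the union of high-confidence SNVs, pileup counts in every sample give
$\mathrm{VAF} = \text{alt}/\text{depth}$, with cells below a depth floor
(default 8) marked missing. A tumour-derived sample *carries* a variant
when $\mathrm{VAF} \ge 0.05$ and alt reads $\ge 3$ — the source study never
defines "shared by" operationally, so these conservative thresholds are
explicit, exposed parameters. Trunk = carried by every tumour-derived
sample; private = exactly one; shared = in between; variants carried by no
sample are reported separately as `absent` and excluded from percentages
(they cannot occur in a caller-derived set, but can under permissive
pileup thresholds). Percentages therefore always sum to 100.

SV records match across samples when type and chromosome pair agree and
both breakends lie within 100 bp (a free parameter; the study does not
state its matching rule); matching is closed transitively into events,
which are classified by the same trunk/shared/private rule.

### Copy number, WGD and aberrant fraction

State occupancy is the fraction of the assayed genome at each integer
total copy number. A sample is called whole-genome duplicated when the
CN 3–4 fraction is $\ge 0.5$: the motivating data show $> 84\%$ in WGD
clones versus $\le 3\%$ elsewhere, so any threshold in between works and
0.5 is the configurable default. Correction halves each segment with
round-half-up on both total and minor copy number, so odd states keep
their heterozygosity ($ (3,1) \to (2,1)$, never $(2,0)$); profiles are
never corrected twice. After any correction, a base is *aberrant* unless
its state is diploid heterozygous $(2,1)$; copy-neutral LOH is $(2,0)$
(while $(1,0)$ is deletion-LOH). Gene states use the majority-overlap
segment with ploidy 2 after correction and an amplification threshold of
total $\ge 6$.

### Methylation

$\beta = \text{methylated}/\text{total}$ with a minimum of 10 reads;
blacklisted (poor-accuracy) probes are dropped. The default stage order is
compute-$\beta$ → quantile normalise → filter/impute → top-1000 most
variable probes. The normalisation is missing-aware: each column's
available values are interpolated onto a common quantile grid, the
reference is the mean of those order statistics, and each present cell
maps to the reference at its within-column quantile (ties to the average
of tied reference values); on complete matrices this is exact quantile
normalisation, preserves within-sample rank order, and sorted columns
become identical. CpGs low-covered in $\ge 2$ samples are removed; a
single low-covered cell is imputed with the median of the remaining
samples. "Most variable" is defined by variance (the statistic is not
named in the source; median absolute deviation would be a defensible
alternative), with ties broken by probe id for determinism.

### Expression

Counts are scaled to counts-per-million by effective library size
(library size × TMM factor). TMM follows the published reference
algorithm: reference column chosen by the 75th-percentile rule, gene-wise
$M$ and $A$ values against it, double trimming (30% on $M$, 5% on $A$),
precision-weighted mean of the surviving $M$, and renormalisation of the
factors to geometric mean 1. The package authors its own implementation;
the test suite checks it against an independent implementation (edgeR) to
$10^{-6}$ on random negative-binomial matrices. Fold change versus the
normal cortex is $\log_2((t+1)/(c+1))$ on normalised values, flagged when
strictly above 2-fold. Variable genes are those with the largest absolute
loadings on PC1/PC2 of the gene-centred data ("contribution" is
operationalised as max absolute loading; the number kept, default 500, is
a free parameter). Heat-map export uses gene-wise z-scores of
$\log_2(x+1)$, and expression clustering uses Pearson-correlation
distance $1 - r$.

### SNP arrays

Genotype concordance is, per sample pair, the fraction of identical calls
among probes callable in both (missing calls are ignored, not penalised).
Variable LogR probes are those with cross-sample range strictly $> 0.3$
and strictly $< 1.5$; the bounds are strict per the source's wording, and
probes with any missing value are not candidates.

### Clustering

All dendrograms use complete-linkage agglomeration on Euclidean distance
(VAF, $\beta$, LogR) or correlation distance (expression). Missing VAF
cells are imputed as 0 before distances: in near-pure clonal lines,
absence of evidence at adequate pileup depth is evidence of absence; the
imputation value is a parameter. Samples are ordered lexicographically
internally so equal-distance merges resolve deterministically regardless
of input column order. Newick export is ultrametric via `ape`: node
heights are half the merge heights, so the cophenetic distance between two
samples equals the height at which they merge.

## The synthetic world

The generator's defaults mirror the motivating cohort: six clones plus
bulk tumour and matched normal; 8696 somatic SNVs (3490 trunk, 3492
private, the rest shared among clades); 83 SV events (10 trunk, 65
private); WGD in every clone but the first; ~68× depth; 10% of the genome
copy-neutral LOH; a miniature genome of 22 autosomes × 10 Mb. The bulk is
a uniform mixture of the clones (the study gives no clone proportions),
and clones split into two clades (the default topology bisects them),
which also drives clade-specific methylation, expression and LogR
structure.

Expected VAF is $m/C$: mutation multiplicity over total copy number at
the locus. Trunk/shared variants predate WGD, so on doubled segments
their multiplicity is 2 (VAF stays 0.5 on $(4,2)$, becomes $2/3$ on
$(3,1)$); private variants postdate WGD (VAF $1/4$ or $1/3$). The WGD
event doubles the *whole* genome: outside the trunk cnLOH region the WGD
clones sit at $(4,2)$ with post-WGD losses to $(3,1)$, and the cnLOH
region itself is doubled to $(4,0)$, which the correction restores to
$(2,0)$ — this is what makes the corrected aberrant fraction equal the
pre-WGD truth exactly. Reads are Poisson depths with binomial alt counts;
methylation is a bimodal Beta mixture with Poisson/binomial counts and a
forced low-coverage fraction; expression is negative-binomial with
planted $>2$-fold genes and varied library sizes; arrays share one
germline genotype with small miscall/missing rates.

Injected artifact candidates each violate exactly one labelled filter
rule while passing all others by construction, so per-rule rejection is
testable. Seven of the eight rules can be violated in isolation; an
"alt-support-only" artifact cannot exist because distinct starts cannot
exceed alt reads, so that rule is exercised by boundary tests instead.

One root seed feeds per-stage sub-streams, so adding or reconfiguring one
simulation stage never perturbs another, and equal seeds give
byte-identical outputs.

**What a green test does and does not establish.** The simulator emulates
clonal structure, sampling noise and the stated filter-violating artifact
classes. It does not emulate mapping artifacts, subclonal copy-number
mosaicism within a clone line, bisulfite conversion failure, batch
effects, or sequence-context realism beyond labelled homopolymer
distances. Recovery results (clustering ARI, WGD detection) are
statements about this stated world, not about arbitrary real cohorts.
With uniform bulk weights a clone-private variant has expected bulk VAF
$0.5/K$ (above the presence threshold for $K = 6$ at default depth), so
the bulk legitimately "carries" private variants; category-recovery and
clade-recovery checks are therefore evaluated over the clone samples,
with the bulk and normal excluded from the partition.

## Numerical choices and degenerate inputs

* Thresholds at boundaries follow the stated inequality direction
  exactly ("at least 5" passes at 5; "$<3\%$" fails at 0.03; WGD $\ge$
  threshold passes at the threshold; fold change "$>2$" fails at 2).
* Round-half-up (not banker's rounding) in the WGD correction, so
  heterozygosity is never destroyed.
* Quantile normalisation of a single-sample matrix warns and returns the
  input; a sample with no observed values is an error everywhere.
* Variance/loading ties break by feature id; equal-distance merges break
  by lexicographic sample order.
* `correct_wgd` refuses non-WGD profiles (unless forced) and refuses to
  run twice.
* Genes overlapping no segment are reported `missing`, never defaulted.

## Limitations

No subclonal deconvolution, cancer-cell-fraction estimation or phylogeny
inference beyond hierarchical clustering; no segmentation from raw
coverage; no differential-expression or differential-methylation testing;
no functional annotation. Pipeline configs are JSON rather than YAML (no
YAML parser is available in the supported dependency set; the schema is
unchanged).
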