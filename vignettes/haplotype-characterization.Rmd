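---
title: "Haplotype characterization of gene regions in germplasm panels"
author: "haplopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype characterization of gene regions in germplasm panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopanel)
```

## The analysis

`haplopanel` characterizes the haplotype diversity of a single gene or QTL
region across a germplasm panel and distills it into a handful of
assayable SNPs. The unit of analysis is the **allele vector**: the ordered
REF/ALT calls of one sample at every retained SNP of the region. Two
samples carry the same haplotype exactly when their vectors are identical.
This definition is deliberately naive — no phasing, no imputation, no
within-region recombination model — because the target material is inbred
germplasm where residual heterozygosity is noise, and because a breeder
needs group labels that are reproducible from raw calls.

The chain is: filter → group → tag → survey → associate.

## Filtering cascade

`apply_cascade()` applies five stages in a fixed order, each with a strict
comparator (boundary values are retained):

1. *Heterozygote recode* (optional): HET → MISSING. Inbred panels treat
   residual hets as unreliable calls.
2. *SNP missingness*: drop SNPs whose missing fraction, over all current
   samples, exceeds `snp_missing_max`.
3. *Sample missingness*: drop samples whose missing fraction, over the
   SNPs surviving stage 2, exceeds `sample_missing_max`.
4. *MAF floor*: drop SNPs with minor allele frequency strictly below
   `maf_min`. The MAF denominator is non-missing homozygous calls only —
   the only well-defined choice after the het recode.
5. *Monomorphic drop* (optional): a separate, reported stage for MAF
   exactly 0. With any `maf_min > 0` stage 4 already removes such SNPs;
   the stage exists so array-data parameterizations that state
   "monomorphic SNPs were omitted" report it explicitly.

Two presets bundle thresholds with a rare-haplotype rule:
`"3krgp"` (het recode, 0.2, 0.2, 0.001, rare = fewer than 30 samples) for
deep resequencing panels, and `"hdra-us"` (0.15, 0.2, 0.02, monomorphic
drop, rare = frequency below 0.05) for array data on a small elite panel.

The stage *order* matters and is part of the method: the MAF of a SNP can
collapse to zero once a high-missingness sample — its only ALT carrier —
is removed at stage 3. The test suite fixes this behaviour with a matrix
where swapping stages 3 and 4 changes the surviving SNP set.

A consequence worth stating: the cascade is one-pass, and one-pass
filtering is not idempotent in adversarial regimes. Removing samples at
stage 3 changes the denominators of stage 2's statistic, so re-filtering
an already-filtered matrix can, in principle, drop further SNPs whose
missingness sat exactly at the cap. At the missingness levels the
thresholds are designed for (a few percent per call against caps of
0.15–0.2) a second pass is a no-op, and the tests assert idempotence in
that regime; we chose not to iterate the cascade to a fixed point because
the published procedure it implements is explicitly single-pass and its
reported sample/SNP counts are single-pass counts.

## Haplotype grouping

`characterize_haplotypes()` groups complete-call samples by exact vector
identity. Groups satisfying the rare rule are named `Hap1..HapN` in
descending size; ties are broken by the allele vector itself (REF before
ALT) so output is permutation-invariant. Complete samples in
below-threshold groups form the rare set.

Samples with missing calls are assigned by *unique compatibility*: if the
non-missing calls match exactly one named group, the sample joins it; if
they match no named group but at least one observed rare vector, the
sample is rare; anything ambiguous is unclassified. Unique-compatibility
assignment is required for realistic data — with a 0.2 missingness cap a
large fraction of retained samples carry at least one missing call, and a
method that sent them all to Unclassified could never cover >90% of a
panel. After partial assignment, labels are re-ranked by final member
count so `Hap1` is always the most common group.

`survey_panel()` applies a *reference* partition to a new panel via a tag
set. It is stricter than `characterize_haplotypes()`: any heterozygous or
missing call at a tag SNP makes the sample unclassified (a het at a
single-SNP assay is real signal of non-inbred material, not noise to
impute around), and complete vectors matching no reference group are
reported as `NOVEL` with their vector rather than silently absorbed.

## Minimum discriminating SNP set

`minimum_tag_set()` treats tag selection as set cover over group pairs: a
SNP "covers" a pair when the two groups carry different alleles at it.
Exact mode first collapses SNPs that induce the same bipartition of the
groups into equivalence classes (a column and its complement cover the
same pairs), then enumerates subsets of class representatives by
increasing size starting at the information bound `ceil(log2 G)` for G
groups — the first cover found is provably minimum. At the scale this
analysis runs (≤ ~10 named groups, tens of SNPs collapsing to few
classes) exact search is instantaneous; `auto` mode falls back to the
classical greedy cover (pick the SNP covering the most unresolved pairs)
when the enumeration budget would be exceeded, reporting greedy's size as
an upper bound. Every returned set is re-verified by
`is_discriminating()`.

Tie-breaks are deterministic and breeder-oriented: among equally good
SNPs, lower genomic position wins, and a caller-supplied priority list
(e.g. a known functional SNP) is honoured among ties only — a preference
can never inflate the set size. Minimality here is a definition choice;
published "minimum SNP sets" selected by hand may legitimately differ in
size on the same data.

## Association and gene action

`anova_pve()` fits the one-way fixed-effects classification and reports
PVE = 100 · SS_between / SS_total — the unadjusted R², matching the
"explained X% of variation" reading. Replicate environment records (e.g.
two years) are averaged per line first: the line, not the plot, is the
unit. Pairwise significance letters come from Tukey HSD (`multcomp`), the
standard all-pairs procedure, at the caller's alpha; classes with a single
phenotyped sample stay in the means table but sit out the letters. Two
numerical notes: with zero residual variance the F statistic is reported
as infinite with p = 0 and letters fall back to distinct-mean grouping;
and because `multcomp`'s single-step adjusted p-values integrate a
multivariate t distribution by quasi-Monte-Carlo, the letter computation
pins a local RNG seed so identical inputs give byte-identical reports.

`classify_two_locus()` builds the interaction classes from one SNP per
locus given the long-allele orientation: the four-class scheme
(Class1 = long/long … Class4 = medium/medium) drops heterozygotes with a
reported count, as appropriate for inbred lines; the nine-class scheme
keeps them for segregating populations. `gene_action_report()` then reads
dominance off the nine classes: within each fixed state of the other
locus, it contrasts the heterozygous class against each homozygous class
using the pooled residual variance. A fully recessive long allele shows
het ≈ homo-medium and het < homo-long; both contrasts significant reads
as additive/partial dominance; neither significant yields an explicit
"insufficient evidence" call rather than a forced conclusion.

## Assay context extraction

`extract_flanks()` returns `upstream[REF/ALT]downstream` (default 100 bp
each side, giving a 205-character string for single-base alleles) from an
indexed FASTA, forward strand only — the coordinate systems these panels
use are forward-strand, and strand flips belong to assay design proper.
The reference base must equal the REF allele and positions near contig
edges are hard errors; no sequence is ever invented.

## The synthetic panel generator

`generate_panel()` exists so that every stage above is testable with known
truth. It emulates the *statistical* structure of a diversity panel:

- subpopulations drawn from fixed proportions, with per-subpopulation
  haplotype frequencies that are strongly skewed (each subpopulation has a
  predominant haplotype, as real panels do);
- rare haplotypes as single-position perturbations of common vectors,
  guaranteed distinct from every defined haplotype;
- per-call heterozygote injection followed by per-call missing injection,
  so a call can end missing regardless of het status;
- a two-locus phenotype: value = μ + effect(A) + effect(B) + N(0, σ),
  where the locus states are read from the post-het-injection causal-SNP
  calls. Dominance at locus A is configurable (`recessive-long` or
  `additive`); locus B is additive. Injected heterozygotes therefore carry
  genuine heterozygote phenotypes, which is what lets the nine-class
  gene-action analysis be validated against programmed truth.

`paper_like_preset()` fixes the study conditions used throughout the
tests: two regions with 8 and 9 defined haplotypes over 12 SNPs each
(vectors built from binary codes expanded through xor-derived columns, so
defined vectors are several substitutions apart); subpopulation
proportions of a 3K-style panel; rare rate 0.01, missing rate 0.03, het
rate 0.01 — realistic call-quality figures for resequencing-derived
matrices; μ = 6.0 mm, effect_A = 0.8 mm (recessive-long),
effect_B = 0.4 mm, σ = 0.25 mm, placing the four homozygous two-locus
class means at 7.2 / 6.8 / 6.4 / 6.0 mm with locus A's effect double
locus B's.

What the generator does **not** emulate: linkage disequilibrium decay,
within-region recombination, genotyping batch effects, multi-allelic
sites, or kinship structure beyond the subpopulation label. Passing
recovery tests on these panels therefore demonstrates correctness of the
algorithms under the stated model, not robustness to every artifact of
real array or resequencing data.

## Problem sizes and test design

The suite validates the tag-set search against an independent brute-force
subset enumeration on 200 random instances (≤ 8 groups × ≤ 12 SNPs),
checks greedy ≥ exact with both covers verified, and asserts the
information lower bound throughout. Parameter recovery runs five seeds of
the preset panel at n = 2000: haplotype-label recovery ≥ 95% after the
`"3krgp"` cascade, ANOVA PVE within 3 percentage points of the programmed
variance fraction, four-class means in the programmed order, and the
recessive-A contrast pattern reproduced. Determinism is asserted at the
byte level on all result tables; the only timestamp lives in the run
manifest. These sizes keep the whole suite under a minute on one CPU
while leaving Monte-Carlo margins (3 points on PVE, 95% on recovery) that
the programmed effects clear comfortably.

## Known limitations

- Haplotype groups are defined by exact identity, so a single genotyping
  error creates a new (rare) vector; the rare rule absorbs this at panel
  scale but per-sample labels near group boundaries are sensitive to call
  quality.
- Unique-compatibility assignment can, with heavy missingness, assign a
  partial vector that would be ambiguous at full resolution; the
  ambiguity rule only sees *observed* groups.
- PVE from one-way ANOVA ignores kinship and subpopulation confounding;
  in structured panels a haplotype's PVE conflates locus effects with
  background differentiation. That is the published estimand, and it is
  reported as such.
- The exact tag-set search guarantees minimality only over the supplied
  groups; adding a new haplotype to the reference can invalidate a
  previously minimal set (the survey stage will surface such samples as
  `NOVEL`).
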