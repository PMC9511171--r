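# haplopanel

Haplotype characterization and tag-SNP selection for crop germplasm panels.

## What problem this solves

Applied breeding programs need cheap, reliable single-SNP assays that track
the functional variation of a gene or QTL region across their germplasm. A
standard route — used for rice grain-shape loci such as *GS3* on chr3 and
grain-length QTL regions on chr7 — is:

1. pull the region's SNP matrix for a large diversity panel
   (resequencing or array data),
2. filter SNPs and samples on missingness and minor allele frequency,
3. collapse samples into **haplotype groups**: two samples share a
   haplotype iff their allele vectors are identical at every retained SNP,
4. find a **minimum SNP set** — the smallest SNP subset whose alleles
   differ between every pair of named haplotype groups — and convert those
   SNPs into KASP assays (a SNP plus ~100 bp of flanking sequence),
5. survey the haplotypes across the breeding panel with the tag SNPs and
   quantify haplotype–phenotype association.

`haplopanel` implements this chain as tested, reusable R functions, plus a
synthetic panel generator so every stage can be exercised without external
genotype downloads.

## Methods at a glance

- **Filtering cascade** (fixed order, strict comparators): heterozygote →
  missing recode; drop SNPs with missing fraction > cap; drop samples with
  missing fraction > cap over the surviving SNPs; drop SNPs with
  MAF < floor, where MAF = min(f_REF, f_ALT) over non-missing calls;
  optional monomorphic stage. Two presets: `"3krgp"` (0.2 / 0.2 / 0.001)
  and `"hdra-us"` (0.15 / 0.2 / 0.02 + monomorphic).
- **Haplotype grouping**: exact allele-vector identity for complete-call
  samples; rare rule by count (`min_count`) or frequency
  (`min_frequency`); samples with missing calls join a named group only if
  uniquely compatible, otherwise Rare/Unclassified.
- **Tag set**: minimum-cardinality discriminating set by exact
  increasing-size search over SNP equivalence classes (greedy fallback for
  large instances); always verified by `is_discriminating()`; size is
  bounded below by ceil(log2 #groups).
- **Association**: one-way fixed-effects ANOVA;
  PVE = 100 · SS_between / SS_total; Tukey HSD significance letters;
  two-locus four-class (inbred lines) and nine-class (segregating
  populations) analyses with gene-action contrasts (het vs each
  homozygote within fixed states of the other locus).
- **Assay context**: `upstream[REF/ALT]downstream` strings extracted from
  an indexed FASTA on the forward strand.

## Worked example

```r
library(haplopanel)

sim <- generate_panel(paper_like_preset(n_samples = 500, seed = 7))
flt <- apply_cascade(sim$matrices$GS3, filter_preset("3krgp")$filter)
part <- characterize_haplotypes(flt$matrix, rare_rule("min_count", 6))
part
#> HaplotypePartition: 494 samples, 12 SNPs, 8 named groups
#>   Hap1: n=185 (37.4%)
#>   Hap2: n=91 (18.4%)
#>   Hap3: n=68 (13.8%)
#>   ...
#>   Rare: 1  Unclassified: 1

minimum_tag_set(part$groups,
                snp_pos = setNames(part$snps$pos, part$snps$id))
#> TagSet: 3 SNP(s) [exact search]
#>   GS3_S2, GS3_S3, GS3_S4

cls <- part$assignments
cls[cls %in% c("RARE", "UNCLASSIFIED")] <- NA
anova_pve(sim$pheno, cls, alpha = 0.001, classification = "GS3 haplotype")
#> AssociationResult (GS3 haplotype): F = 136, p = 8.98e-110, PVE = 66.2%
```

The partition says: after filtering, 494 of 500 simulated samples remain
and collapse into eight named haplotype groups (Hap1 most common) plus one
rare and one unclassified sample. Three SNPs suffice to tell all eight
groups apart — those are the SNPs one would order as KASP assays. The
haplotype classification explains 66% of grain-length variance in this
panel; the letter column of the association table separates the long-grain
haplotype cluster (≈7.0–7.1 mm) from the medium-grain cluster
(≈6.2 mm) at p < 0.001.

The same stages are scriptable end to end:

```sh
Rscript inst/cli/haplopanel.R simulate --n 500 --seed 7 --out sim/
Rscript inst/cli/haplopanel.R pipeline --genotypes sim/GS3.tsv \
    --format snp_table --pheno sim/pheno.tsv --meta sim/meta.tsv --out out/
```

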