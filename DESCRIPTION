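Package: haplopanel
Title: Haplotype Characterization and Tag-SNP Selection for Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes SNP haplotype diversity of a gene or QTL region
    across crop germplasm panels. Implements the full analysis chain used in
    applied marker development: a missingness/minor-allele-frequency filtering
    cascade with an audit trail, haplotype grouping by exact allele-vector
    identity with rare and unclassified handling, selection of a minimum
    discriminating SNP subset (tag set) by exact set-cover search with a
    greedy fallback, surveying of reference haplotypes across new panels via
    the tag set, one-way ANOVA marker-trait association with percent variance
    explained and Tukey significance letters, two-locus genotypic class
    analysis including gene-action contrasts, and KASP-style flanking-sequence
    extraction. A synthetic germplasm-panel generator with
    subpopulation-skewed haplotype frequencies and a two-locus phenotype model
    supports testing of every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    multcomp,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
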