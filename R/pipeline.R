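# End-to-end orchestration: filter -> haplotype -> tag set -> survey ->
# association, with a run manifest (parameters, input checksums, package
# version). All result tables are deterministic given identical inputs;
# the timestamp lives only in the manifest.

#' Run the full haplotype-characterization pipeline on one region
#'
#' @param genotypes Path to the genotype file.
#' @param format `"vcf"` or `"snp_table"`.
#' @param pheno Optional path to a phenotype TSV (see [read_phenotypes()]).
#' @param meta Optional path to a sample-metadata TSV.
#' @param preset `"3krgp"` or `"hdra-us"` (see [filter_preset()]).
#' @param trait Phenotype trait name.
#' @param alpha Significance level for association letters.
#' @param tag_mode Tag-set search mode (see [minimum_tag_set()]).
#' @param out_dir Output directory, created if needed.
#' @return (Invisibly) a list with the filtered matrix, partition, tag set,
#'   survey partition and association result (the latter `NULL` without
#'   phenotypes).
#' @export
run_pipeline <- function(genotypes, format = c("vcf", "snp_table"),
                         pheno = NULL, meta = NULL, preset = "3krgp",
                         trait = "grain_length", alpha = 0.05,
                         tag_mode = "auto", out_dir = ".") {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- filter_preset(preset)

  m <- read_variant_matrix(genotypes, format)
  flt <- apply_cascade(m, pre$filter)
  write_filter_report(flt$report, file.path(out_dir, "filter_report.tsv"))

  meta_tab <- if (!is.null(meta)) read_sample_meta(meta) else NULL
  part <- characterize_haplotypes(flt$matrix, pre$rare)
  write_haplotype_report(part, meta_tab,
                         file.path(out_dir, "haplotypes.tsv"))
  write_group_defs(part, file.path(out_dir, "group_defs.tsv"))
  if (!is.null(meta_tab)) {
    comp <- composition_summary(part, meta_tab)
    con <- file(file.path(out_dir, "composition.tsv"), "w")
    writeLines(.comment_header("composition summary"), con)
    utils::write.table(comp, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }

  tagset <- NULL
  survey <- NULL
  if (length(part$groups) >= 2) {
    pos <- stats::setNames(part$snps$pos, part$snps$id)
    tagset <- minimum_tag_set(part$groups, mode = tag_mode, snp_pos = pos)
    write_tagset(tagset, part$groups, part$snps,
                 file.path(out_dir, "tagset.tsv"))
    survey <- survey_panel(flt$matrix, part$groups, tagset$snp_ids)
    write_haplotype_report(survey, meta_tab,
                           file.path(out_dir, "survey.tsv"))
  }

  assoc <- NULL
  if (!is.null(pheno) && length(part$groups) >= 2) {
    ph <- read_phenotypes(pheno, trait)
    cls <- part$assignments
    cls[cls %in% c("RARE", "UNCLASSIFIED")] <- NA
    assoc <- anova_pve(ph, cls, alpha = alpha,
                       classification = "haplotype group")
    write_association_report(assoc,
                             file.path(out_dir, "association.tsv"))
  }

  .write_manifest(out_dir, list(genotypes = genotypes, pheno = pheno,
                                meta = meta, preset = preset, trait = trait,
                                alpha = alpha, tag_mode = tag_mode))
  invisible(list(matrix = flt$matrix, filter_report = flt$report,
                 partition = part, tagset = tagset, survey = survey,
                 association = assoc))
}

.write_manifest <- function(out_dir, params) {
  inputs <- Filter(function(p) is.character(p) && file.exists(p) &&
                     !dir.exists(p), params)
  sums <- if (length(inputs))
    tools::md5sum(unlist(inputs)) else character(0)
  lines <- c(paste0("haplopanel_version\t",
                    as.character(utils::packageVersion("haplopanel"))),
             paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(params), function(k)
               paste0("param:", k, "\t",
                      if (is.null(params[[k]])) "" else
                        paste(params[[k]], collapse = ",")), character(1)),
             if (length(sums)) paste0("md5:", names(sums), "\t", sums))
  writeLines(lines, file.path(out_dir, "manifest.tsv"))
  invisible(NULL)
}
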