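# Readers/writers for the external representations the pipeline touches.
# Genotypes arrive either as VCF 4.x (GT field only) or as a "snp_table":
# a TSV whose first column is the sample id and whose remaining columns are
# markers, cells holding two-letter genotypes ("CC", "CA"), a single base,
# or a missing-data spelling ("N", "-", ".", "./.", ".|.").

.MISSING_SPELLINGS <- c("N", "NN", "-", ".", "./.", ".|.", "")

.comment_header <- function(what, params = character()) {
  c(sprintf("# %s | haplopanel %s", what,
            as.character(utils::packageVersion("haplopanel"))),
    if (length(params)) paste0("# ", names(params), " = ", params))
}

#' Read a genotype matrix from VCF or a SNP table
#'
#' Multi-allelic VCF records and indels never enter a [variant_matrix()]:
#' they are dropped with a warning reporting the count. Heterozygous calls
#' map to `"HET"`; `"N"`, `"-"`, `"."`, `"./."`, `".|."` and absent genotypes
#' map to `"MISSING"`.
#'
#' The snp_table dialect is tab-separated with a header row of marker names
#' and the sample id in the first column. Marker headers of the form
#' `id:chrom:pos:ref:alt` carry the variant metadata; bare marker names are
#' accepted, in which case the alleles are inferred from the observed calls
#' (major allele = REF) and positions default to the column index.
#'
#' @param path Path to the input file.
#' @param format `"vcf"` or `"snp_table"`.
#' @return A [variant_matrix()].
#' @export
read_variant_matrix <- function(path, format = c("vcf", "snp_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  if (format == "vcf") .read_vcf_matrix(path) else .read_snp_table(path)
}

.read_vcf_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- !multi & (!(toupper(fix$REF) %in% bases) |
                       !(toupper(fix$ALT) %in% bases))
  n_drop <- sum(multi) + sum(indel)
  if (n_drop > 0) {
    warning(sprintf("dropped %d non-biallelic-SNP record(s) (%d multi-allelic, %d indel/non-SNP)",
                    n_drop, sum(multi), sum(indel)))
  }
  keep <- !multi & !indel
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  samples <- colnames(gt)
  calls <- matrix("MISSING", nrow = length(samples), ncol = nrow(fix))
  gtt <- t(gt)                               # samples x variants
  gtt[is.na(gtt)] <- "./."
  gtt <- gsub("|", "/", gtt, fixed = TRUE)
  calls[gtt %in% c("0/0", "0")] <- "REF"
  calls[gtt %in% c("1/1", "1")] <- "ALT"
  calls[gtt %in% c("0/1", "1/0")] <- "HET"
  known <- gtt %in% c("0/0", "0", "1/1", "1", "0/1", "1/0", "./.", ".")
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop(sprintf("unsupported genotype '%s' for sample %s at marker %s",
                 gtt[!known][1], samples[bad[1]], ids[bad[2]]))
  }
  variant_matrix(samples,
                 data.frame(id = ids, chrom = fix$CHROM,
                            pos = as.integer(fix$POS),
                            ref = toupper(fix$REF), alt = toupper(fix$ALT),
                            stringsAsFactors = FALSE),
                 calls)
}

.parse_marker_headers <- function(hdr) {
  parts <- strsplit(hdr, ":", fixed = TRUE)
  if (all(lengths(parts) == 5L)) {
    m <- do.call(rbind, parts)
    return(data.frame(id = m[, 1], chrom = m[, 2], pos = as.integer(m[, 3]),
                      ref = toupper(m[, 4]), alt = toupper(m[, 5]),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = hdr, chrom = NA_character_, pos = seq_along(hdr),
             ref = NA_character_, alt = NA_character_,
             stringsAsFactors = FALSE)
}

.read_snp_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("snp_table needs a sample column and >=1 marker")
  samples <- trimws(tab[[1]])
  vars <- .parse_marker_headers(colnames(tab)[-1])
  raw <- toupper(trimws(as.matrix(tab[, -1, drop = FALSE])))
  calls <- matrix(NA_character_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- raw[, j]
    miss <- cell %in% .MISSING_SPELLINGS | grepl("N", cell, fixed = TRUE)
    first <- substr(cell, 1, 1)
    second <- ifelse(nchar(cell) >= 2, substr(cell, 2, 2), first)
    if (is.na(vars$ref[j])) {         # infer alleles from observed bases
      obs <- sort(table(c(first[!miss], second[!miss])), decreasing = TRUE)
      if (length(obs) > 2) {
        stop("marker ", vars$id[j], " has >2 observed alleles: ",
             paste(names(obs), collapse = ", "))
      }
      vars$ref[j] <- names(obs)[1]
      vars$alt[j] <- if (length(obs) == 2) names(obs)[2] else
        setdiff(c("A", "C", "G", "T"), names(obs)[1])[1]
    }
    ref <- vars$ref[j]; alt <- vars$alt[j]
    out <- rep("MISSING", length(cell))
    hom_ref <- !miss & first == ref & second == ref
    hom_alt <- !miss & first == alt & second == alt
    het <- !miss & ((first == ref & second == alt) |
                      (first == alt & second == ref))
    out[hom_ref] <- "REF"; out[hom_alt] <- "ALT"; out[het] <- "HET"
    bad <- !miss & !hom_ref & !hom_alt & !het
    if (any(bad)) {
      stop(sprintf("genotype '%s' for sample %s at marker %s matches neither ref (%s) nor alt (%s)",
                   cell[bad][1], samples[bad][1], vars$id[j], ref, alt))
    }
    calls[, j] <- out
  }
  variant_matrix(samples, vars, calls)
}

#' Write a genotype matrix as a SNP table
#'
#' Emits the tab-separated dialect understood by [read_variant_matrix()]
#' with `format = "snp_table"`: marker headers `id:chrom:pos:ref:alt` and
#' two-letter genotype cells (`"N"` for missing).
#'
#' @param x A `VariantMatrix`.
#' @param path Output path.
#' @export
write_snp_table <- function(x, path) {
  stopifnot(inherits(x, "VariantMatrix"))
  v <- x$variants
  hdr <- paste(v$id, v$chrom, v$pos, v$ref, v$alt, sep = ":")
  cell <- matrix("N", nrow(x$calls), ncol(x$calls))
  for (j in seq_len(ncol(x$calls))) {
    cj <- x$calls[, j]
    cell[cj == "REF", j] <- paste0(v$ref[j], v$ref[j])
    cell[cj == "ALT", j] <- paste0(v$alt[j], v$alt[j])
    cell[cj == "HET", j] <- paste0(v$ref[j], v$alt[j])
  }
  out <- cbind(sample_id = x$samples, as.data.frame(cell))
  colnames(out) <- c("sample_id", hdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Writes a plain-text VCF 4.2 with GT-only genotype fields (`0/0`, `1/1`,
#' `0/1`, `./.`). Intended for interchange of simulated panels; all sites
#' are biallelic SNPs by construction of the `VariantMatrix` type.
#'
#' @param x A `VariantMatrix`.
#' @param path Output path.
#' @export
write_vcf_matrix <- function(x, path) {
  stopifnot(inherits(x, "VariantMatrix"))
  v <- x$variants
  gt_code <- c(REF = "0/0", ALT = "1/1", HET = "0/1", MISSING = "./.")
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", gt_code[x$calls[, j]]), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a tab-separated file with a header row; column 1 is the sample
#' id, column 2 the trait value, and an optional column 3 an environment
#' tag (e.g. year). Rows whose value does not parse as a number are
#' rejected with a warning.
#'
#' @param path Input path.
#' @param trait One of `"grain_length"`, `"grain_width"`, `"lwr"`; values
#'   for the length/width traits are millimeters.
#' @return `data.frame` with columns `sample_id`, `trait`, `environment`,
#'   `value`.
#' @export
read_phenotypes <- function(path,
                            trait = c("grain_length", "grain_width", "lwr")) {
  trait <- match.arg(trait)
  if (!file.exists(path)) stop("cannot read phenotype file: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, comment.char = "#")
  if (nrow(tab) == 0) {
    warning("empty phenotype file: ", path)
    return(data.frame(sample_id = character(), trait = character(),
                      environment = character(), value = numeric()))
  }
  if (ncol(tab) < 2) stop("phenotype table needs sample and value columns")
  env <- if (ncol(tab) >= 3) trimws(tab[[3]]) else rep("", nrow(tab))
  val <- suppressWarnings(as.numeric(tab[[2]]))
  bad <- is.na(val) | val <= 0
  if (any(bad)) {
    warning(sprintf("rejected %d phenotype row(s) with unparseable or non-positive values",
                    sum(bad)))
  }
  out <- data.frame(sample_id = trimws(tab[[1]])[!bad], trait = trait,
                    environment = env[!bad], value = val[!bad],
                    stringsAsFactors = FALSE)
  key <- paste(out$sample_id, out$trait, out$environment, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate phenotype row for sample ",
         out$sample_id[duplicated(key)][1])
  }
  out
}

#' Read a sample metadata table
#'
#' Tab-separated with header; recognised columns are `sample_id`,
#' `subpopulation`, `grain_class` and optionally `release_year`.
#' Unrecognised subpopulation or grain-class values become `"unknown"`
#' with a warning.
#'
#' @param path Input path.
#' @return `data.frame` with one row per sample.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("cannot read metadata file: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, comment.char = "#")
  need <- c("sample_id", "subpopulation", "grain_class")
  if (!all(need %in% colnames(tab))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(sample_id = trimws(tab$sample_id),
                    subpopulation = trimws(tab$subpopulation),
                    grain_class = trimws(tab$grain_class),
                    release_year = if ("release_year" %in% colnames(tab))
                      suppressWarnings(as.integer(tab$release_year))
                    else NA_integer_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample id in metadata: ",
         out$sample_id[duplicated(out$sample_id)][1])
  }
  bad_sub <- !(out$subpopulation %in% .SUBPOPULATIONS)
  bad_cls <- !(out$grain_class %in% .GRAIN_CLASSES)
  if (any(bad_sub) || any(bad_cls)) {
    warning(sprintf("%d unrecognised subpopulation and %d grain-class values set to 'unknown'",
                    sum(bad_sub), sum(bad_cls)))
    out$subpopulation[bad_sub] <- "unknown"
    out$grain_class[bad_cls] <- "unknown"
  }
  out
}

#' Write a haplotype report
#'
#' One row per named haplotype group (descending size) with member count,
#' frequency among all partitioned samples, per-subpopulation counts and
#' the allele vector as bases, followed by `Rare` and `Unclassified` rows
#' (and `Novel` rows in survey mode). A `#`-prefixed header records the
#' partition parameters.
#'
#' @param partition A [characterize_haplotypes()] / [survey_panel()] result.
#' @param meta Sample metadata (`data.frame` as from [read_sample_meta()]),
#'   or `NULL`; samples absent from `meta` count as `"unknown"`.
#' @param path Output path.
#' @export
write_haplotype_report <- function(partition, meta = NULL, path) {
  stopifnot(inherits(partition, "HaplotypePartition"))
  total <- partition$n_samples
  subpop_of <- function(ids) {
    if (is.null(meta)) return(rep("unknown", length(ids)))
    sp <- meta$subpopulation[match(ids, meta$sample_id)]
    sp[is.na(sp)] <- "unknown"
    sp
  }
  subpops <- .SUBPOPULATIONS
  row_for <- function(label, ids, alleles) {
    sp <- table(factor(subpop_of(ids), levels = subpops))
    base_vec <- if (is.null(alleles)) "" else
      paste(.alleles_to_bases(alleles, partition$snps), collapse = "")
    c(group = label, n = length(ids),
      frequency = sprintf("%.8f", length(ids) / total),
      as.character(as.integer(sp)), allele_vector = base_vec)
  }
  rows <- list()
  for (g in partition$groups) {
    rows[[length(rows) + 1L]] <- row_for(g$label, g$members, g$alleles)
  }
  rows[[length(rows) + 1L]] <- row_for("Rare", partition$rare_samples, NULL)
  rows[[length(rows) + 1L]] <-
    row_for("Unclassified", partition$unclassified_samples, NULL)
  for (nv in partition$novel) {
    rows[[length(rows) + 1L]] <- row_for("Novel", nv$samples, nv$alleles)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("group", "n", "frequency", subpops, "allele_vector")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.comment_header("haplotype report",
                             c(n_samples = total,
                               rule = .rule_string(partition$rule))), con)
  utils::write.table(mat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-read a haplotype report written by [write_haplotype_report()]
#'
#' @param path Path to the report.
#' @return `data.frame` with columns `group`, `n`, `frequency` (plus the
#'   per-subpopulation counts and allele vector).
#' @export
read_haplotype_report <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  tab$n <- as.integer(tab$n)
  tab$frequency <- as.numeric(tab$frequency)
  tab
}

.alleles_to_bases <- function(alleles, snps) {
  i <- match(names(alleles), snps$id)
  ifelse(alleles == "REF", snps$ref[i], snps$alt[i])
}

.rule_string <- function(rule) {
  if (is.null(rule)) "none" else paste0(rule$mode, ":", rule$threshold)
}

#' Export/import haplotype group definitions
#'
#' Long-format TSV (`label`, `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#' `allele`, `base`) so that a reference partition derived from one panel
#' can be applied to any other panel via [survey_panel()].
#'
#' @param partition A `HaplotypePartition`.
#' @param path Output path.
#' @export
write_group_defs <- function(partition, path) {
  stopifnot(inherits(partition, "HaplotypePartition"))
  snps <- partition$snps
  rows <- do.call(rbind, lapply(partition$groups, function(g) {
    i <- match(names(g$alleles), snps$id)
    data.frame(label = g$label, snp_id = names(g$alleles),
               chrom = snps$chrom[i], pos = snps$pos[i], ref = snps$ref[i],
               alt = snps$alt[i], allele = unname(g$alleles),
               base = .alleles_to_bases(g$alleles, snps),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.comment_header("haplotype group definitions"), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_group_defs
#' @return `read_group_defs()`: a list of haplotype groups, each with
#'   `label` and named `alleles` vector, with the SNP metadata attached as
#'   attribute `"snps"`.
#' @export
read_group_defs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  groups <- lapply(split(tab, factor(tab$label, levels = unique(tab$label))),
                   function(d) {
                     list(label = d$label[1],
                          alleles = stats::setNames(d$allele, d$snp_id),
                          n = NA_integer_, members = character())
                   })
  groups <- unname(groups)
  snps <- unique(tab[, c("snp_id", "chrom", "pos", "ref", "alt")])
  names(snps)[1] <- "id"
  snps$pos <- as.integer(snps$pos)
  attr(groups, "snps") <- snps
  groups
}

#' Write an association report
#'
#' Per-class summary TSV (class, n, mean, sd, letter) with `#` header lines
#' carrying the F statistic, p value, percent variance explained, alpha and
#' the multiple-comparison procedure.
#'
#' @param result An [anova_pve()] result.
#' @param path Output path.
#' @export
write_association_report <- function(result, path) {
  stopifnot(inherits(result, "AssociationResult"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.comment_header("association report",
                             c(classification = result$classification,
                               F = format(result$F, digits = 8),
                               p = format(result$p, digits = 8),
                               pve = format(result$pve, digits = 8),
                               alpha = result$alpha,
                               letters = "Tukey HSD")), con)
  tab <- result$table
  tab$mean <- round(tab$mean, 4)
  tab$sd <- round(tab$sd, 4)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tag-set report
#'
#' Lists each selected SNP with its coordinates, the allele carried by each
#' haplotype group, and the number of group pairs the SNP separates.
#'
#' @param tagset A [minimum_tag_set()] result.
#' @param groups The haplotype groups the set discriminates.
#' @param snps SNP metadata `data.frame` (`id`, `chrom`, `pos`, `ref`,
#'   `alt`), e.g. `partition$snps`.
#' @param path Output path.
#' @export
write_tagset <- function(tagset, groups, snps, path) {
  stopifnot(inherits(tagset, "TagSet"))
  i <- match(tagset$snp_ids, snps$id)
  per_group <- vapply(groups, function(g) {
    paste(.alleles_to_bases(g$alleles[tagset$snp_ids], snps), collapse = "")
  }, character(1))
  pow <- vapply(tagset$snp_ids, function(s)
    distinguishing_power(s, groups), integer(1))
  tab <- data.frame(snp_id = tagset$snp_ids, chrom = snps$chrom[i],
                    pos = snps$pos[i], ref = snps$ref[i], alt = snps$alt[i],
                    pairs_separated = pow, stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(.comment_header("minimum discriminating SNP set",
                               c(method = tagset$method,
                                 size = tagset$size)),
               paste0("# group alleles: ",
                      paste(vapply(groups, `[[`, "", "label"), per_group,
                            sep = "=", collapse = " "))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
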