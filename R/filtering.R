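# SNP/sample filtering cascade. Stage order matters and is fixed:
#   1. recode HET -> MISSING (optional; inbred germplasm assumption)
#   2. drop SNPs with missing fraction  > snp_missing_max   (strict)
#   3. drop samples with missing fraction > sample_missing_max over the
#      SNPs surviving stage 2                               (strict)
#   4. drop SNPs with MAF < maf_min over non-missing calls of the
#      remaining samples                                    (strict)
#   5. optionally drop monomorphic SNPs (MAF exactly 0)
# All comparators are strict, so boundary values are retained.

#' Filtering-cascade parameters
#'
#' @param het_as_missing Recode heterozygous calls to missing before any
#'   thresholding (stage 1). Germplasm panels of inbred lines treat residual
#'   heterozygosity as unreliable.
#' @param snp_missing_max SNPs with missing-call fraction strictly greater
#'   than this are dropped (stage 2).
#' @param sample_missing_max Samples with missing fraction strictly greater
#'   than this, over the SNPs surviving stage 2, are dropped (stage 3).
#' @param maf_min SNPs with minor allele frequency strictly below this are
#'   dropped (stage 4); MAF is computed over non-missing calls only.
#' @param drop_monomorphic Drop SNPs with MAF exactly 0 as a separate,
#'   reported stage (stage 5).
#' @return A `FilterParams` list.
#' @seealso [filter_preset()] for the two published parameterizations.
#' @export
filter_params <- function(het_as_missing = TRUE, snp_missing_max = 0.2,
                          sample_missing_max = 0.2, maf_min = 0.001,
                          drop_monomorphic = FALSE) {
  stopifnot(snp_missing_max >= 0, snp_missing_max <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(het_as_missing = isTRUE(het_as_missing),
                 snp_missing_max = snp_missing_max,
                 sample_missing_max = sample_missing_max,
                 maf_min = maf_min,
                 drop_monomorphic = isTRUE(drop_monomorphic)),
            class = "FilterParams")
}

#' Preset filter/rare-rule bundles
#'
#' `"3krgp"`: the deep-resequencing panel regime — heterozygotes recoded to
#' missing, SNP and sample missingness caps of 0.2, MAF floor 0.001, no
#' separate monomorphic stage; rare rule = fewer than 30 samples.
#' `"hdra-us"`: the array-data regime restricted to a small elite panel —
#' SNP missingness cap 0.15, sample cap 0.2, MAF floor 0.02, monomorphic
#' SNPs dropped; rare rule = group frequency below 0.05.
#'
#' @param name `"3krgp"` or `"hdra-us"`.
#' @return List with elements `filter` ([filter_params()]) and `rare`
#'   ([rare_rule()]).
#' @export
filter_preset <- function(name = c("3krgp", "hdra-us")) {
  name <- match.arg(name)
  if (name == "3krgp") {
    list(filter = filter_params(TRUE, 0.2, 0.2, 0.001, FALSE),
         rare = rare_rule("min_count", 30))
  } else {
    list(filter = filter_params(TRUE, 0.15, 0.2, 0.02, TRUE),
         rare = rare_rule("min_frequency", 0.05))
  }
}

#' Minor allele frequency of a call vector
#'
#' The lesser of the REF and ALT allele frequencies over non-missing calls.
#' Heterozygous calls never contribute (the cascade recodes them before MAF
#' is evaluated; any remaining HET is excluded from the denominator).
#'
#' @param calls Character vector of calls in
#'   `c("REF","ALT","HET","MISSING")`.
#' @return The MAF, in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(calls) {
  n_ref <- sum(calls == "REF")
  n_alt <- sum(calls == "ALT")
  n <- n_ref + n_alt
  if (n == 0) stop("MAF undefined: no non-missing homozygous calls")
  min(n_ref, n_alt) / n
}

.stage_row <- function(stage, sb, sa, nb, na_) {
  data.frame(stage = stage, snps_before = sb, snps_after = sa,
             samples_before = nb, samples_after = na_,
             stringsAsFactors = FALSE)
}

#' Apply the filtering cascade
#'
#' Runs the five-stage cascade (see [filter_params()]) in its fixed order
#' and records an audit trail: one row per stage with SNP/sample counts
#' before and after, so every dropped SNP or sample is attributable to
#' exactly one stage.
#'
#' @param m A [variant_matrix()].
#' @param params A [filter_params()] object.
#' @return List with elements `matrix` (the filtered `VariantMatrix`) and
#'   `report` (the per-stage `data.frame`).
#' @export
apply_cascade <- function(m, params = filter_params()) {
  stopifnot(inherits(m, "VariantMatrix"), inherits(params, "FilterParams"))
  if (length(m$samples) == 0 || nrow(m$variants) == 0) {
    stop("cannot filter an empty matrix")
  }
  calls <- m$calls
  report <- .stage_row(character(0), integer(0), integer(0), integer(0),
                       integer(0))
  note <- function(stage, sb, nb) {
    report <<- rbind(report, .stage_row(stage, sb, ncol(calls), nb,
                                        nrow(calls)))
  }

  if (params$het_as_missing) {
    sb <- ncol(calls); nb <- nrow(calls)
    calls[calls == "HET"] <- "MISSING"
    note("het_to_missing", sb, nb)
  }

  sb <- ncol(calls); nb <- nrow(calls)
  miss_frac <- colMeans(calls == "MISSING")
  calls <- calls[, miss_frac <= params$snp_missing_max, drop = FALSE]
  note("snp_missingness", sb, nb)
  if (ncol(calls) == 0) stop("empty result: all SNPs dropped at stage snp_missingness")

  sb <- ncol(calls); nb <- nrow(calls)
  samp_frac <- rowMeans(calls == "MISSING")
  calls <- calls[samp_frac <= params$sample_missing_max, , drop = FALSE]
  note("sample_missingness", sb, nb)
  if (nrow(calls) == 0) stop("empty result: all samples dropped at stage sample_missingness")

  sb <- ncol(calls); nb <- nrow(calls)
  maf <- apply(calls, 2, function(cc) {
    if (!any(cc %in% c("REF", "ALT"))) return(0)
    minor_allele_frequency(cc)
  })
  calls <- calls[, maf >= params$maf_min, drop = FALSE]
  maf <- maf[maf >= params$maf_min]
  note("maf", sb, nb)
  if (ncol(calls) == 0) stop("empty result: all SNPs dropped at stage maf")

  if (params$drop_monomorphic) {
    sb <- ncol(calls); nb <- nrow(calls)
    calls <- calls[, maf > 0, drop = FALSE]
    note("monomorphic", sb, nb)
    if (ncol(calls) == 0) stop("empty result: all SNPs dropped at stage monomorphic")
  }

  out <- variant_matrix(rownames(calls),
                        m$variants[match(colnames(calls), m$variants$id), ,
                                   drop = FALSE],
                        calls)
  list(matrix = out, report = report)
}

#' Write a filter report
#'
#' @param report The `report` element of an [apply_cascade()] result.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.comment_header("filter cascade report"), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
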