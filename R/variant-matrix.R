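# Core container: a sample x SNP allele-call grid for one genomic region.
# Calls are one of "REF", "ALT", "HET", "MISSING"; only biallelic SNPs enter.

.CALL_LEVELS <- c("REF", "ALT", "HET", "MISSING")

.SUBPOPULATIONS <- c("aus", "indica", "indica-admix", "japonica-admix",
                     "tropical-japonica", "temperate-japonica", "aromatic",
                     "admix", "unknown")

.GRAIN_CLASSES <- c("long", "medium", "short", "unknown")

#' Construct a variant matrix
#'
#' A `VariantMatrix` holds the genotype calls of one gene/QTL region: an
#' ordered set of samples, an ordered set of biallelic SNPs, and a
#' sample-by-SNP grid of allele calls coded `"REF"`, `"ALT"`, `"HET"` or
#' `"MISSING"`. It is the object every pipeline stage transforms.
#'
#' @param samples Character vector of unique sample identifiers.
#' @param variants `data.frame` with columns `id` (unique marker name),
#'   `chrom`, `pos` (1-based coordinate), `ref` and `alt` (single IUPAC
#'   bases, distinct).
#' @param calls Character matrix, `length(samples)` rows by `nrow(variants)`
#'   columns, with entries in `c("REF","ALT","HET","MISSING")`.
#' @return An object of class `VariantMatrix`.
#' @examples
#' vm <- variant_matrix(
#'   samples  = c("s1", "s2"),
#'   variants = data.frame(id = "snp1", chrom = "chr3", pos = 100,
#'                         ref = "C", alt = "A"),
#'   calls    = matrix(c("REF", "ALT"), nrow = 2)
#' )
#' dim(vm)
#' @export
variant_matrix <- function(samples, variants, calls) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    stop("variants must have columns: ", paste(req, collapse = ", "))
  }
  variants <- as.data.frame(variants)[, req]
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant ids")
  }
  if (any(!is.na(variants$pos) & variants$pos < 1L)) {
    stop("variant positions must be >= 1")
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt allele identical for: ",
         paste(variants$id[variants$ref == variants$alt], collapse = ", "))
  }
  calls <- as.matrix(calls)
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(variants)) {
    stop("calls grid is ", nrow(calls), "x", ncol(calls),
         " but expected ", length(samples), "x", nrow(variants))
  }
  mode(calls) <- "character"
  bad <- !(calls %in% .CALL_LEVELS)
  if (any(bad)) {
    stop("invalid allele calls: ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  dimnames(calls) <- list(samples, variants$id)
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "VariantMatrix")
}

#' @export
dim.VariantMatrix <- function(x) dim(x$calls)

#' @export
print.VariantMatrix <- function(x, ...) {
  cat(sprintf("VariantMatrix: %d samples x %d SNPs\n",
              length(x$samples), nrow(x$variants)))
  if (nrow(x$variants) > 0) {
    cat(sprintf("  region: %s:%s-%s\n", x$variants$chrom[1],
                format(min(x$variants$pos)), format(max(x$variants$pos))))
  }
  tab <- table(factor(x$calls, levels = .CALL_LEVELS))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Subset a variant matrix
#'
#' @param x A `VariantMatrix`.
#' @param samples Optional character vector of sample ids to keep (in the
#'   given order).
#' @param snps Optional character vector of variant ids to keep.
#' @return A `VariantMatrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "VariantMatrix"))
  keep_s <- if (is.null(samples)) x$samples else samples
  keep_v <- if (is.null(snps)) x$variants$id else snps
  if (!all(keep_s %in% x$samples)) {
    stop("unknown samples: ",
         paste(setdiff(keep_s, x$samples), collapse = ", "))
  }
  if (!all(keep_v %in% x$variants$id)) {
    stop("unknown SNP ids: ",
         paste(setdiff(keep_v, x$variants$id), collapse = ", "))
  }
  variant_matrix(keep_s,
                 x$variants[match(keep_v, x$variants$id), , drop = FALSE],
                 x$calls[keep_s, keep_v, drop = FALSE])
}
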