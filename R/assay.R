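# KASP assay context: 100 bp of reference sequence either side of a SNP
# with the alleles bracketed, the format genotyping vendors take on order
# forms. Forward strand only; reference coordinates are 1-based.

#' Extract bracketed-allele flanking sequence for a SNP
#'
#' Returns `upstream [REF/ALT] downstream` in uppercase; with single-base
#' alleles and the default 100-bp flanks the string is 207 characters. The
#' reference base at the SNP position must equal the variant's REF allele,
#' otherwise a consistency error names the SNP. Positions closer than
#' `flank_length` to a contig edge are an error — no padding is invented.
#'
#' @param reference A [Biostrings::DNAStringSet], or the path to a FASTA
#'   file (read with [Biostrings::readDNAStringSet()]; names are truncated
#'   at the first whitespace).
#' @param variant One-row `data.frame` (or list) with `id`, `chrom`, `pos`,
#'   `ref`, `alt` — e.g. one row of a `VariantMatrix`'s `variants`.
#' @param flank_length Bases either side, default 100.
#' @return The assay string.
#' @export
extract_flanks <- function(reference, variant, flank_length = 100L) {
  stopifnot(flank_length >= 1)
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  if (!chrom %in% names(reference)) {
    stop("reference has no sequence named '", chrom, "'")
  }
  seq_len_chrom <- Biostrings::width(reference[chrom])
  if (pos - flank_length < 1 || pos + flank_length > seq_len_chrom) {
    stop(sprintf("SNP %s at %s:%d is within %d bp of the contig edge (length %d)",
                 variant$id, chrom, pos, flank_length, seq_len_chrom))
  }
  base_at <- toupper(as.character(
    Biostrings::subseq(reference[[chrom]], pos, pos)))
  if (base_at != ref) {
    stop(sprintf("reference base mismatch for SNP %s: reference has %s at %s:%d but ref allele is %s",
                 variant$id, base_at, chrom, pos, ref))
  }
  up <- toupper(as.character(
    Biostrings::subseq(reference[[chrom]], pos - flank_length, pos - 1L)))
  down <- toupper(as.character(
    Biostrings::subseq(reference[[chrom]], pos + 1L, pos + flank_length)))
  paste0(up, "[", ref, "/", alt, "]", down)
}

#' Flanking-sequence table for a set of SNPs
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param variants `data.frame` with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param flank_length Bases either side, default 100.
#' @param path Optional output TSV path.
#' @return `data.frame` with `snp_id`, `chrom`, `pos`, `assay_string`.
#' @export
flank_table <- function(reference, variants, flank_length = 100L,
                        path = NULL) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  out <- data.frame(snp_id = variants$id, chrom = variants$chrom,
                    pos = as.integer(variants$pos),
                    assay_string = vapply(seq_len(nrow(variants)), function(i)
                      extract_flanks(reference, variants[i, , drop = FALSE],
                                     flank_length), character(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(.comment_header("KASP flanking sequences",
                               c(flank_length = flank_length)), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
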