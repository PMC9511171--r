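# Fixture builders shared across the suite. All data are generated in code.

# Build a VariantMatrix from per-sample call strings over the alphabet
# R (REF), A (ALT), H (HET), N (MISSING), e.g. c(s1 = "RRA", s2 = "NAH").
make_vm <- function(strings, chrom = "chr1", pos = NULL) {
  m <- nchar(strings[1])
  stopifnot(all(nchar(strings) == m))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  samples <- names(strings)
  if (is.null(samples)) samples <- paste0("s", seq_along(strings))
  map <- c(R = "REF", A = "ALT", H = "HET", N = "MISSING")
  calls <- do.call(rbind, lapply(strings, function(s)
    unname(map[strsplit(s, "")[[1]]])))
  variant_matrix(samples,
                 data.frame(id = paste0("snp", seq_len(m)), chrom = chrom,
                            pos = pos,
                            ref = rep(c("C", "G", "T", "A"), length.out = m),
                            alt = rep(c("A", "T", "C", "G"), length.out = m),
                            stringsAsFactors = FALSE),
                 calls)
}

# Haplotype-group list from 0/1 strings (1 = ALT), e.g. c("001", "010").
make_groups <- function(bits, snp_ids = NULL) {
  m <- nchar(bits[1])
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  lapply(seq_along(bits), function(i) {
    v <- strsplit(bits[i], "")[[1]]
    list(label = paste0("Hap", i),
         alleles = stats::setNames(ifelse(v == "1", "ALT", "REF"), snp_ids),
         n = NA_integer_, members = character())
  })
}

# Independent brute-force minimum-discriminating-set oracle: enumerates
# subsets by increasing size over ALL SNP columns (no equivalence-class
# collapse), entirely separate from the search under test.
brute_force_tag_size <- function(groups) {
  g <- do.call(rbind, lapply(groups, function(x) x$alleles == "ALT"))
  pr <- t(utils::combn(nrow(g), 2))
  sep <- matrix(FALSE, nrow(pr), ncol(g))
  for (j in seq_len(ncol(g))) sep[, j] <- g[pr[, 1], j] != g[pr[, 2], j]
  if (!all(rowSums(sep) > 0)) return(NA_integer_)
  for (k in seq_len(ncol(g))) {
    cmb <- utils::combn(ncol(g), k)
    for (ci in seq_len(ncol(cmb))) {
      if (all(rowSums(sep[, cmb[, ci], drop = FALSE]) > 0)) return(k)
    }
  }
  NA_integer_
}

# Random set of distinct haplotype groups for property tests.
random_groups <- function(n_groups, n_snps) {
  repeat {
    g <- matrix(sample(c("0", "1"), n_groups * n_snps, replace = TRUE),
                n_groups, n_snps)
    bits <- apply(g, 1, paste, collapse = "")
    if (!anyDuplicated(bits)) return(make_groups(bits))
  }
}

# Random call matrix (REF/ALT/MISSING) for filtering/partition properties.
random_vm <- function(n_samples, n_snps, missing_rate = 0.1) {
  calls <- matrix(sample(c("REF", "ALT"), n_samples * n_snps, replace = TRUE),
                  n_samples, n_snps)
  calls[matrix(stats::runif(n_samples * n_snps) < missing_rate,
               n_samples)] <- "MISSING"
  variant_matrix(paste0("s", seq_len(n_samples)),
                 data.frame(id = paste0("snp", seq_len(n_snps)),
                            chrom = "chr1", pos = seq_len(n_snps) * 10L,
                            ref = "C", alt = "A", stringsAsFactors = FALSE),
                 calls)
}
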