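# Synthetic germplasm-panel generator. Emulates the statistical structure
# the analysis assumes: subpopulation-skewed haplotype frequencies over one
# or two gene regions, rare haplotypes as single-position perturbations of
# common vectors, per-call heterozygosity and missingness noise, and a
# two-locus additive phenotype with configurable dominance at locus A.
# It does NOT emulate linkage disequilibrium decay or recombination within
# a region: haplotypes are atomic allele vectors, exactly as the grouping
# definition treats them.

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || x < 0 || x > 1) stop(name, " must be in [0, 1]")
}

#' Define a synthetic panel
#'
#' @param n_samples Number of panel samples.
#' @param subpop_proportions Named numeric vector over subpopulations,
#'   summing to 1.
#' @param regions Named list of regions; each region is a list with
#'   `snps` (`data.frame`: `id`, `chrom`, `pos`, `ref`, `alt`),
#'   `haplotypes` (matrix, haplotype x SNP, entries `"REF"`/`"ALT"`,
#'   rownames are the true labels), `freq` (matrix, subpopulation x
#'   haplotype, rows summing to 1), `causal_snp` (a SNP id) and
#'   `long_allele` (`"REF"` or `"ALT"`, the long-grain allele at the
#'   causal SNP).
#' @param rare_haplotype_rate Per-sample-per-region probability of carrying
#'   a rare haplotype (a single-position perturbation of a common vector,
#'   guaranteed distinct from every defined haplotype).
#' @param missing_rate,het_rate Per-call noise rates, applied in the order
#'   heterozygote injection then missing injection, so a call can end up
#'   missing regardless of het status.
#' @param phenotype List: `mu` (baseline, mm: the homozygous-medium/medium
#'   mean), `effect_a`, `effect_b` (mm added by the homozygous long allele
#'   at the first and second region), `dominance_a` (`"recessive-long"`:
#'   heterozygotes at locus A express the medium phenotype; `"additive"`:
#'   half effect), `sigma` (residual sd, mm). Locus B is additive.
#' @param seed Integer seed; a single seed governs all randomness and the
#'   caller's RNG state is left untouched.
#' @return A validated `SyntheticPanelSpec`.
#' @export
synthetic_panel_spec <- function(n_samples, subpop_proportions, regions,
                                 rare_haplotype_rate = 0.01,
                                 missing_rate = 0.03, het_rate = 0.01,
                                 phenotype = list(mu = 6.0, effect_a = 0.8,
                                                  effect_b = 0.4,
                                                  dominance_a = "recessive-long",
                                                  sigma = 0.25),
                                 seed = 1L) {
  stopifnot(n_samples >= 1)
  if (abs(sum(subpop_proportions) - 1) > 1e-9) {
    stop("subpop_proportions must sum to 1")
  }
  .check_fraction(rare_haplotype_rate, "rare_haplotype_rate")
  .check_fraction(missing_rate, "missing_rate")
  .check_fraction(het_rate, "het_rate")
  stopifnot(length(regions) >= 1, !is.null(names(regions)))
  for (rn in names(regions)) {
    r <- regions[[rn]]
    if (nrow(r$snps) != ncol(r$haplotypes)) {
      stop("region ", rn, ": haplotype matrix width != number of SNPs")
    }
    if (!all(r$haplotypes %in% c("REF", "ALT"))) {
      stop("region ", rn, ": haplotype entries must be REF/ALT")
    }
    if (anyDuplicated(apply(r$haplotypes, 1, paste, collapse = ""))) {
      stop("region ", rn, ": duplicate haplotype vectors")
    }
    if (!setequal(rownames(r$freq), names(subpop_proportions)) ||
        ncol(r$freq) != nrow(r$haplotypes)) {
      stop("region ", rn, ": freq must be subpopulation x haplotype")
    }
    if (any(abs(rowSums(r$freq) - 1) > 1e-9)) {
      stop("region ", rn, ": per-subpopulation haplotype frequencies must sum to 1")
    }
    if (!r$causal_snp %in% r$snps$id) {
      stop("region ", rn, ": causal_snp not among the region SNPs")
    }
    stopifnot(r$long_allele %in% c("REF", "ALT"))
  }
  stopifnot(phenotype$dominance_a %in% c("recessive-long", "additive"),
            phenotype$sigma >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 subpop_proportions = subpop_proportions,
                 regions = regions,
                 rare_haplotype_rate = rare_haplotype_rate,
                 missing_rate = missing_rate, het_rate = het_rate,
                 phenotype = phenotype, seed = as.integer(seed)),
            class = "SyntheticPanelSpec")
}

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.effect_of_state <- function(state, effect, dominance) {
  # state in {"homo-L", "het", "homo-M"}
  ifelse(state == "homo-L", effect,
         ifelse(state == "het",
                if (dominance == "recessive-long") 0 else effect / 2,
                0))
}

#' Generate a synthetic germplasm panel
#'
#' Sampling order per sample: subpopulation; haplotype per region from that
#' subpopulation's frequencies (with probability `rare_haplotype_rate` a
#' perturbed rare vector instead); per-call heterozygote injection; per-call
#' missing injection; phenotype = mu + locus effects + Normal(0, sigma).
#' Locus effects are evaluated on the post-heterozygote, pre-missing state
#' of the causal SNPs, so injected heterozygotes carry genuine heterozygote
#' phenotypes under the configured dominance model. Identical seeds give
#' byte-identical outputs.
#'
#' @param spec A [synthetic_panel_spec()].
#' @param seed Overrides `spec$seed` if given.
#' @return List: `matrices` (named list of [variant_matrix()], one per
#'   region), `meta` (sample metadata `data.frame`), `pheno` (phenotype
#'   `data.frame`), `truth` (`data.frame`: per-sample true haplotype label
#'   per region, causal-locus states, four/nine-class labels and the
#'   pre-noise genetic value), and `spec`.
#' @export
generate_panel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "SyntheticPanelSpec"))
  if (is.null(seed)) seed <- spec$seed
  .with_seed(seed, {
    n <- spec$n_samples
    ids <- sprintf("SIM_%04d", seq_len(n))
    subpop <- sample(names(spec$subpop_proportions), n, replace = TRUE,
                     prob = spec$subpop_proportions)

    matrices <- list()
    labels <- states <- list()
    for (rn in names(spec$regions)) {
      r <- spec$regions[[rn]]
      n_hap <- nrow(r$haplotypes)
      hap_keys <- apply(r$haplotypes, 1, paste, collapse = "")
      hap_idx <- integer(n)
      for (sp in unique(subpop)) {
        sel <- which(subpop == sp)
        hap_idx[sel] <- sample.int(n_hap, length(sel), replace = TRUE,
                                   prob = r$freq[sp, ])
      }
      lab <- rownames(r$haplotypes)[hap_idx]
      calls <- r$haplotypes[hap_idx, , drop = FALSE]
      rare <- stats::runif(n) < spec$rare_haplotype_rate
      for (i in which(rare)) {
        repeat {
          v <- r$haplotypes[sample.int(n_hap, 1), ]
          j <- sample.int(length(v), 1)
          v[j] <- if (v[j] == "REF") "ALT" else "REF"
          if (!paste(v, collapse = "") %in% hap_keys) break
        }
        calls[i, ] <- v
        lab[i] <- "RARE"
      }
      # HET injection first, then MISSING: a call can end MISSING
      # regardless of het status.
      het_hit <- matrix(stats::runif(n * ncol(calls)) < spec$het_rate,
                        nrow = n)
      calls[het_hit] <- "HET"
      causal_col <- match(r$causal_snp, r$snps$id)
      cc <- calls[, causal_col]
      states[[rn]] <- ifelse(cc == "HET", "het",
                             ifelse(cc == r$long_allele, "homo-L", "homo-M"))
      miss_hit <- matrix(stats::runif(n * ncol(calls)) < spec$missing_rate,
                         nrow = n)
      calls[miss_hit] <- "MISSING"
      labels[[rn]] <- lab
      matrices[[rn]] <- variant_matrix(ids, r$snps, calls)
    }

    ph <- spec$phenotype
    st_a <- states[[1]]
    st_b <- if (length(states) >= 2) states[[2]] else rep("homo-M", n)
    g <- ph$mu +
      .effect_of_state(st_a, ph$effect_a, ph$dominance_a) +
      .effect_of_state(st_b, ph$effect_b, "additive")
    value <- g + stats::rnorm(n, 0, ph$sigma)

    class4 <- rep(NA_character_, n)
    hom <- st_a != "het" & st_b != "het"
    lab4 <- c("homo-L.homo-L" = "Class1", "homo-L.homo-M" = "Class2",
              "homo-M.homo-L" = "Class3", "homo-M.homo-M" = "Class4")
    class4[hom] <- lab4[paste(st_a[hom], st_b[hom], sep = ".")]
    ln <- names(spec$regions)[1:2]
    if (length(spec$regions) == 1) ln <- c(ln[1], "B")
    class9 <- paste0(ln[1], "-", st_a, "/", ln[2], "-", st_b)

    grain_class <- ifelse(st_a == "homo-L", "long",
                          ifelse(st_a == "homo-M", "medium", "unknown"))
    meta <- data.frame(sample_id = ids, subpopulation = subpop,
                       grain_class = grain_class,
                       release_year = sample(1960:2020, n, replace = TRUE),
                       stringsAsFactors = FALSE)
    pheno <- data.frame(sample_id = ids, trait = "grain_length",
                        environment = "sim", value = value,
                        stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    for (rn in names(spec$regions)) {
      truth[[paste0("label_", rn)]] <- labels[[rn]]
    }
    truth$state_a <- st_a
    truth$state_b <- st_b
    truth$class4 <- class4
    truth$class9 <- class9
    truth$genetic_value <- g

    list(matrices = matrices, meta = meta, pheno = pheno, truth = truth,
         spec = spec)
  })
}

# --- paper-like preset -----------------------------------------------------

# Haplotype vectors are built from short binary codes expanded through
# xor-derived columns, which guarantees every pair of defined vectors
# differs at several SNPs (so single-flip rare vectors never collide and
# partial vectors rarely match two groups).
.codes_to_vectors <- function(codes, cols) {
  m <- vapply(cols, function(ix) {
    Reduce(function(a, b) xor(a, b), lapply(ix, function(i) codes[, i] == 1))
  }, logical(nrow(codes)))
  ifelse(m, "ALT", "REF")
}

# Row 1 is the causal SNP; remaining rows are evenly spaced across the
# region. Rows align one-to-one with haplotype-matrix columns.
.region_snps <- function(prefix, chrom, start, end, m, causal_pos,
                         causal_name) {
  pos <- round(seq(start, end, length.out = m + 1))[-1]
  pos[1] <- causal_pos
  if (anyDuplicated(pos)) stop("degenerate region layout")
  ids <- paste0(prefix, "_S", seq_len(m))
  ids[1] <- causal_name
  ref <- rep(c("C", "G", "A", "T"), length.out = m)
  alt <- rep(c("A", "T", "G", "C"), length.out = m)
  data.frame(id = ids, chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Panel specification emulating the published study conditions
#'
#' Two gene regions: a grain-size gene on chr3 with eight haplotypes whose
#' causal SNP's ALT allele is the long-grain allele (recessive), and a
#' grain-length QTL region on chr7 with nine haplotypes and a smaller,
#' additive effect. Haplotype frequencies are strongly subpopulation-skewed
#' (e.g. one haplotype dominating tropical japonica, another temperate
#' japonica). Noise: 1% rare haplotypes, 3% missing calls, 1% heterozygous
#' calls. Phenotype: baseline 6.0 mm, +0.8 mm for the homozygous long
#' allele at locus A, +0.4 mm at locus B, residual sd 0.25 mm — placing
#' the four homozygous two-locus class means at 7.2 / 6.8 / 6.4 / 6.0 mm.
#'
#' @param n_samples Panel size (default 2000).
#' @param seed Seed stored in the spec.
#' @return A [synthetic_panel_spec()].
#' @export
paper_like_preset <- function(n_samples = 2000, seed = 101L) {
  subpops <- c(indica = 0.40, aus = 0.07, `indica-admix` = 0.06,
               `tropical-japonica` = 0.15, `temperate-japonica` = 0.13,
               `japonica-admix` = 0.05, aromatic = 0.03, admix = 0.11)

  # Region A: 8 haplotypes over 12 SNPs from 3-bit codes.
  codes_a <- matrix(c(1, 0, 0,  0, 0, 0,  0, 0, 1,  0, 1, 0,
                      0, 1, 1,  1, 0, 1,  1, 1, 0,  1, 1, 1),
                    ncol = 3, byrow = TRUE)
  cols_a <- list(1, 2, 3, c(1, 2), c(2, 3), c(1, 3), c(1, 2, 3),
                 1, 2, 3, c(2, 3), c(1, 3))
  hap_a <- .codes_to_vectors(codes_a, cols_a)
  rownames(hap_a) <- paste0("Hap", 1:8)
  snps_a <- .region_snps("GS3", "chr3", 16729501, 16735109, 12,
                         16733441, "GS3_SNP1")
  colnames(hap_a) <- snps_a$id   # column 1 (code bit 1) is the causal SNP
  freq_a <- matrix(c(
    0.35, 0.25, 0.05, 0.15, 0.10, 0.05, 0.03, 0.02,   # indica
    0.10, 0.40, 0.02, 0.25, 0.13, 0.05, 0.03, 0.02,   # aus
    0.30, 0.25, 0.05, 0.15, 0.10, 0.08, 0.04, 0.03,   # indica-admix
    0.76, 0.05, 0.10, 0.03, 0.02, 0.02, 0.01, 0.01,   # tropical-japonica
    0.20, 0.08, 0.52, 0.08, 0.05, 0.03, 0.02, 0.02,   # temperate-japonica
    0.40, 0.10, 0.30, 0.08, 0.05, 0.03, 0.02, 0.02,   # japonica-admix
    0.30, 0.20, 0.20, 0.10, 0.10, 0.05, 0.03, 0.02,   # aromatic
    0.40, 0.20, 0.15, 0.10, 0.05, 0.05, 0.03, 0.02),  # admix
    nrow = 8, byrow = TRUE,
    dimnames = list(names(subpops), rownames(hap_a)))

  # Region B: 9 haplotypes over 12 SNPs from 4-bit codes.
  codes_b <- matrix(c(1, 0, 0, 0,  1, 1, 0, 0,  0, 0, 0, 0,  0, 0, 1, 0,
                      0, 1, 0, 0,  1, 0, 1, 0,  0, 1, 1, 0,  1, 1, 1, 0,
                      0, 0, 0, 1),
                    ncol = 4, byrow = TRUE)
  cols_b <- list(1, 2, 3, 4, c(1, 2), c(2, 3), c(3, 4), c(1, 3), c(2, 4),
                 c(1, 4), c(1, 2, 3, 4), 1)
  hap_b <- .codes_to_vectors(codes_b, cols_b)
  rownames(hap_b) <- paste0("Hap", 1:9)
  snps_b <- .region_snps("qGL7", "chr7", 24845026, 25319809, 12,
                         25211630, "qGL7.1_SNP1")
  colnames(hap_b) <- snps_b$id
  freq_b <- matrix(c(
    0.50, 0.05, 0.05, 0.15, 0.10, 0.06, 0.04, 0.03, 0.02,   # indica
    0.35, 0.05, 0.05, 0.20, 0.15, 0.08, 0.05, 0.04, 0.03,   # aus
    0.45, 0.08, 0.06, 0.14, 0.10, 0.07, 0.05, 0.03, 0.02,   # indica-admix
    0.03, 0.80, 0.09, 0.02, 0.02, 0.01, 0.01, 0.01, 0.01,   # tropical-japonica
    0.02, 0.20, 0.61, 0.07, 0.04, 0.02, 0.02, 0.01, 0.01,   # temperate-japonica
    0.05, 0.45, 0.30, 0.08, 0.05, 0.03, 0.02, 0.01, 0.01,   # japonica-admix
    0.10, 0.30, 0.25, 0.15, 0.10, 0.05, 0.03, 0.01, 0.01,   # aromatic
    0.25, 0.25, 0.20, 0.10, 0.08, 0.05, 0.04, 0.02, 0.01),  # admix
    nrow = 8, byrow = TRUE,
    dimnames = list(names(subpops), rownames(hap_b)))

  synthetic_panel_spec(
    n_samples = n_samples,
    subpop_proportions = subpops,
    regions = list(
      GS3 = list(snps = snps_a, haplotypes = hap_a, freq = freq_a,
                 causal_snp = "GS3_SNP1", long_allele = "ALT"),
      qGL7.1 = list(snps = snps_b, haplotypes = hap_b, freq = freq_b,
                    causal_snp = "qGL7.1_SNP1", long_allele = "ALT")),
    rare_haplotype_rate = 0.01, missing_rate = 0.03, het_rate = 0.01,
    phenotype = list(mu = 6.0, effect_a = 0.8, effect_b = 0.4,
                     dominance_a = "recessive-long", sigma = 0.25),
    seed = seed)
}
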