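# Haplotype grouping: samples sharing an identical allele vector across all
# retained SNPs of a region form one haplotype. Groups meeting the rare rule
# are named Hap1, Hap2, ... in descending size.

#' Rare-haplotype rule
#'
#' Published regimes use either an absolute count ("haplotypes found in
#' fewer than k samples are rare") or a frequency floor ("haplotypes at a
#' frequency of at least f are characterized"). Comparisons are strict for
#' `min_count` (a group of exactly `threshold` members is named) and
#' inclusive for `min_frequency` (frequency `>= threshold` is named).
#'
#' @param mode `"min_count"` or `"min_frequency"`.
#' @param threshold Integer `>= 1` for `min_count`; a fraction in (0, 1)
#'   for `min_frequency`.
#' @return A `RareRule` list.
#' @export
rare_rule <- function(mode = c("min_count", "min_frequency"), threshold) {
  mode <- match.arg(mode)
  if (mode == "min_count") {
    stopifnot(threshold >= 1, threshold == as.integer(threshold))
  } else {
    stopifnot(threshold > 0, threshold < 1)
  }
  structure(list(mode = mode, threshold = threshold), class = "RareRule")
}

.meets_rule <- function(n, total, rule) {
  if (rule$mode == "min_count") n >= rule$threshold
  else n / total >= rule$threshold
}

.new_partition <- function(groups, rare, unclassified, assignments, snps,
                           n_samples, rule, novel = list()) {
  structure(list(groups = groups, rare_samples = rare,
                 unclassified_samples = unclassified,
                 assignments = assignments, snps = snps,
                 n_samples = n_samples, rule = rule, novel = novel),
            class = "HaplotypePartition")
}

#' @export
print.HaplotypePartition <- function(x, ...) {
  cat(sprintf("HaplotypePartition: %d samples, %d SNPs, %d named groups\n",
              x$n_samples, nrow(x$snps), length(x$groups)))
  for (g in x$groups) {
    cat(sprintf("  %s: n=%d (%.1f%%)\n", g$label, g$n,
                100 * g$n / x$n_samples))
  }
  cat(sprintf("  Rare: %d  Unclassified: %d", length(x$rare_samples),
              length(x$unclassified_samples)))
  if (length(x$novel)) {
    cat(sprintf("  Novel: %d vector(s)", length(x$novel)))
  }
  cat("\n")
  invisible(x)
}

# Deterministic ordering: descending size, ties broken by the allele vector
# itself with REF sorting before ALT.
.order_groups <- function(counts, keys) {
  key01 <- chartr("RA", "01", keys)   # REF sorts before ALT
  order(-counts, key01)
}

#' Partition samples into haplotype groups
#'
#' Samples with complete calls are grouped by exact allele-vector identity;
#' groups meeting the rare rule are named `Hap1..HapN` by descending member
#' count (ties broken by allele vector, REF before ALT). Complete samples
#' in below-threshold groups go to the rare set. Samples with one or more
#' missing calls are assigned to a named group only when their non-missing
#' calls are compatible with exactly one named group; a partial vector
#' compatible with no named group but with at least one observed rare
#' vector goes to the rare set; anything else is unclassified.
#'
#' @param m A filtered [variant_matrix()] whose calls are only
#'   REF/ALT/MISSING (run [apply_cascade()] with `het_as_missing = TRUE`
#'   first; any residual HET is treated as MISSING here, with a warning).
#' @param rule A [rare_rule()].
#' @return A `HaplotypePartition`.
#' @export
characterize_haplotypes <- function(m, rule = rare_rule("min_count", 30)) {
  stopifnot(inherits(m, "VariantMatrix"), inherits(rule, "RareRule"))
  if (length(m$samples) == 0 || nrow(m$variants) == 0) {
    stop("cannot characterize an empty matrix")
  }
  calls <- m$calls
  if (any(calls == "HET")) {
    warning("heterozygous calls present; treated as MISSING for grouping")
    calls[calls == "HET"] <- "MISSING"
  }
  code <- matrix(NA_character_, nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  code[calls == "REF"] <- "R"
  code[calls == "ALT"] <- "A"

  complete <- rowSums(is.na(code)) == 0
  total <- length(m$samples)
  assignments <- stats::setNames(rep(NA_character_, total), m$samples)

  vec_key <- apply(code[complete, , drop = FALSE], 1, paste, collapse = "")
  tab <- table(vec_key)
  counts <- as.integer(tab)
  keys <- names(tab)
  ord <- .order_groups(counts, keys)
  counts <- counts[ord]; keys <- keys[ord]
  named_idx <- which(vapply(counts, .meets_rule, logical(1), total, rule))
  named_keys <- keys[named_idx]
  rare_keys <- setdiff(keys, named_keys)

  groups <- vector("list", length(named_keys))
  for (i in seq_along(named_keys)) {
    members <- names(vec_key)[vec_key == named_keys[i]]
    alleles <- stats::setNames(
      ifelse(strsplit(named_keys[i], "")[[1]] == "R", "REF", "ALT"),
      m$variants$id)
    groups[[i]] <- list(label = paste0("Hap", i), alleles = alleles,
                        n = length(members), members = members)
    assignments[members] <- paste0("Hap", i)
  }
  rare <- names(vec_key)[vec_key %in% rare_keys]
  assignments[rare] <- "RARE"

  # Partial-match assignment for samples carrying missing calls.
  unclassified <- character(0)
  named_mat <- if (length(named_keys))
    do.call(rbind, strsplit(named_keys, "")) else
      matrix(character(0), 0, ncol(code))
  rare_mat <- if (length(rare_keys))
    do.call(rbind, strsplit(rare_keys, "")) else
      matrix(character(0), 0, ncol(code))
  for (s in m$samples[!complete]) {
    v <- code[s, ]
    seen <- !is.na(v)
    if (!any(seen)) {
      unclassified <- c(unclassified, s)
      next
    }
    compat_named <- if (nrow(named_mat))
      which(colSums(t(named_mat[, seen, drop = FALSE]) != v[seen]) == 0) else
        integer(0)
    if (length(compat_named) == 1L) {
      lab <- paste0("Hap", compat_named)
      assignments[s] <- lab
      groups[[compat_named]]$members <-
        c(groups[[compat_named]]$members, s)
      groups[[compat_named]]$n <- groups[[compat_named]]$n + 1L
    } else if (length(compat_named) == 0L && nrow(rare_mat) &&
               any(colSums(t(rare_mat[, seen, drop = FALSE]) != v[seen]) == 0)) {
      rare <- c(rare, s)
    } else {
      unclassified <- c(unclassified, s)
    }
  }
  assignments[rare] <- "RARE"
  assignments[unclassified] <- "UNCLASSIFIED"
  # Relabel so Hap1 is the largest group after partial-match assignment
  # (stable: ties keep the complete-call ordering).
  if (length(groups) > 1) {
    final_n <- vapply(groups, `[[`, integer(1), "n")
    ord2 <- order(-final_n, seq_along(groups))
    groups <- groups[ord2]
    for (i in seq_along(groups)) {
      assignments[groups[[i]]$members] <- paste0("Hap", i)
      groups[[i]]$label <- paste0("Hap", i)
    }
  }
  .new_partition(groups, rare, unclassified, assignments, m$variants,
                 total, rule)
}

#' Survey reference haplotypes across a panel via a tag set
#'
#' Matches each panel sample against the tag-SNP alleles of reference
#' haplotype groups. A heterozygous or missing call at any tag SNP makes
#' the sample unclassified. Complete vectors matching no reference group
#' are reported as novel with their vector, never silently folded into an
#' existing group.
#'
#' @param panel A [variant_matrix()] restricted to (a superset of) the tag
#'   SNPs; only SNPs present in the reference groups are used.
#' @param reference_groups List of haplotype groups (from a
#'   `HaplotypePartition`'s `groups` or [read_group_defs()]).
#' @param snp_ids Optional character vector restricting the comparison to
#'   these SNPs (e.g. a tag set); default: all SNPs shared by panel and
#'   reference definitions.
#' @return A `HaplotypePartition` over the panel samples, with a `novel`
#'   element listing unmatched complete vectors.
#' @export
survey_panel <- function(panel, reference_groups, snp_ids = NULL) {
  stopifnot(inherits(panel, "VariantMatrix"), length(reference_groups) >= 1)
  ref_snps <- names(reference_groups[[1]]$alleles)
  if (is.null(snp_ids)) snp_ids <- intersect(panel$variants$id, ref_snps)
  if (length(snp_ids) == 0) stop("panel shares no SNPs with the reference groups")
  if (!all(snp_ids %in% panel$variants$id)) {
    stop("panel lacks tag SNPs: ",
         paste(setdiff(snp_ids, panel$variants$id), collapse = ", "))
  }
  ref <- vapply(reference_groups, function(g) {
    if (!all(snp_ids %in% names(g$alleles))) {
      stop("reference group ", g$label, " lacks alleles for some tag SNPs")
    }
    paste(substr(g$alleles[snp_ids], 1, 1), collapse = "")  # "R"/"A" string
  }, character(1))
  labels <- vapply(reference_groups, `[[`, "", "label")
  if (anyDuplicated(ref)) {
    clash <- duplicated(ref) | duplicated(ref, fromLast = TRUE)
    stop("reference groups not distinguishable on the provided SNPs: ",
         paste(labels[clash], collapse = ", "))
  }
  calls <- panel$calls[, snp_ids, drop = FALSE]
  assignments <- stats::setNames(rep("UNCLASSIFIED", length(panel$samples)),
                                 panel$samples)
  ok <- rowSums(calls == "HET" | calls == "MISSING") == 0
  key <- rep(NA_character_, length(panel$samples))
  key[ok] <- apply(matrix(substr(calls[ok, , drop = FALSE], 1, 1),
                          nrow = sum(ok)), 1, paste, collapse = "")
  hit <- match(key, ref)
  assignments[!is.na(hit)] <- labels[hit[!is.na(hit)]]
  novel_keys <- unique(key[ok & is.na(hit)])
  novel <- lapply(novel_keys, function(k) {
    list(alleles = stats::setNames(
      ifelse(strsplit(k, "")[[1]] == "R", "REF", "ALT"), snp_ids),
      samples = panel$samples[!is.na(key) & key == k])
  })
  assignments[ok & is.na(hit)] <- "NOVEL"
  groups <- lapply(seq_along(reference_groups), function(i) {
    g <- reference_groups[[i]]
    members <- names(assignments)[assignments == g$label]
    list(label = g$label, alleles = g$alleles[snp_ids],
         n = length(members), members = members)
  })
  snps <- panel$variants[match(snp_ids, panel$variants$id), , drop = FALSE]
  .new_partition(groups, character(0),
                 names(assignments)[assignments == "UNCLASSIFIED"],
                 assignments, snps, length(panel$samples), NULL, novel)
}

#' Percent of samples covered by named haplotype groups
#'
#' Reported as an integer percent, rounded half-up.
#'
#' @param classified Number of samples carrying a named haplotype.
#' @param total Total samples in the partition.
#' @return Integer percent.
#' @examples
#' coverage_percent(2222, 2426)  # 92
#' @export
coverage_percent <- function(classified, total) {
  if (total <= 0) stop("total must be positive")
  stopifnot(classified >= 0, classified <= total)
  as.integer(floor(100 * classified / total + 0.5))
}

#' Per-group composition by subpopulation, grain class and varietal group
#'
#' For each named group (plus the rare and unclassified sets) tabulates
#' member counts and within-group percentages by subpopulation and by grain
#' class, alongside the varietal-group rollup: Indica = indica + aus +
#' indica-admix; Japonica = tropical/temperate japonica + aromatic +
#' japonica-admix. Samples absent from `meta` count as unknown.
#'
#' @param partition A `HaplotypePartition`.
#' @param meta Metadata `data.frame` as from [read_sample_meta()].
#' @return Long `data.frame` with columns `group`, `category_type`,
#'   `category`, `n`, `pct`.
#' @export
composition_summary <- function(partition, meta) {
  stopifnot(inherits(partition, "HaplotypePartition"))
  rollup <- c(indica = "Indica", aus = "Indica", `indica-admix` = "Indica",
              `tropical-japonica` = "Japonica",
              `temperate-japonica` = "Japonica", aromatic = "Japonica",
              `japonica-admix` = "Japonica", admix = "Admix",
              unknown = "unknown")
  sets <- c(stats::setNames(lapply(partition$groups, `[[`, "members"),
                            vapply(partition$groups, `[[`, "", "label")),
            list(Rare = partition$rare_samples,
                 Unclassified = partition$unclassified_samples))
  out <- list()
  for (gname in names(sets)) {
    ids <- sets[[gname]]
    i <- match(ids, meta$sample_id)
    sp <- ifelse(is.na(i), "unknown", meta$subpopulation[i])
    gc <- ifelse(is.na(i), "unknown", meta$grain_class[i])
    add <- function(type, values, levels) {
      if (length(ids) == 0) return(NULL)
      tb <- table(factor(values, levels = levels))
      tb <- tb[tb > 0]
      data.frame(group = gname, category_type = type,
                 category = names(tb), n = as.integer(tb),
                 pct = round(100 * as.integer(tb) / length(ids), 2),
                 stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- add("subpopulation", sp, .SUBPOPULATIONS)
    out[[length(out) + 1L]] <- add("grain_class", gc, .GRAIN_CLASSES)
    out[[length(out) + 1L]] <-
      add("varietal_group", unname(rollup[sp]),
          c("Indica", "Japonica", "Admix", "unknown"))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
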