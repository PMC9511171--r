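# Minimum discriminating SNP set ("tag set"): the smallest SNP subset whose
# alleles differ between every pair of named haplotype groups. This is a
# set-cover problem over group pairs; solved exactly by increasing-size
# subset search after collapsing SNPs with identical group-partition
# patterns, with a classical greedy cover as fallback for large instances.

.group_allele_mat <- function(groups, snp_ids = NULL) {
  stopifnot(length(groups) >= 1)
  ids <- names(groups[[1]]$alleles)
  if (!is.null(snp_ids)) {
    if (!all(snp_ids %in% ids)) {
      stop("unknown SNP id(s): ", paste(setdiff(snp_ids, ids), collapse = ", "))
    }
    ids <- snp_ids
  }
  m <- do.call(rbind, lapply(groups, function(g) g$alleles[ids] == "ALT"))
  rownames(m) <- vapply(groups, `[[`, "", "label")
  colnames(m) <- ids
  m
}

.pairs_of <- function(n) {
  if (n < 2) stop("need at least two haplotype groups to discriminate")
  t(utils::combn(n, 2))
}

#' Does a SNP set discriminate all haplotype groups?
#'
#' @param snps Character vector of SNP ids.
#' @param groups List of haplotype groups (label + named REF/ALT allele
#'   vector), e.g. a `HaplotypePartition`'s `groups`.
#' @return List with `discriminating` (logical) and `failing_pairs`
#'   (`data.frame` of group label pairs with no separating SNP in the set;
#'   empty when discriminating).
#' @export
is_discriminating <- function(snps, groups) {
  g <- .group_allele_mat(groups, snps)
  pr <- .pairs_of(nrow(g))
  sep <- vapply(seq_len(nrow(pr)), function(k)
    any(g[pr[k, 1], ] != g[pr[k, 2], ]), logical(1))
  labs <- rownames(g)
  list(discriminating = all(sep),
       failing_pairs = data.frame(group_i = labs[pr[!sep, 1]],
                                  group_j = labs[pr[!sep, 2]],
                                  stringsAsFactors = FALSE))
}

#' Number of group pairs a SNP separates
#'
#' A SNP splitting the groups into sets of sizes a and b separates a*b
#' pairs; used for greedy ordering and reporting.
#'
#' @param snp_id A SNP id present in the groups' allele vectors.
#' @param groups List of haplotype groups.
#' @return Integer count of separated pairs.
#' @export
distinguishing_power <- function(snp_id, groups) {
  g <- .group_allele_mat(groups, snp_id)
  n_alt <- sum(g[, 1])
  as.integer(n_alt * (nrow(g) - n_alt))
}

# Candidate ordering: priority SNPs first (in the given order), then by
# genomic position, then id — makes every tie-break deterministic and
# position-stable.
.candidate_order <- function(ids, pos, priority) {
  pri_rank <- match(ids, priority)
  pri_rank[is.na(pri_rank)] <- length(priority) + 1L
  order(pri_rank, pos, ids)
}

#' Find a minimum discriminating SNP set
#'
#' Exact mode guarantees minimum cardinality: SNPs inducing the same
#' bipartition of the groups are collapsed into equivalence classes, then
#' subsets of class representatives are enumerated by increasing size
#' starting from the information bound `ceiling(log2(n_groups))`. Greedy
#' mode iteratively adds the SNP separating the most currently-unresolved
#' pairs. Auto uses exact while the equivalence-class count and
#' `exact_size_limit` keep the enumeration small, else greedy (with a
#' message stating the greedy size is an upper bound).
#'
#' @param groups List of haplotype groups, pairwise distinct on the full
#'   SNP set.
#' @param mode `"exact"`, `"greedy"` or `"auto"`.
#' @param exact_size_limit Largest subset size exact search will attempt.
#' @param snp_pos Optional named numeric vector of genomic positions used
#'   for tie-breaking (lower position preferred); defaults to the column
#'   order of the allele vectors.
#' @param priority Optional character vector of SNP ids preferred among
#'   ties (e.g. a known functional SNP).
#' @return A `TagSet`: `snp_ids`, `size`, `pair_coverage` (list mapping
#'   `"g1|g2"` to the separating SNPs in the set) and `method`.
#' @export
minimum_tag_set <- function(groups, mode = c("auto", "exact", "greedy"),
                            exact_size_limit = 10L, snp_pos = NULL,
                            priority = character()) {
  mode <- match.arg(mode)
  g <- .group_allele_mat(groups)
  labs <- rownames(g)
  pr <- .pairs_of(nrow(g))

  ident <- apply(g, 1, paste, collapse = "")
  if (anyDuplicated(ident)) {
    clash <- which(duplicated(ident) | duplicated(ident, fromLast = TRUE))
    stop("inseparable haplotype groups (identical allele vectors): ",
         paste(labs[clash], collapse = ", "))
  }

  ids <- colnames(g)
  pos <- if (is.null(snp_pos)) stats::setNames(seq_along(ids), ids) else
    snp_pos[ids]

  # Per-SNP separated-pair sets, as logical vectors over the pair list.
  sep <- matrix(FALSE, nrow(pr), ncol(g), dimnames = list(NULL, ids))
  for (j in seq_len(ncol(g))) {
    sep[, j] <- g[pr[, 1], j] != g[pr[, 2], j]
  }
  informative <- colSums(sep) > 0

  # Equivalence classes: same bipartition pattern (a column and its
  # complement separate the same pairs).
  patt <- apply(sep[, , drop = FALSE], 2, paste, collapse = "")
  patt[!informative] <- NA
  reps <- character(0)
  for (key in unique(patt[!is.na(patt)])) {
    members <- ids[!is.na(patt) & patt == key]
    reps <- c(reps,
              members[.candidate_order(members, pos[members], priority)][1])
  }
  reps <- reps[.candidate_order(reps, pos[reps], priority)]
  n_class <- length(reps)

  lower <- ceiling(log2(nrow(g)))
  if (mode == "auto") {
    budget <- sum(choose(n_class, seq_len(min(n_class, exact_size_limit))))
    if (budget <= 2e5) {
      mode <- "exact"
    } else {
      mode <- "greedy"
      message(sprintf(
        "auto: %d SNP equivalence classes exceed the exact-search budget; greedy size is an upper bound on the minimum (lower bound %d)",
        n_class, lower))
    }
  }

  chosen <- NULL
  if (mode == "exact") {
    k_max <- min(n_class, exact_size_limit)
    if (lower > k_max) {
      stop("no discriminating subset of size <= ", k_max,
           " can exist (information bound ", lower, ")")
    }
    for (k in seq(from = lower, to = k_max)) {
      combs <- utils::combn(reps, k)
      for (ci in seq_len(ncol(combs))) {
        subset <- combs[, ci]
        if (all(rowSums(sep[, subset, drop = FALSE]) > 0)) {
          chosen <- subset
          break
        }
      }
      if (!is.null(chosen)) break
    }
    if (is.null(chosen)) {
      stop("no discriminating subset of size <= ", exact_size_limit,
           " found; raise exact_size_limit or use greedy mode")
    }
    method <- "exact"
  } else {
    uncovered <- rep(TRUE, nrow(pr))
    chosen <- character(0)
    avail <- reps
    while (any(uncovered)) {
      gain <- vapply(avail, function(s) sum(sep[uncovered, s]), numeric(1))
      if (max(gain) == 0) {
        stop("greedy cover stalled; groups are not pairwise separable")
      }
      pick <- avail[which.max(gain)]   # avail is in candidate order
      chosen <- c(chosen, pick)
      uncovered <- uncovered & !sep[, pick]
      avail <- setdiff(avail, pick)
    }
    method <- "greedy"
  }

  chosen <- chosen[order(pos[chosen], chosen)]
  coverage <- list()
  for (k in seq_len(nrow(pr))) {
    key <- paste(labs[pr[k, 1]], labs[pr[k, 2]], sep = "|")
    coverage[[key]] <- chosen[sep[k, chosen]]
  }
  structure(list(snp_ids = chosen, size = length(chosen),
                 pair_coverage = coverage, method = method,
                 lower_bound = lower),
            class = "TagSet")
}

#' @export
print.TagSet <- function(x, ...) {
  cat(sprintf("TagSet: %d SNP(s) [%s search]\n", x$size, x$method))
  cat(" ", paste(x$snp_ids, collapse = ", "), "\n")
  invisible(x)
}
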