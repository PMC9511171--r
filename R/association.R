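# Marker/haplotype-trait association: one-way fixed-effects ANOVA with
# percent variance explained (PVE = 100 * SS_between / SS_total), Tukey HSD
# significance letters, two-locus genotypic classes, and the gene-action
# contrasts read off the nine-class analysis.

#' One-way ANOVA with percent variance explained
#'
#' Samples with multiple environment records (e.g. two years) are averaged
#' per sample before fitting, so the line — not the plot — is the analysis
#' unit. PVE is the unadjusted R-squared of the one-way classification.
#' Significance letters come from Tukey HSD at `alpha` (classes sharing no
#' letter differ); classes with a single phenotyped sample are kept in the
#' means table but excluded from the letter procedure with a warning.
#'
#' @param pheno `data.frame` as from [read_phenotypes()] (columns
#'   `sample_id`, `value`, optionally `environment`).
#' @param classes Named character vector mapping sample id to class label.
#'   Samples labelled `NA` are dropped.
#' @param alpha Significance level for the letters.
#' @param classification Name recorded in the result (e.g.
#'   `"GS3 haplotype"`).
#' @return An `AssociationResult`: per-class table (`class`, `n`, `mean`,
#'   `sd`, `letter`), `F`, `p`, `pve`, `alpha`, and the per-sample `data`
#'   used for the fit.
#' @export
anova_pve <- function(pheno, classes, alpha = 0.05,
                      classification = "haplotype") {
  stopifnot(is.numeric(pheno$value), !is.null(pheno$sample_id))
  y_by_sample <- tapply(pheno$value, pheno$sample_id, mean)
  ids <- intersect(names(classes)[!is.na(classes)], names(y_by_sample))
  d <- data.frame(sample_id = ids, class = unname(classes[ids]),
                  y = as.numeric(y_by_sample[ids]),
                  stringsAsFactors = FALSE)
  cls_n <- table(d$class)
  if (length(cls_n) < 2) stop("need at least two classes with phenotyped samples")
  if (sum(cls_n >= 2) < 2) stop("need at least two classes with >= 2 phenotyped samples")

  grand <- mean(d$y)
  means <- tapply(d$y, d$class, mean)
  sds <- tapply(d$y, d$class, stats::sd)
  ss_total <- sum((d$y - grand)^2)
  ss_between <- sum(cls_n[names(means)] * (means - grand)^2)
  ss_within <- ss_total - ss_between
  df_b <- length(cls_n) - 1L
  df_w <- nrow(d) - length(cls_n)
  pve <- if (ss_total > 0) 100 * ss_between / ss_total else 0

  if (ss_within <= ss_total * 1e-12 || df_w == 0) {
    # Degenerate: no residual variance. F is infinite when classes differ.
    Fstat <- if (ss_between > 0) Inf else 0
    pval <- if (ss_between > 0) 0 else 1
    letters <- .letters_by_mean(means)
  } else {
    Fstat <- (ss_between / df_b) / (ss_within / df_w)
    pval <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
    letters <- .tukey_letters(d, cls_n, alpha)
  }

  tab <- data.frame(class = names(means), n = as.integer(cls_n[names(means)]),
                    mean = as.numeric(means), sd = as.numeric(sds),
                    letter = letters[names(means)],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean), ]
  rownames(tab) <- NULL
  structure(list(classification = classification, table = tab, F = Fstat,
                 p = pval, pve = pve, alpha = alpha, data = d),
            class = "AssociationResult")
}

.letters_by_mean <- function(means) {
  # Zero residual variance: every distinct mean is its own letter group.
  u <- sort(unique(means), decreasing = TRUE)
  stats::setNames(letters[match(means, u)], names(means))
}

.tukey_letters <- function(d, cls_n, alpha) {
  eligible <- names(cls_n)[cls_n >= 2]
  if (length(eligible) < length(cls_n)) {
    warning(sprintf("%d class(es) with n = 1 excluded from significance letters",
                    length(cls_n) - length(eligible)))
  }
  out <- stats::setNames(rep(NA_character_, length(cls_n)), names(cls_n))
  if (length(eligible) < 2) return(out)
  dd <- d[d$class %in% eligible, ]
  dd$class <- factor(dd$class)
  fit <- stats::aov(y ~ class, data = dd)
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(class = "Tukey"))
  # The single-step adjusted p values integrate a multivariate t by
  # quasi-Monte-Carlo; pin the stream so letters are reproducible, and
  # muffle the integrator's accuracy chatter (letters only need p vs
  # alpha, far from the reported error).
  lt <- .with_seed(1L, withCallingHandlers(
    multcomp::cld(glt, level = alpha, decreasing = TRUE)$mcletters$Letters,
    warning = function(w) {
      if (grepl("abseps|Completion", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out[names(lt)] <- unname(lt)
  out
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("AssociationResult (%s): F = %.3g, p = %.3g, PVE = %.1f%%\n",
              x$classification, x$F, x$p, x$pve))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Classify samples by two-locus genotype
#'
#' Builds the genotypic classes used for two-QTL interaction analysis from
#' the calls at one SNP per locus, given the long-allele orientation of
#' each. The four-class scheme (inbred lines) keeps homozygous states only
#' and drops heterozygous samples with a reported count: Class1 = long at
#' both loci, Class2 = long at A / medium at B, Class3 = medium at A / long
#' at B, Class4 = medium at both. The nine-class scheme (segregating
#' populations) enumerates homo-L/het/homo-M at both loci. Samples missing
#' either genotype are excluded and counted.
#'
#' @param calls_a,calls_b Named call vectors (REF/ALT/HET/MISSING) at the
#'   locus-A and locus-B SNPs, over the same samples.
#' @param long_allele Length-2 character vector: the allele (`"REF"` or
#'   `"ALT"`) associated with long grain at locus A and at locus B.
#' @param mode `"four"` or `"nine"`.
#' @param locus_names Labels used in nine-class labels.
#' @return List with `classes` (named character vector; `NA` for excluded
#'   samples), `n_het_dropped`, `n_missing_dropped`.
#' @export
classify_two_locus <- function(calls_a, calls_b,
                               long_allele = c(A = "ALT", B = "ALT"),
                               mode = c("four", "nine"),
                               locus_names = c("A", "B")) {
  mode <- match.arg(mode)
  stopifnot(length(calls_a) == length(calls_b),
            all(long_allele %in% c("REF", "ALT")))
  samples <- names(calls_a)
  if (is.null(samples)) samples <- as.character(seq_along(calls_a))
  state <- function(calls, long) {
    ifelse(calls == "HET", "het",
           ifelse(calls == "MISSING", NA,
                  ifelse(calls == long, "homo-L", "homo-M")))
  }
  sa <- state(calls_a, long_allele[1])
  sb <- state(calls_b, long_allele[2])
  miss <- is.na(sa) | is.na(sb)
  out <- rep(NA_character_, length(samples))
  if (mode == "four") {
    het <- !miss & (sa == "het" | sb == "het")
    keep <- !miss & !het
    lab <- c("homo-L.homo-L" = "Class1", "homo-L.homo-M" = "Class2",
             "homo-M.homo-L" = "Class3", "homo-M.homo-M" = "Class4")
    out[keep] <- lab[paste(sa[keep], sb[keep], sep = ".")]
    n_het <- sum(het)
  } else {
    keep <- !miss
    out[keep] <- paste0(locus_names[1], "-", sa[keep], "/",
                        locus_names[2], "-", sb[keep])
    n_het <- 0L
  }
  list(classes = stats::setNames(out, samples),
       n_het_dropped = as.integer(n_het),
       n_missing_dropped = as.integer(sum(miss)))
}

#' Gene-action contrasts from a nine-class analysis
#'
#' Reads dominance off the nine genotypic classes: for each locus, within
#' each fixed state of the other locus, contrasts the heterozygous class
#' against each homozygous class (het vs homo-L, het vs homo-M). A fully
#' recessive long allele shows het ~ homo-M (non-significant) and het <
#' homo-L (significant); an additive locus shows both contrasts
#' significant. Tests use the pooled residual variance of the nine-class
#' one-way fit. A per-locus call summarises the pattern, with an explicit
#' `"insufficient evidence"` marker when no heterozygote contrast reaches
#' `alpha`.
#'
#' @param result An [anova_pve()] result fitted on nine-class labels of the
#'   form produced by [classify_two_locus()] with `mode = "nine"`.
#' @param alpha Significance level for the contrast flags.
#' @return List with `contrasts` (`data.frame`: locus, fixed state, the two
#'   classes, mean difference, SE, t, p, `significant`, `estimable`) and
#'   `gene_action` (named character: per-locus call).
#' @export
gene_action_report <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "AssociationResult"))
  d <- result$data
  parts <- strsplit(d$class, "/", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("gene_action_report needs nine-class labels of the form 'A-state/B-state'")
  }
  locus_a <- sub("-(homo-L|homo-M|het)$", "", vapply(parts, `[`, "", 1))[1]
  locus_b <- sub("-(homo-L|homo-M|het)$", "", vapply(parts, `[`, "", 2))[1]
  st_a <- sub("^.*?-(homo-L|homo-M|het)$", "\\1", vapply(parts, `[`, "", 1))
  st_b <- sub("^.*?-(homo-L|homo-M|het)$", "\\1", vapply(parts, `[`, "", 2))

  # Pooled residual variance over all populated classes.
  cls_n <- table(d$class)
  mse <- {
    dev <- d$y - stats::ave(d$y, d$class)
    dfw <- nrow(d) - sum(cls_n > 0)
    if (dfw > 0) sum(dev^2) / dfw else NA_real_
  }
  dfw <- nrow(d) - sum(cls_n > 0)

  one_contrast <- function(locus, fixed_state, st_self, st_other, a, b) {
    in_fixed <- st_other == fixed_state
    ya <- d$y[in_fixed & st_self == a]
    yb <- d$y[in_fixed & st_self == b]
    est <- length(ya) >= 1 && length(yb) >= 1 && !is.na(mse) && dfw > 0
    if (est) {
      diff <- mean(ya) - mean(yb)
      se <- sqrt(mse * (1 / length(ya) + 1 / length(yb)))
      tval <- diff / se
      pval <- 2 * stats::pt(abs(tval), dfw, lower.tail = FALSE)
    } else {
      diff <- se <- tval <- pval <- NA_real_
    }
    data.frame(locus = locus, fixed = fixed_state,
               class_i = a, class_j = b, n_i = length(ya),
               n_j = length(yb), diff = diff, se = se, t = tval, p = pval,
               significant = est && pval < alpha, estimable = est,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (fx in c("homo-L", "het", "homo-M")) {
    rows[[length(rows) + 1L]] <-
      one_contrast(locus_a, fx, st_a, st_b, "het", "homo-M")
    rows[[length(rows) + 1L]] <-
      one_contrast(locus_a, fx, st_a, st_b, "het", "homo-L")
    rows[[length(rows) + 1L]] <-
      one_contrast(locus_b, fx, st_b, st_a, "het", "homo-M")
    rows[[length(rows) + 1L]] <-
      one_contrast(locus_b, fx, st_b, st_a, "het", "homo-L")
  }
  contrasts <- do.call(rbind, rows)

  call_for <- function(locus) {
    cc <- contrasts[contrasts$locus == locus & contrasts$estimable, ]
    if (nrow(cc) == 0) return("not estimable")
    sig_vs_m <- any(cc$significant[cc$class_j == "homo-M"])
    sig_vs_l <- any(cc$significant[cc$class_j == "homo-L"])
    if (!sig_vs_m && sig_vs_l) "long allele recessive"
    else if (sig_vs_m && !sig_vs_l) "long allele dominant"
    else if (sig_vs_m && sig_vs_l) "additive/partial dominance"
    else "insufficient evidence"
  }
  ga <- stats::setNames(c(call_for(locus_a), call_for(locus_b)),
                        c(locus_a, locus_b))
  list(contrasts = contrasts, gene_action = ga, alpha = alpha)
}
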