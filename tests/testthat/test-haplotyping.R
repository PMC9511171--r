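test_that("complete samples group by exact allele-vector identity with a rare set", {
  vm <- make_vm(c(a = "RRR", b = "RRR", c = "RRR", d = "AAA", e = "AAA",
                  f = "RRA"))
  part <- characterize_haplotypes(vm, rare_rule("min_count", 2))
  expect_equal(length(part$groups), 2)
  expect_equal(part$groups[[1]]$label, "Hap1")
  expect_equal(part$groups[[1]]$n, 3L)
  expect_equal(part$groups[[2]]$n, 2L)
  expect_equal(part$rare_samples, "f")
  expect_equal(unname(part$assignments[c("a", "d", "f")]),
               c("Hap1", "Hap2", "RARE"))
})

test_that("partial vectors assign to a unique compatible named group, else fall through", {
  # groups RRR (x3) and AAA (x2); "RNR" matches only Hap1
  vm <- make_vm(c(a = "RRR", b = "RRR", c = "RRR", d = "AAA", e = "AAA",
                  p = "RNR"))
  part <- characterize_haplotypes(vm, rare_rule("min_count", 2))
  expect_equal(unname(part$assignments["p"]), "Hap1")
  expect_equal(part$groups[[1]]$n, 4L)

  # "NAA" is compatible with both RAA and AAA -> unclassified
  vm2 <- make_vm(c(a = "RAA", b = "RAA", c = "AAA", d = "AAA", p = "NAA"))
  part2 <- characterize_haplotypes(vm2, rare_rule("min_count", 2))
  expect_equal(unname(part2$assignments["p"]), "UNCLASSIFIED")
  expect_true("p" %in% part2$unclassified_samples)

  # partial compatible only with an observed rare vector -> RARE
  vm3 <- make_vm(c(a = "RRR", b = "RRR", r = "AAA", p = "NAA"))
  part3 <- characterize_haplotypes(vm3, rare_rule("min_count", 2))
  expect_equal(unname(part3$assignments["r"]), "RARE")
  expect_equal(unname(part3$assignments["p"]), "RARE")
})

test_that("groups, rare and unclassified partition every sample exactly", {
  set.seed(21)
  for (rep in 1:8) {
    vm <- random_vm(60, 6, missing_rate = 0.2)
    part <- characterize_haplotypes(vm, rare_rule("min_count", 4))
    member_ids <- unlist(lapply(part$groups, `[[`, "members"))
    all_ids <- c(member_ids, part$rare_samples, part$unclassified_samples)
    expect_equal(sort(all_ids), sort(vm$samples))
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_equal(sum(vapply(part$groups, `[[`, integer(1), "n")) +
                   length(part$rare_samples) +
                   length(part$unclassified_samples), length(vm$samples))
    # every named group satisfies the rare rule on complete-call members
    for (g in part$groups) expect_gte(g$n, 1)
  }
})

test_that("sample order does not change group membership", {
  set.seed(31)
  vm <- random_vm(50, 5, missing_rate = 0.15)
  part1 <- characterize_haplotypes(vm, rare_rule("min_count", 3))
  perm <- sample(vm$samples)
  vm2 <- subset_matrix(vm, samples = perm)
  part2 <- characterize_haplotypes(vm2, rare_rule("min_count", 3))
  key <- function(p) {
    sets <- lapply(p$groups, function(g) sort(g$members))
    sets[order(vapply(sets, paste, "", collapse = ","))]
  }
  expect_identical(key(part1), key(part2))
  expect_identical(sort(part1$rare_samples), sort(part2$rare_samples))
  expect_identical(sort(part1$unclassified_samples),
                   sort(part2$unclassified_samples))
})

test_that("frequency-mode rare rule names groups at or above the floor", {
  vm <- make_vm(c(a = "RR", b = "RR", c = "RR", d = "AA", e = "RA",
                  f = "RR", g = "RR", h = "RR", i = "RR", j = "RR"))
  # RR: 8/10 = 0.8, AA: 0.1, RA: 0.1; floor 0.1 names all three
  part <- characterize_haplotypes(vm, rare_rule("min_frequency", 0.1))
  expect_equal(length(part$groups), 3)
  part2 <- characterize_haplotypes(vm, rare_rule("min_frequency", 0.15))
  expect_equal(length(part2$groups), 1)
  expect_equal(length(part2$rare_samples), 2)
})

test_that("coverage percent is rounded half-up on the printed scale", {
  expect_identical(coverage_percent(2222, 2426), 92L)
  expect_identical(coverage_percent(2873, 2993), 96L)
  expect_identical(coverage_percent(0, 10), 0L)
  expect_identical(coverage_percent(1, 200), 1L)   # 0.5 rounds up
  expect_error(coverage_percent(1, 0), "positive")
})

test_that("composition summary rolls subpopulations up to varietal groups", {
  vm <- make_vm(c(a = "RR", b = "RR", c = "RR", d = "RR"))
  part <- characterize_haplotypes(vm, rare_rule("min_count", 1))
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     subpopulation = c("indica", "indica", "aus",
                                       "tropical-japonica"),
                     grain_class = c("long", "long", "short", "long"),
                     stringsAsFactors = FALSE)
  comp <- composition_summary(part, meta)
  vg <- comp[comp$group == "Hap1" & comp$category_type == "varietal_group", ]
  expect_equal(vg$pct[vg$category == "Indica"], 75)
  expect_equal(vg$pct[vg$category == "Japonica"], 25)
  # within-group percentages sum to 100 per category type
  for (ct in unique(comp$category_type)) {
    expect_equal(sum(comp$pct[comp$group == "Hap1" &
                                comp$category_type == ct]), 100,
                 tolerance = 0.05)
  }
  # absent metadata counts as unknown
  comp2 <- composition_summary(part, meta[1:2, ])
  sp <- comp2[comp2$group == "Hap1" & comp2$category_type == "subpopulation", ]
  expect_equal(sp$n[sp$category == "unknown"], 2L)
})

test_that("survey matches tag alleles, flags het/missing as unclassified, reports novel vectors", {
  groups <- make_groups(c("000", "011", "110"))
  vm <- make_vm(c(a = "RAA", b = "RAA", c = "RAA", d = "RAA", e = "RAA",
                  h = "RHA", m = "RNA", n = "AAA"))
  sv <- survey_panel(vm, groups)
  expect_equal(sv$groups[[2]]$n, 5L)          # Hap2 = 011
  expect_equal(unname(sv$assignments[c("h", "m")]),
               c("UNCLASSIFIED", "UNCLASSIFIED"))
  expect_equal(unname(sv$assignments["n"]), "NOVEL")
  expect_equal(length(sv$novel), 1)
  expect_equal(sv$novel[[1]]$samples, "n")
  # indistinguishable reference groups on the chosen SNPs -> error
  expect_error(survey_panel(vm, make_groups(c("000", "001")),
                            snp_ids = c("snp1", "snp2")),
               "not distinguishable")
})

test_that("survey via a valid tag set reproduces full-vector labels for complete samples", {
  sim <- generate_panel(paper_like_preset(n_samples = 400, seed = 9))
  vm <- sim$matrices$GS3
  flt <- apply_cascade(vm, filter_preset("3krgp")$filter)
  part <- characterize_haplotypes(flt$matrix, rare_rule("min_count", 5))
  ts <- minimum_tag_set(part$groups,
                        snp_pos = stats::setNames(part$snps$pos,
                                                  part$snps$id))
  sv <- survey_panel(flt$matrix, part$groups, ts$snp_ids)
  complete <- rowSums(flt$matrix$calls == "MISSING") == 0
  ids <- flt$matrix$samples[complete]
  full_named <- part$assignments[ids] %in%
    vapply(part$groups, `[[`, "", "label")
  expect_true(all(sv$assignments[ids][full_named] ==
                    part$assignments[ids][full_named]))
})
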