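ph <- function(ids, values) {
  data.frame(sample_id = ids, trait = "grain_length", environment = "e1",
             value = values, stringsAsFactors = FALSE)
}

test_that("PVE spans its extremes: perfect separation and equal means", {
  p <- ph(c("a", "b", "c", "d"), c(7, 7, 5, 5))
  cls <- stats::setNames(c("L", "L", "M", "M"), c("a", "b", "c", "d"))
  res <- anova_pve(p, cls)
  expect_equal(res$pve, 100)
  expect_equal(res$p, 0)
  lt <- stats::setNames(res$table$letter, res$table$class)
  expect_false(lt["L"] == lt["M"])   # distinct letters

  # same value distribution split into two labels -> nothing explained
  p2 <- ph(c("a", "b", "c", "d"), c(5, 7, 5, 7))
  cls2 <- stats::setNames(c("X", "X", "Y", "Y"), c("a", "b", "c", "d"))
  expect_equal(anova_pve(p2, cls2)$pve, 0)

  # equal class means {6,8} vs {5,9} -> between-SS is zero
  p3 <- ph(c("a", "b", "c", "d"), c(6, 8, 5, 9))
  expect_equal(anova_pve(p3, cls2)$pve, 0)
})

test_that("PVE is invariant to phenotype shift and positive rescaling", {
  set.seed(61)
  ids <- paste0("s", 1:40)
  vals <- rnorm(40, mean = rep(c(6, 7), each = 20), sd = 0.3)
  cls <- stats::setNames(rep(c("A", "B"), each = 20), ids)
  base <- anova_pve(ph(ids, vals), cls)$pve
  expect_equal(anova_pve(ph(ids, vals + 100), cls)$pve, base,
               tolerance = 1e-9)
  expect_equal(anova_pve(ph(ids, vals * 3.7), cls)$pve, base,
               tolerance = 1e-9)
})

test_that("replicate environment records are averaged per line before fitting", {
  p <- rbind(ph(c("a", "b"), c(6, 8)),
             data.frame(sample_id = c("a", "b"), trait = "grain_length",
                        environment = "e2", value = c(8, 6)))
  cls <- stats::setNames(c("X", "Y"), c("a", "b"))
  p2 <- rbind(p, ph(c("c", "d"), c(7, 7)))
  cls2 <- c(cls, stats::setNames(c("X", "Y"), c("c", "d")))
  res <- anova_pve(p2, cls2)
  # both lines average to 7, so class means are equal
  expect_equal(res$pve, 0, tolerance = 1e-9)
})

test_that("singleton classes stay in the means table but not the letters", {
  p <- ph(c("a", "b", "c", "d", "e"), c(6.1, 6.3, 7.0, 7.2, 9.9))
  cls <- stats::setNames(c("A", "A", "B", "B", "C"),
                         c("a", "b", "c", "d", "e"))
  expect_warning(res <- anova_pve(p, cls), "n = 1")
  expect_true("C" %in% res$table$class)
  expect_true(is.na(res$table$letter[res$table$class == "C"]))
  expect_false(any(is.na(res$table$letter[res$table$class != "C"])))
  expect_error(anova_pve(p, stats::setNames(rep("A", 5), names(cls))),
               "two classes")
})

test_that("four-class mode drops heterozygotes; nine-class mode keeps them", {
  calls_a <- stats::setNames(c("ALT", "ALT", "REF", "HET", "MISSING"),
                             paste0("s", 1:5))
  calls_b <- stats::setNames(c("ALT", "REF", "ALT", "REF", "ALT"),
                             paste0("s", 1:5))
  long <- c(A = "ALT", B = "ALT")
  four <- classify_two_locus(calls_a, calls_b, long, mode = "four")
  expect_equal(unname(four$classes[1:3]), c("Class1", "Class2", "Class3"))
  expect_true(is.na(four$classes["s4"]))
  expect_equal(four$n_het_dropped, 1L)
  expect_equal(four$n_missing_dropped, 1L)

  nine <- classify_two_locus(calls_a, calls_b, long, mode = "nine",
                             locus_names = c("A", "B"))
  expect_equal(unname(nine$classes["s4"]), "A-het/B-homo-M")
  expect_equal(unname(nine$classes["s1"]), "A-homo-L/B-homo-L")
  expect_true(is.na(nine$classes["s5"]))
  # long-allele orientation flips the class labels
  four_flip <- classify_two_locus(calls_a, calls_b, c(A = "REF", B = "ALT"),
                                  mode = "four")
  expect_equal(unname(four_flip$classes[1]), "Class3")
})

test_that("gene-action contrasts recover programmed dominance", {
  run_sim <- function(dominance, seed) {
    spec <- paper_like_preset(n_samples = 900, seed = seed)
    spec$het_rate <- 0.25
    spec$missing_rate <- 0
    spec$phenotype$dominance_a <- dominance
    sim <- generate_panel(spec)
    cls <- stats::setNames(sim$truth$class9, sim$truth$sample_id)
    gene_action_report(anova_pve(sim$pheno, cls, alpha = 0.001),
                       alpha = 0.001)
  }
  rec <- run_sim("recessive-long", 71)
  expect_equal(unname(rec$gene_action["GS3"]), "long allele recessive")
  ca <- rec$contrasts[rec$contrasts$locus == "GS3" & rec$contrasts$estimable, ]
  expect_false(any(ca$significant[ca$class_j == "homo-M"]))
  expect_true(any(ca$significant[ca$class_j == "homo-L"]))

  add <- run_sim("additive", 72)
  expect_equal(unname(add$gene_action["GS3"]), "additive/partial dominance")
})

test_that("empty contrast cells are marked not estimable", {
  # no heterozygotes at locus B at all -> het-B contrasts inestimable
  ids <- paste0("s", 1:12)
  cls <- stats::setNames(rep(c("A-homo-L/B-homo-L", "A-homo-M/B-homo-L",
                               "A-het/B-homo-L"), each = 4), ids)
  p <- ph(ids, rnorm(12, 7, 0.2))
  ga <- gene_action_report(anova_pve(p, cls))
  cb <- ga$contrasts[ga$contrasts$locus == "B", ]
  expect_false(any(cb$estimable))
  expect_equal(unname(ga$gene_action["B"]), "not estimable")
})
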