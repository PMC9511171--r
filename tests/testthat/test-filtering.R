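test_that("minor allele frequency counts non-missing homozygous calls only", {
  expect_equal(minor_allele_frequency(c("REF", "REF", "ALT", "ALT")), 0.5)
  expect_equal(minor_allele_frequency(c(rep("REF", 999), "ALT")), 0.001)
  expect_equal(minor_allele_frequency(
    c("REF", "MISSING", "MISSING", "ALT", "ALT")), 1 / 3)
  expect_equal(minor_allele_frequency(c("REF", "HET", "ALT")), 0.5)
  expect_error(minor_allele_frequency(c("MISSING", "MISSING")), "undefined")
})

test_that("thresholds are strict: boundary missingness and MAF are retained", {
  # SNP 1: exactly 0.2 missing -> kept at snp_missing_max = 0.2
  vm <- make_vm(c("RR", "RR", "AR", "AR", "NA"))
  res <- apply_cascade(vm, filter_params(TRUE, 0.2, 0.2, 0.001, FALSE))
  expect_true("snp1" %in% res$matrix$variants$id)
  # MAF exactly at the floor is kept, strictly below is dropped
  vm2 <- make_vm(c("RR", "RR", "RR", "RR", "RA", "RA", "RA", "RA", "RA",
                   "AA"))
  # snp1 MAF = 0.1, snp2 MAF = 0.5
  res2 <- apply_cascade(vm2, filter_params(TRUE, 0.2, 0.2, 0.2, FALSE))
  expect_equal(res2$matrix$variants$id, "snp2")
  res3 <- apply_cascade(vm2, filter_params(TRUE, 0.2, 0.2, 0.1, FALSE))
  expect_equal(res3$matrix$variants$id, c("snp1", "snp2"))
})

test_that("het recoding feeds the SNP-missingness stage", {
  # one all-HET SNP among four: recoded to missing, dropped at stage 2
  vm <- make_vm(c("HRRR", "HRRR", "HAAA", "HAAA", "HRAR", "HARA"))
  res <- apply_cascade(vm, filter_params(TRUE, 0.2, 0.5, 0.001, FALSE))
  expect_false("snp1" %in% res$matrix$variants$id)
  st <- res$report
  expect_equal(st$snps_after[st$stage == "snp_missingness"], 3L)
  # without het recoding (and no MAF floor) the SNP survives
  res2 <- apply_cascade(vm, filter_params(FALSE, 0.2, 0.5, 0, FALSE))
  expect_true("snp1" %in% res2$matrix$variants$id)
})

test_that("cascade is idempotent at realistic missingness and every drop is attributable to one stage", {
  # Idempotence is a property of the data regime, not of the algorithm:
  # removing samples at stage 3 can in principle push a surviving SNP's
  # missing fraction back over the cap. At the missingness levels the
  # thresholds are designed for (a few percent per call, caps of 0.15-0.2)
  # a second pass is a no-op; assert that on toy and simulated panels.
  set.seed(11)
  sim <- generate_panel(paper_like_preset(n_samples = 400, seed = 11))
  fixtures <- c(list(make_vm(c("HRRR", "HRRR", "HAAA", "HAAA", "HRAR",
                               "HARA")),
                     make_vm(c("RR", "RR", "AR", "AR", "NA")),
                     sim$matrices$GS3, sim$matrices$`qGL7.1`),
                lapply(1:3, function(i) random_vm(40, 12,
                                                  missing_rate = 0.04)))
  for (vm in fixtures) {
    p <- filter_params(TRUE, 0.2, 0.2, 0.05, FALSE)
    once <- apply_cascade(vm, p)
    twice <- apply_cascade(once$matrix, p)
    expect_identical(twice$matrix$calls, once$matrix$calls)
    # stage accounting chains: before(k) == after(k-1), final == dims
    st <- once$report
    expect_equal(st$snps_before[-1], st$snps_after[-nrow(st)])
    expect_equal(st$samples_before[-1], st$samples_after[-nrow(st)])
    expect_equal(st$snps_after[nrow(st)], ncol(once$matrix$calls))
    expect_equal(st$samples_after[nrow(st)], nrow(once$matrix$calls))
    expect_true(all(st$snps_after <= st$snps_before))
    expect_true(all(st$samples_after <= st$samples_before))
  }
})

test_that("sample filtering before MAF is order-sensitive by design", {
  # SNP X's only ALT carrier is a high-missingness sample that stage 3
  # removes, after which X is monomorphic and stage 4 drops it. Running
  # MAF before the sample stage would keep X.
  vm <- make_vm(c(S1 = "ANNNR", S2 = "RRARR", S3 = "RRRAR", S4 = "RARRA",
                  S5 = "RRARA"))
  p <- filter_params(FALSE, 0.25, 0.2, 0.15, FALSE)
  standard <- apply_cascade(vm, p)
  expect_false("snp1" %in% standard$matrix$variants$id)
  expect_false("S1" %in% standard$matrix$samples)

  # emulate the swapped order with two passes: MAF first (sample stage
  # disabled), then the sample stage alone
  maf_first <- apply_cascade(vm, filter_params(FALSE, 0.25, 1, 0.15, FALSE))
  swapped <- apply_cascade(maf_first$matrix,
                           filter_params(FALSE, 1, 0.2, 0, FALSE))
  expect_true("snp1" %in% swapped$matrix$variants$id)
  expect_false(setequal(swapped$matrix$variants$id,
                        standard$matrix$variants$id))
})

test_that("monomorphic stage exists only when enabled and empty results are named errors", {
  vm <- make_vm(c("RR", "RA", "AR", "RA"))
  with_mono <- apply_cascade(vm, filter_params(TRUE, 1, 1, 0, TRUE))
  expect_true("monomorphic" %in% with_mono$report$stage)
  without <- apply_cascade(vm, filter_params(TRUE, 1, 1, 0, FALSE))
  expect_false("monomorphic" %in% without$report$stage)

  all_missing <- make_vm(c("NN", "NN", "NN"))
  expect_error(apply_cascade(all_missing, filter_params()),
               "snp_missingness")
  mono <- make_vm(c("RR", "RR", "RR"))
  expect_error(apply_cascade(mono, filter_params(TRUE, 1, 1, 0.001, FALSE)),
               "maf")
})

test_that("presets carry the published thresholds", {
  p3 <- filter_preset("3krgp")
  expect_equal(p3$filter$snp_missing_max, 0.2)
  expect_equal(p3$filter$sample_missing_max, 0.2)
  expect_equal(p3$filter$maf_min, 0.001)
  expect_false(p3$filter$drop_monomorphic)
  expect_equal(p3$rare$mode, "min_count")
  expect_equal(p3$rare$threshold, 30)
  ph <- filter_preset("hdra-us")
  expect_equal(ph$filter$snp_missing_max, 0.15)
  expect_equal(ph$filter$maf_min, 0.02)
  expect_true(ph$filter$drop_monomorphic)
  expect_equal(ph$rare$mode, "min_frequency")
  expect_equal(ph$rare$threshold, 0.05)
})
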