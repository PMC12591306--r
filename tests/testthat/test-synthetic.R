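test_that("the default cohort reproduces the study's group structure", {
  co <- simulateCohort(seed = 1)
  expect_equal(nrow(co), 358L)
  expect_equal(as.integer(table(co$group)[c("control", "low", "high")]),
               c(110L, 115L, 133L))
  expect_true(all(co$dose_gbq[co$group == "control"] == 0))
  expect_true(all(co$dose_gbq[co$group == "low"] > 1.11 - 1e-9 &
                    co$dose_gbq[co$group == "low"] < 7.4))
  expect_true(all(co$dose_gbq[co$group == "high"] >= 7.4))
  expect_true(all(is.na(co$age_rait[co$group == "control"])))
  treated <- co[co$group != "control", ]
  expect_true(all(treated$elapsed_months >= 12))
  expect_true(all(treated$age_rait >= 19))
  # reproducibility and sensitivity to the seed
  expect_identical(co, simulateCohort(seed = 1))
  expect_false(identical(co$age_ch, simulateCohort(seed = 2)$age_ch))
  # empty groups are honoured
  none <- simulateCohort(cohortSimParams(n_control = 0L, n_low = 3L,
                                         n_high = 4L), seed = 1)
  expect_equal(sum(none$dose_gbq == 0), 0L)
})

test_that("simulated covariate means hit their targets within 3 SE", {
  big <- simulateCohort(cohortSimParams(n_control = 10000L, n_low = 0L,
                                        n_high = 10000L), seed = 4)
  ctrl <- big[big$group == "control", ]
  expect_lt(abs(mean(ctrl$age_ch) - 60.0), 3 * 14.5 / 100 + 0.1)
  expect_lt(abs(mean(ctrl$sex == "female") - 0.855), 3 * 0.0036)
  high <- big[big$group == "high", ]
  expect_lt(abs(mean(high$dose_gbq) - 23.9), 3 * 16.5 / 100)
})

test_that("simulated CDS panels satisfy the coding constraints", {
  panel <- simulateCdsPanel(5, 100, seed = 2)
  expect_length(panel, 5L)
  for (g in panel) {
    expect_equal(nchar(g@cds), 303L)          # 100 codons + stop
    aa <- translateCds(g@cds)
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(substr(g@cds, 1, 3), "ATG")
  }
  again <- simulateCdsPanel(5, 100, seed = 2)
  expect_identical(vapply(panel, function(g) g@cds, character(1)),
                   vapply(again, function(g) g@cds, character(1)))
})

test_that("zero rates give an empty truth set and VAFs respect the floor", {
  co <- simulateCohort(cohortSimParams(5L, 5L, 5L), seed = 1)
  panel <- simulateCdsPanel(3, 60, seed = 1)
  zero <- effectConfig(base_rates = c(synonymous = 0, missense = 0,
                                      nonsense = 0, frameshift = 0,
                                      splice_site = 0, inframe_indel = 0))
  expect_equal(nrow(simulateTruthMutations(co, zero, panel, seed = 1)), 0L)
  truth <- simulateTruthMutations(co, effectConfig(), panel, seed = 1)
  expect_true(all(truth$true_vaf > 0.005))
  expect_identical(truth,
                   simulateTruthMutations(co, effectConfig(), panel,
                                          seed = 1))
})

test_that("truth mutations are independent of covariates under null
          effects", {
  set.seed(30)
  n <- 2000
  co <- data.frame(sample_id = sprintf("N%04d", 1:n),
                   age_ch = runif(n, 30, 80),
                   dose_gbq = runif(n, 0, 30))
  panel <- simulateCdsPanel(1, 80, seed = 30, gene_names = "PPM1D")
  eff <- effectConfig(base_rates = c(missense = 0.5),
                      age_effect = c(PPM1D = 1), age_default = 1,
                      dose_effect = list())
  truth <- simulateTruthMutations(co, eff, panel, seed = 30)
  has <- co$sample_id %in% truth$sample_id
  pAge <- chisq.test(table(has, co$age_ch > 55))$p.value
  pDose <- chisq.test(table(has, co$dose_gbq > 15))$p.value
  expect_gt(pAge, 0.01)
  expect_gt(pDose, 0.01)
})

test_that("a planted dose effect on truncating PPM1D is recovered", {
  panel <- simulateCdsPanel(1, 80, seed = 33, gene_names = "PPM1D")
  eff <- effectConfig(base_rates = c(nonsense = 0.25),
                      age_effect = c(PPM1D = 1), age_default = 1,
                      dose_effect = list(PPM1D = c(truncating = 1.5)))
  set.seed(33)
  signs <- vapply(1:200, function(r) {
    n <- 150
    co <- data.frame(sample_id = sprintf("D%03d", 1:n),
                     age_ch = runif(n, 40, 70),
                     dose_gbq = runif(n, 0, 10))
    truth <- simulateTruthMutations(co, eff, panel, seed = 33000 + r)
    has <- as.numeric(co$sample_id %in% truth$sample_id)
    coef(glm(has ~ co$dose_gbq, family = binomial()))[2] > 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("rendered calls carry construction-guaranteed violations", {
  co <- simulateCohort(cohortSimParams(10L, 10L, 10L), seed = 6)
  panel <- simulateCdsPanel(4, 100, seed = 6)
  mask <- RegionMask("chr_DNMT3A", 1200L, 1240L, flank_bp = 5L)
  eff <- effectConfig()
  truth <- simulateTruthMutations(co, eff, panel, seed = 6, mask = mask)
  raw <- renderRawCalls(truth, eff, co, panel, mask, seed = 6)
  df <- variants(raw$variants)
  lbl <- raw$truth$label

  expect_true(all(df$popaf_exome[lbl == "germline_leak"] > 0.01))
  expect_true(all(df$alt_rev[lbl == "strand_bias"] == 0))
  expect_true(all(df$f2r1[lbl == "orientation_bias"] == 0))
  expect_true(all(df$depth[lbl == "low_depth"] <= 400))
  expect_true(all(applyRegionMask(
    VariantSet(df[lbl == "masked_region", ]), mask)))
  recKeys <- unique(variantKey(df[lbl == "recurrent", ]))
  for (k in recKeys)
    expect_gt(length(unique(df$sample_id[variantKey(df) == k &
                                           lbl == "recurrent"])) / 30, 0.10)
  # emitted true calls always clear the observed-VAF floor
  expect_true(all(df$vaf[lbl == "true_CH"] > 0.005))

  # artifact rates of zero leave only true calls
  quiet <- effectConfig(artifact_rates = c(germline_leak = 0,
                                           strand_bias = 0,
                                           orientation_bias = 0,
                                           masked_region = 0,
                                           low_depth = 0),
                        recurrent_keys = 0L)
  raw0 <- renderRawCalls(truth, quiet, co, panel, mask, seed = 6)
  expect_true(all(raw0$truth$label == "true_CH"))
})

test_that("each artifact class alone is fully removed by its filter", {
  co <- simulateCohort(cohortSimParams(10L, 10L, 10L), seed = 7)
  panel <- simulateCdsPanel(3, 100, seed = 7)
  mask <- RegionMask("chr_DNMT3A", 1150L, 1200L, flank_bp = 5L)
  emptyTruth <- simulateTruthMutations(co, effectConfig(
    base_rates = c(missense = 0)), panel, seed = 7)
  classes <- c("germline_leak", "strand_bias", "orientation_bias",
               "masked_region", "low_depth")
  expectFilter <- c(germline_leak = "germline", strand_bias = "strand_bias",
                    orientation_bias = "orientation_bias",
                    masked_region = "region_mask",
                    low_depth = "low_confidence")
  for (cl in classes) {
    rates <- setNames(as.numeric(classes == cl), classes)
    eff <- effectConfig(artifact_rates = rates, recurrent_keys = 0L)
    raw <- renderRawCalls(emptyTruth, eff, co, panel, mask, seed = 7)
    if (!length(raw$variants)) next
    res <- runFilterPipeline(raw$variants, mask, n_samples = 30)
    expect_equal(length(res$retained), 0L)
    expect_true(all(res$audit@perVariant$first_fail == expectFilter[[cl]]))
  }
  # recurrent alone
  eff <- effectConfig(artifact_rates = setNames(numeric(5), classes),
                      recurrent_keys = 2L)
  raw <- renderRawCalls(emptyTruth, eff, co, panel, mask, seed = 7)
  res <- runFilterPipeline(raw$variants, mask, n_samples = 30)
  expect_equal(length(res$retained), 0L)
  expect_true(all(res$audit@perVariant$first_fail == "recurrent"))
})

test_that("paired cohorts have the linked structure and limiting
          behaviours", {
  sim <- simulatePairedCohort(n_pairs = 24, seed = 8)
  expect_equal(nrow(sim$cohort), 48L)
  expect_equal(sum(!is.na(sim$cohort$paired_pre_sample)), 24L)
  expect_true(all(sim$cohort$paired_pre_sample[
    !is.na(sim$cohort$paired_pre_sample)] %in% sim$cohort$sample_id))

  frozen <- simulatePairedCohort(n_pairs = 6, drift_sd = 0, drop_rate = 0,
                                 add_mean = 0, seed = 9)
  res <- runLongitudinal(frozen$variants, frozen$cohort)
  expect_true(all(res$paired$category == "unchanged"))

  wiped <- simulatePairedCohort(n_pairs = 6, drift_sd = 0, drop_rate = 1,
                                add_mean = 0, seed = 10)
  resW <- runLongitudinal(wiped$variants, wiped$cohort)
  expect_true(all(resW$paired$category == "vanished_decreased"))
})
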