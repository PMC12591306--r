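test_that("orientation and strand bias tests match closed forms", {
  balanced <- makeVariants(1, f1r2 = 10L, f2r1 = 10L)
  b <- assessSequenceBias(balanced, 0.05, 0.05)
  expect_false(b$orientation_fail)

  oneSided <- makeVariants(1, f1r2 = 20L, f2r1 = 0L)
  b2 <- assessSequenceBias(oneSided, 0.05, 0.05)
  expect_true(b2$orientation_fail)
  expect_equal(b2$orientation_p, 2 * 0.5^20, tolerance = 1e-12)

  sameProp <- makeVariants(1, ref_fwd = 50L, ref_rev = 50L,
                           alt_fwd = 15L, alt_rev = 15L, depth = 130L,
                           alt_count = 30L)
  expect_false(assessSequenceBias(sameProp, 0.05, 0.05)$strand_fail)

  biased <- makeVariants(1, ref_fwd = 500L, ref_rev = 480L,
                         alt_fwd = 20L, alt_rev = 0L, depth = 1000L,
                         alt_count = 20L)
  expect_true(assessSequenceBias(biased, 0.05, 0.05)$strand_fail)

  missing <- makeVariants(1, f1r2 = NA_integer_, f2r1 = NA_integer_,
                          ref_fwd = NA_integer_, ref_rev = NA_integer_,
                          alt_fwd = NA_integer_, alt_rev = NA_integer_)
  bm <- assessSequenceBias(missing, 0.05, 0.05)
  expect_true(bm$untestable)
  expect_false(bm$orientation_fail)   # untestable variants pass

  neg <- makeVariants(1, alt_fwd = -1L)
  expect_error(suppressWarnings(assessSequenceBias(neg, 0.05, 0.05)),
               "negative")
})

test_that("germline rules drop population-frequent and high-VAF calls", {
  g <- applyGermlineFilters(makeVariants(1, popaf_exome = 0.02))
  expect_equal(g$reason, "popAF")
  g2 <- applyGermlineFilters(makeVariants(1, alt_count = 360L,
                                          popaf_exome = NA_real_))
  expect_equal(g2$reason, "VAF35")            # VAF 0.36, popAF missing
  g3 <- applyGermlineFilters(makeVariants(1, alt_count = 340L,
                                          popaf_exome = 1e-4))
  expect_true(g3$keep)                        # VAF 0.34 passes everything
  vs <- makeVariants(1, alt_count = 250L)     # VAF 0.25
  key <- variantKey(variants(vs))
  g4 <- applyGermlineFilters(vs, review_keys = key)
  expect_equal(g4$reason, "review-germline")
  g5 <- applyGermlineFilters(vs, review_keys = "chrX:1:A:G")
  expect_true(g5$keep)                        # not in the review resource
  g6 <- applyGermlineFilters(makeVariants(1, popaf_genome = 0.011))
  expect_equal(g6$reason, "popAF")            # either database suffices
})

test_that("region masking hits flanked intervals and indel spans", {
  m0 <- RegionMask("chr1", 99L, 100L, flank_bp = 0L)
  expect_true(applyRegionMask(makeVariants(1, pos = 100L), m0))
  m5 <- RegionMask("chr1", 105L, 120L, flank_bp = 5L)
  expect_true(applyRegionMask(makeVariants(1, pos = 104L), m5))
  expect_false(applyRegionMask(makeVariants(1, pos = 50L), m5))
  # deletion spanning into the mask from the left
  del <- makeVariants(1, pos = 98L, ref = "AAAA", alt = "A")
  expect_true(applyRegionMask(del, m5))       # span 98..101, flank hits 101
})

test_that("confidence thresholds are strict and class-specific", {
  expect_false(applyConfidenceFilters(makeVariants(1, depth = 400L,
                                                   alt_count = 10L)))
  expect_true(applyConfidenceFilters(makeVariants(1, depth = 500L,
                                                  alt_count = 3L)))
  expect_false(applyConfidenceFilters(makeVariants(1, depth = 500L,
                                                   alt_count = 2L)))
  del6 <- makeVariants(1, ref = "AT", alt = "A", depth = 500L,
                       alt_count = 6L)
  del5 <- makeVariants(1, ref = "AT", alt = "A", depth = 500L,
                       alt_count = 5L)
  expect_true(applyConfidenceFilters(del6))
  expect_false(applyConfidenceFilters(del5))
})

test_that("recurrence counts distinct samples against a strict fraction", {
  mk <- function(samples) {
    df <- do.call(rbind, lapply(samples, function(s)
      variants(makeVariants(1, sample_id = s))))
    VariantSet(df)
  }
  expect_true(all(applyRecurrenceFilter(mk(paste0("S", 1:3)), 20)))   # 15%
  expect_false(any(applyRecurrenceFilter(mk(paste0("S", 1:2)), 20)))  # 10%
  expect_false(any(applyRecurrenceFilter(mk("S1"), 20)))
  # repeated calls in one sample do not count twice
  expect_false(any(applyRecurrenceFilter(mk(c("S1", "S1", "S2")), 20)))
})

test_that("nonsynonymous selection keeps both streams", {
  vs <- makeVariants(3, consequence = c("synonymous", "missense",
                                        "nonsense"))
  st <- selectNonsynonymous(vs)
  expect_equal(length(st$nonsynonymous), 2L)
  expect_equal(length(st$synonymous), 1L)
  expect_equal(variants(st$synonymous)$consequence, "synonymous")
  odd <- makeVariants(1, consequence = "weird")
  expect_warning(st2 <- selectNonsynonymous(odd), "unknown")
  expect_equal(length(st2$nonsynonymous), 1L)  # retained, flagged
})

test_that("the pipeline audit reconciles and attributes first failures", {
  vs <- makeVariants(4,
    pos = c(100L, 200L, 300L, 400L),
    popaf_exome = c(0.05, 0, 0, 0),
    f1r2 = c(10L, 20L, 10L, 10L), f2r1 = c(10L, 0L, 10L, 10L),
    depth = c(1000L, 1000L, 300L, 1000L),
    alt_count = c(20L, 20L, 10L, 20L))
  res <- runFilterPipeline(vs, config = chConfig(alpha_orientation = 0.05),
                           n_samples = 20)
  rc <- removedCounts(res$audit)
  expect_equal(unname(rc[c("orientation_bias", "germline",
                           "low_confidence")]), c(1L, 1L, 1L))
  expect_equal(res$audit@nRetained, 1L)
  expect_equal(sum(rc) + res$audit@nRetained, res$audit@nInput)
  # the popAF call is also orientation-testable but popAF comes later:
  # first-failure follows pipeline order
  expect_equal(res$audit@perVariant$first_fail[2], "orientation_bias")
})

test_that("empty input and disabled thresholds behave as identities", {
  empty <- VariantSet()
  res <- runFilterPipeline(empty)
  expect_equal(res$audit@nInput, 0L)
  expect_equal(length(res$retained), 0L)

  vs <- makeVariants(5, popaf_exome = c(0.5, 0, 0, 0, 0),
                     depth = c(100L, 1000L, 1000L, 1000L, 1000L),
                     alt_count = c(1L, 400L, 20L, 20L, 20L))
  res2 <- runFilterPipeline(vs, config = disabledConfig())
  expect_equal(length(res2$retained), 5L)
})

test_that("the retained set matches an order-free predicate oracle", {
  set.seed(11)
  cfg <- chConfig(alpha_orientation = 0.05, alpha_strand = 0.05)
  for (rep in 1:10) {
    n <- 40
    df <- variants(makeVariants(n,
      sample_id = sample(paste0("S", 1:8), n, replace = TRUE),
      pos = sample(50:400, n),
      popaf_exome = sample(c(0, 0, 0, 0.05), n, replace = TRUE),
      depth = sample(c(300L, 1000L, 2000L), n, replace = TRUE),
      alt_count = sample(c(2L, 8L, 30L, 300L), n, replace = TRUE)))
    df$alt_count <- pmin(df$alt_count, df$depth)
    df$vaf <- df$alt_count / df$depth
    df$f1r2 <- rbinom(n, df$alt_count, sample(c(0.5, 0.95), n, TRUE))
    df$f2r1 <- df$alt_count - df$f1r2
    df$alt_fwd <- rbinom(n, df$alt_count, 0.5)
    df$alt_rev <- df$alt_count - df$alt_fwd
    df$ref_fwd <- rbinom(n, df$depth - df$alt_count, 0.5)
    df$ref_rev <- df$depth - df$alt_count - df$ref_fwd
    vs <- VariantSet(df)
    mask <- RegionMask("chr1", c(120L, 300L), c(160L, 320L), flank_bp = 5L)

    res <- runFilterPipeline(vs, mask, cfg, n_samples = 8)

    # oracle: independent predicates evaluated in arbitrary order;
    # recurrence on the post-germline subset
    bias <- assessSequenceBias(vs, 0.05, 0.05)
    germ <- applyGermlineFilters(vs, config = cfg)
    keep <- !bias$orientation_fail & !bias$strand_fail & germ$keep &
      !applyRegionMask(vs, mask) & applyConfidenceFilters(vs, cfg) &
      df$vaf > configValue(cfg, "vaf_floor")
    rec <- logical(n)
    rec[germ$keep] <- applyRecurrenceFilter(vs[germ$keep], 8,
                                            0.10)
    keep <- keep & !rec
    expect_equal(variantKey(res$retained),
                 variantKey(vs[keep]))
    # audit conservation per sample
    pv <- res$audit@perVariant
    perSample <- table(pv$sample_id, is.na(pv$first_fail))
    expect_equal(rowSums(perSample), table(df$sample_id)[rownames(perSample)],
                 ignore_attr = TRUE)
  }
})

test_that("relaxing a threshold never shrinks the retained set", {
  set.seed(12)
  n <- 60
  vs <- makeVariants(n,
    sample_id = sample(paste0("S", 1:6), n, replace = TRUE),
    pos = sample(50:500, n),
    popaf_exome = sample(c(0, 0.005, 0.02), n, replace = TRUE),
    depth = sample(c(350L, 600L, 1500L), n, replace = TRUE),
    alt_count = sample(c(2L, 5L, 40L), n, replace = TRUE))
  strict <- chConfig()
  relaxed <- chConfig(min_depth_exclusive = 300,
                      min_alt_snv_exclusive = 1,
                      popaf_max = 0.05, vaf_floor = 0.001)
  kStrict <- variantKey(runFilterPipeline(vs, config = strict)$retained)
  kRelax <- variantKey(runFilterPipeline(vs, config = relaxed)$retained)
  expect_true(all(kStrict %in% kRelax))
})
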