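test_that("dose groups split at zero and the 7.4 GBq cutoff", {
  expect_equal(as.character(assignDoseGroup(c(0, 3.7, 7.4, 7.39, 30))),
               c("control", "low", "high", "low", "high"))
  expect_error(assignDoseGroup(-0.1), "negative")
})

test_that("per-subject maximum VAF picks the largest clone
          deterministically", {
  vs <- makeVariants(3, sample_id = c("A", "A", "B"),
                     alt_count = c(6L, 21L, 10L), depth = 1000L,
                     pos = c(100L, 200L, 300L))
  s <- maxVafPerIndividual(vs, sample_ids = c("A", "B", "C"))
  expect_equal(s$max_vaf, c(0.021, 0.010, NA))
  expect_equal(s$n_mutations, c(2L, 1L, 0L))
  # tie: witness is the lowest (chrom, pos)
  tie <- makeVariants(2, sample_id = "A", alt_count = 10L,
                      pos = c(500L, 120L))
  st <- maxVafPerIndividual(tie)
  expect_equal(st$witness, "chr1:120:A:G")
  expect_equal(st$max_vaf, 0.01)
})

test_that("CH presence is strict in the cutoff and monotone across
          cutoffs", {
  s <- data.frame(sample_id = c("A", "B", "C"),
                  max_vaf = c(0.020, 0.021, NA))
  expect_equal(chPresence(s, 0.02), c(FALSE, TRUE, FALSE))
  set.seed(14)
  s2 <- data.frame(sample_id = paste0("S", 1:50),
                   max_vaf = ifelse(runif(50) < 0.2, NA,
                                    rlnorm(50, log(0.01), 1)))
  prev <- vapply(c(0.005, 0.01, 0.02, 0.05),
                 function(co) mean(chPresence(s2, co)), numeric(1))
  expect_true(all(diff(prev) <= 0))
})

test_that("log-VAF regression recovers a known dose slope", {
  set.seed(15)
  n <- 2000
  cohort <- data.frame(sample_id = paste0("S", 1:n),
                       age_ch = runif(n, 30, 80),
                       sex = sample(c("female", "male"), n, TRUE),
                       smoking = rbinom(n, 1, 0.2) == 1,
                       dose_gbq = runif(n, 0, 30))
  true_slope <- 0.1   # per 1.11 GBq on log percent VAF
  logv <- -0.2 + true_slope * cohort$dose_gbq / 1.11 + rnorm(n, 0, 1)
  subjects <- data.frame(sample_id = cohort$sample_id,
                         max_vaf = exp(logv) / 100)
  fit <- fitLogVafRegression(cohort, subjects, exposure = "dose")
  row <- fit$table[fit$table$predictor == "dose_u", ]
  expect_lt(abs(row$estimate - true_slope), 3 * row$se)
  # age rescaling changes the coefficient scale, not the t-statistic
  cfg2 <- chConfig(age_unit_years = 1)
  fit2 <- fitLogVafRegression(cohort, subjects, exposure = "dose",
                              config = cfg2)
  t1 <- fit$table$estimate / fit$table$se
  t2 <- fit2$table$estimate / fit2$table$se
  expect_equal(t1[fit$table$predictor == "age10"],
               t2[fit2$table$predictor == "age10"], tolerance = 1e-9)
  # subjects without mutations are excluded and counted
  subjects$max_vaf[1:10] <- NA
  fit3 <- fitLogVafRegression(cohort, subjects, exposure = "dose")
  expect_equal(fit3$n_excluded, 10L)
  expect_equal(fit3$n, n - 10L)
})

test_that("interaction p-values are uniform under the null", {
  set.seed(16)
  n <- 300
  reps <- 200
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    cohort <- data.frame(sample_id = paste0("S", 1:n),
                         age_ch = runif(n, 30, 80),
                         sex = "female", smoking = FALSE,
                         dose_gbq = runif(n, 0, 30))
    subjects <- data.frame(sample_id = cohort$sample_id,
                           max_vaf = rlnorm(n, log(0.01), 0.8))
    fit <- fitLogVafRegression(cohort, subjects, exposure = "dose",
                               interaction = TRUE, covariates = NULL)
    pvals[r] <- fit$table$p[fit$table$predictor == "age10:dose_u"]
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("marginal predictions exponentiate onto the percent scale", {
  set.seed(17)
  cohort <- data.frame(sample_id = paste0("S", 1:200),
                       age_ch = runif(200, 30, 80), sex = "female",
                       smoking = FALSE, dose_gbq = runif(200, 0, 20))
  subjects <- data.frame(sample_id = cohort$sample_id,
                         max_vaf = rlnorm(200, log(0.01), 0.5))
  fit <- fitLogVafRegression(cohort, subjects, exposure = "dose",
                             covariates = NULL)
  grid <- data.frame(age10 = c(4, 6), dose_u = c(0, 10))
  pred <- marginalLogVaf(fit, grid)
  expect_equal(pred$vaf_pct_hat, exp(pred$log_vaf_hat))
})

test_that("the cutoff optimizer finds a strong step and respects
          min_group_n", {
  set.seed(18)
  n <- 400
  dose <- runif(n, 0, 16)
  y <- rbinom(n, 1, plogis(qlogis(0.1) + log(6) * (dose >= 8))) == 1
  res <- optimizeDoseCutoff(dose, y, grid = seq(6, 10, 0.5))
  expect_lte(abs(res$best - 8), 0.5)
  expect_equal(res$criterion, "firth_lrt")
  one <- optimizeDoseCutoff(dose, y, grid = 7.0)
  expect_equal(one$best, 7.0)
  expect_error(optimizeDoseCutoff(dose, y, grid = 100, min_group_n = 5),
               "min_group_n")
  youden <- optimizeDoseCutoff(dose, y, grid = seq(6, 10, 0.5),
                               criterion = "youden")
  expect_lte(abs(youden$best - 8), 1.0)
})

test_that("a flat dose-risk profile shows no cutoff beating its
          permutation null", {
  set.seed(19)
  n <- 300
  dose <- runif(n, 0, 16)
  y <- rbinom(n, 1, 0.12) == 1              # risk unrelated to dose
  grid <- seq(4, 12, 1)
  obs <- max(optimizeDoseCutoff(dose, y, grid)$trace$stat, na.rm = TRUE)
  perm <- vapply(1:100, function(i)
    max(optimizeDoseCutoff(dose, sample(y), grid)$trace$stat,
        na.rm = TRUE), numeric(1))
  expect_lte(obs, quantile(perm, 0.95))
})

test_that("co-occurrence p-values equal the hypergeometric-sum oracle", {
  pres <- matrix(FALSE, 100, 2, dimnames = list(NULL, c("GA", "GB")))
  pres[1:10, "GA"] <- TRUE                  # both = 5, onlyA = 5
  pres[c(1:5, 11:15), "GB"] <- TRUE         # onlyB = 5, neither = 85
  res <- pairwiseCooccurrence(pres)
  # two-sided Fisher p: sum of hypergeometric probabilities no larger
  # than the observed table's
  dens <- dhyper(0:10, 10, 90, 10)
  oracle <- sum(dens[dens <= dhyper(5, 10, 90, 10) * (1 + 1e-7)])
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$q, res$p)
  expect_false(any(res$gene_a == res$gene_b))   # no self-pairs
})

test_that("independent genes rarely co-occur significantly", {
  set.seed(20)
  fracs <- vapply(1:30, function(r) {
    pres <- matrix(rbinom(60 * 6, 1, 0.25) == 1, 60, 6,
                   dimnames = list(NULL, paste0("G", 1:6)))
    mean(pairwiseCooccurrence(pres)$p < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("score tertiles are balanced and slopes recover a planted
          effect", {
  vs <- makeVariants(9, CADD = c(1:9) * 2, pos = 1:9 * 10L,
                     alt_count = c(6L, 9L, 12L, 15L, 20L, 25L, 30L, 40L,
                                   50L))
  res <- pathogenicityVafAssociation(vs)
  expect_equal(res$tertiles$n, c(3L, 3L, 3L))
  expect_error(pathogenicityVafAssociation(
    makeVariants(5, CADD = rep(3, 5))), "no score variation")
  expect_error(pathogenicityVafAssociation(
    makeVariants(2, CADD = c(1, 2))), "fewer than 3|missing")
  set.seed(22)
  hits <- vapply(1:50, function(r) {
    n <- 200
    score <- runif(n, 0, 30)
    vaf <- exp(log(0.8) + 0.03 * score + rnorm(n, 0, 0.6)) / 100
    v <- makeVariants(n, CADD = score, vaf = vaf,
                      pos = seq(10L, by = 7L, length.out = n))
    r <- pathogenicityVafAssociation(v)
    r$slope > 0 && r$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
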