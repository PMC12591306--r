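## Subject-level association statistics: dose groups, per-subject maximum
## VAF and CH presence at configurable cutoffs, log-VAF linear models with
## dose x age interactions, dose-cutoff optimization, gene co-occurrence,
## and pathogenicity-score/VAF association.

#' Assign RAIT dose groups
#'
#' Zero dose is control; doses strictly between 0 and the cutoff are low;
#' doses at or above the cutoff (default 7.4 GBq) are high.
#'
#' @param dose_gbq numeric cumulative doses (GBq).
#' @param cutoff_gbq low/high split (default 7.4).
#' @return factor with levels control, low, high.
#' @export
assignDoseGroup <- function(dose_gbq, cutoff_gbq = 7.4) {
  if (any(dose_gbq < 0, na.rm = TRUE)) stop("negative dose")
  factor(ifelse(dose_gbq == 0, "control",
                ifelse(dose_gbq < cutoff_gbq, "low", "high")),
         levels = c("control", "low", "high"))
}

#' Per-subject maximum VAF summary
#'
#' The maximum VAF is the VAF of the subject's most expanded mutation;
#' subjects with no retained mutations get NA (they are excluded from
#' VAF-level models but remain in presence models). Ties are broken by the
#' lowest (chrom, pos) witness.
#'
#' @param vs filtered [VariantSet-class].
#' @param sample_ids all cohort sample ids (so mutation-free subjects
#'   appear); defaults to the samples present in `vs`.
#' @return data.frame: sample_id, max_vaf, n_mutations, witness key.
#' @export
maxVafPerIndividual <- function(vs, sample_ids = NULL) {
  df <- variants(vs)
  if (is.null(sample_ids)) sample_ids <- sort(unique(df$sample_id))
  out <- data.frame(sample_id = sample_ids, max_vaf = NA_real_,
                    n_mutations = 0L, witness = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[order(df$sample_id, -df$vaf, df$chrom, df$pos), ]
    firstIdx <- !duplicated(df$sample_id)
    top <- df[firstIdx, c("sample_id", "vaf", "chrom", "pos", "ref", "alt")]
    m <- match(top$sample_id, out$sample_id)
    keep <- !is.na(m)
    out$max_vaf[m[keep]] <- top$vaf[keep]
    out$witness[m[keep]] <- variantKey(top[keep, ])
    tab <- table(df$sample_id)
    out$n_mutations <- as.integer(tab[out$sample_id])
    out$n_mutations[is.na(out$n_mutations)] <- 0L
  }
  out
}

#' CH presence at a VAF cutoff
#'
#' TRUE iff the subject's maximum VAF strictly exceeds the cutoff; subjects
#' without mutations are FALSE.
#'
#' @param subjects data.frame from [maxVafPerIndividual()].
#' @param cutoff VAF cutoff (fraction, e.g. 0.02).
#' @return logical vector aligned with `subjects`.
#' @export
chPresence <- function(subjects, cutoff) {
  !is.na(subjects$max_vaf) & subjects$max_vaf > cutoff
}

#' Gene-by-sample presence matrix at a VAF cutoff
#' @param vs filtered [VariantSet-class].
#' @param sample_ids cohort sample ids.
#' @param cutoff VAF cutoff (strict).
#' @return logical matrix samples x genes.
#' @export
genePresenceMatrix <- function(vs, sample_ids, cutoff) {
  df <- variants(vs)
  df <- df[df$vaf > cutoff, , drop = FALSE]
  genes <- sort(unique(df$gene))
  m <- matrix(FALSE, length(sample_ids), length(genes),
              dimnames = list(sample_ids, genes))
  if (nrow(df)) {
    idx <- cbind(match(df$sample_id, sample_ids), match(df$gene, genes))
    idx <- idx[stats::complete.cases(idx), , drop = FALSE]
    m[idx] <- TRUE
  }
  m
}

#' Linear model of log maximum VAF
#'
#' OLS on the natural log of the maximum VAF expressed in percent (no
#' pseudocount is needed: detected VAFs are at least 0.5%). Age enters per
#' 10 years and continuous dose per 1.11 GBq; the RAIT exposure can instead
#' be the categorical dose group. Subjects with no mutations are excluded
#' and counted.
#'
#' @param cohort cohort data.frame ([readCohort()] / [simulateCohort()]).
#' @param subjects data.frame from [maxVafPerIndividual()].
#' @param exposure "dose" (continuous) or "group" (factor control/low/high).
#' @param interaction include an age x exposure interaction term.
#' @param covariates extra cohort columns added as adjustments.
#' @param config a [PipelineConfig-class] (scaling units, dose cutoff).
#' @return list: `fit` (lm), `table` (coefficient summary), `n`,
#'   `n_excluded`.
#' @export
fitLogVafRegression <- function(cohort, subjects,
                                exposure = c("dose", "group"),
                                interaction = FALSE,
                                covariates = c("sex", "smoking"),
                                config = chConfig()) {
  exposure <- match.arg(exposure)
  d <- merge(cohort, subjects, by = "sample_id")
  n_excluded <- sum(is.na(d$max_vaf))
  d <- d[!is.na(d$max_vaf), , drop = FALSE]
  d$log_vaf <- log(100 * d$max_vaf)
  d$age10 <- d$age_ch / configValue(config, "age_unit_years")
  d$dose_u <- d$dose_gbq / configValue(config, "dose_unit_gbq")
  d$group <- assignDoseGroup(d$dose_gbq,
                             configValue(config, "dose_cutoff_gbq"))
  expo <- if (exposure == "dose") "dose_u" else "group"
  rhs <- c("age10", expo, covariates)
  if (interaction) rhs <- c(rhs, paste0("age10:", expo))
  form <- stats::as.formula(paste("log_vaf ~", paste(rhs, collapse = " + ")))
  if (nrow(d) <= length(rhs) + 1)
    stop("fewer subjects than model parameters")
  fit <- stats::lm(form, data = d)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  tab <- data.frame(predictor = rownames(sm), estimate = sm[, 1],
                    se = sm[, 2], ci_low = ci[, 1], ci_high = ci[, 2],
                    p = sm[, 4], row.names = NULL)
  list(fit = fit, table = tab, n = nrow(d), n_excluded = n_excluded)
}

#' Marginal predictions from a log-VAF model
#' @param model result of [fitLogVafRegression()].
#' @param grid data.frame of covariate values on the model's scale.
#' @return `grid` with predicted log VAF and percent-scale VAF columns.
#' @export
marginalLogVaf <- function(model, grid) {
  grid$log_vaf_hat <- stats::predict(model$fit, newdata = grid)
  grid$vaf_pct_hat <- exp(grid$log_vaf_hat)
  grid
}

#' Optimize the dose cutoff for predicting CH
#'
#' For each candidate cutoff the dose is dichotomized and the chosen
#' criterion computed: the penalized likelihood-ratio statistic of the
#' dichotomized dose in a Firth logistic model (default), or Youden's J
#' from the 2x2 table. Candidates leaving either side below `min_group_n`
#' are skipped. Which statistic produced the selection is recorded, as the
#' choice of optimization criterion is this package's interpretation.
#'
#' @param dose_gbq numeric dose vector.
#' @param outcome logical CH-presence vector.
#' @param grid candidate cutoffs (GBq).
#' @param min_group_n minimum subjects on each side (default 5).
#' @param criterion "firth_lrt" or "youden".
#' @param covariates optional numeric matrix of adjustment columns.
#' @return list: `best` cutoff, `trace` data.frame, `criterion`.
#' @export
optimizeDoseCutoff <- function(dose_gbq, outcome, grid, min_group_n = 5,
                               criterion = c("firth_lrt", "youden"),
                               covariates = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(min_group_n >= 1)
  y <- as.numeric(outcome)
  trace <- data.frame(cutoff = grid, stat = NA_real_, n_below = NA_integer_,
                      n_above = NA_integer_)
  for (i in seq_along(grid)) {
    x <- as.numeric(dose_gbq >= grid[i])
    trace$n_below[i] <- sum(x == 0)
    trace$n_above[i] <- sum(x == 1)
    if (min(trace$n_below[i], trace$n_above[i]) < min_group_n) next
    if (criterion == "firth_lrt") {
      X <- cbind(`(Intercept)` = 1, high = x)
      if (!is.null(covariates)) X <- cbind(X, covariates)
      fit <- fitFirthLogistic(X, y, ci = "wald")
      trace$stat[i] <- firthLrtStat(fit, "high")
    } else {
      sens <- sum(y == 1 & x == 1) / sum(y == 1)
      spec <- sum(y == 0 & x == 0) / sum(y == 0)
      trace$stat[i] <- sens + spec - 1
    }
  }
  if (all(is.na(trace$stat)))
    stop("all candidate cutoffs violate min_group_n")
  best <- trace$cutoff[which.max(trace$stat)]
  list(best = best, trace = trace, criterion = criterion)
}

#' Pairwise gene co-occurrence tests
#'
#' Two-sided Fisher exact test on the 2x2 subject table of each unordered
#' gene pair, with BH adjustment across pairs.
#'
#' @param presence logical samples x genes matrix
#'   (from [genePresenceMatrix()]).
#' @return data.frame: gene_a, gene_b, counts, odds ratio (conditional MLE),
#'   p and q.
#' @export
pairwiseCooccurrence <- function(presence) {
  genes <- colnames(presence)
  if (length(genes) < 2) stop("need at least two genes")
  pairs <- utils::combn(genes, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- presence[, pr[1]]; b <- presence[, pr[2]]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2)
    ft <- stats::fisher.test(tab)
    c(both = tab[1, 1], only_a = tab[2, 1], only_b = tab[1, 2],
      neither = tab[2, 2], or = unname(ft$estimate), p = ft$p.value)
  })
  out <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                    t(res), stringsAsFactors = FALSE)
  out$q <- adjustFdr(out$p)
  out
}

#' Pathogenicity-score vs clone-size association
#'
#' Splits scored mutations into empirical tertiles and regresses log VAF
#' (percent scale) on the score.
#'
#' @param vs filtered [VariantSet-class].
#' @param score column name of the score (default "CADD").
#' @return list: `tertiles` summary data.frame, `slope`, `p`, `fit`.
#' @export
pathogenicityVafAssociation <- function(vs, score = "CADD") {
  df <- variants(vs)
  if (is.null(df[[score]])) stop("all scores missing: no column ", score)
  d <- df[!is.na(df[[score]]) & !is.na(df$vaf), , drop = FALSE]
  if (nrow(d) < 3) stop("all scores missing or fewer than 3 scored mutations")
  s <- d[[score]]
  if (max(s) == min(s)) stop("no score variation")
  ter <- ceiling(3 * rank(s, ties.method = "first") / length(s))
  tert <- data.frame(
    tertile = 1:3,
    n = as.integer(table(factor(ter, levels = 1:3))),
    score_median = tapply(s, factor(ter, levels = 1:3), stats::median),
    vaf_median = tapply(d$vaf, factor(ter, levels = 1:3), stats::median),
    vaf_mean = tapply(d$vaf, factor(ter, levels = 1:3), mean))
  fit <- stats::lm(log(100 * d$vaf) ~ s)
  sm <- summary(fit)$coefficients
  list(tertiles = tert, slope = sm[2, 1], p = sm[2, 4], fit = fit)
}
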