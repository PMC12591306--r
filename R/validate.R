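## Self-contained validation experiments: each runs one of the package's
## methods under known (simulated) truth and measures how well it is
## recovered. They back the test suite and the reproduction script, and are
## exported so users can rerun them at other settings.

#' Filter-pipeline truth recovery experiment
#'
#' Simulates a cohort with planted true CH clones and all six artifact
#' classes, runs the full filter pipeline, and measures (a) the fraction of
#' emitted true calls retained, (b) whether every artifact was removed with
#' its intended first-failure reason, and (c) audit reconciliation.
#'
#' @param n_control,n_low,n_high simulated group sizes (default 31/32/37,
#'   a 100-sample cohort).
#' @param seed master seed.
#' @return list with retention, artifact accounting and the audit.
#' @export
truthRecoveryExperiment <- function(n_control = 31L, n_low = 32L,
                                    n_high = 37L, seed = 1L) {
  cohort <- simulateCohort(cohortSimParams(n_control, n_low, n_high), seed)
  panel <- simulateCdsPanel(seed = seed)
  eff <- effectConfig()
  mask <- RegionMask(chrom = c("chr_DNMT3A", "chr_TET2"),
                     start0 = c(1200L, 1400L), end0 = c(1230L, 1430L),
                     flank_bp = 5L)
  truth <- simulateTruthMutations(cohort, eff, panel, seed = seed,
                                  mask = mask)
  raw <- renderRawCalls(truth, eff, cohort, panel, mask, seed = seed)
  res <- runFilterPipeline(raw$variants, mask, chConfig(),
                           n_samples = nrow(cohort))
  pv <- res$audit@perVariant
  lbl <- raw$truth$label
  expected <- c(germline_leak = "germline", strand_bias = "strand_bias",
                orientation_bias = "orientation_bias",
                masked_region = "region_mask", low_depth = "low_confidence",
                recurrent = "recurrent")
  isTrue <- lbl == "true_CH"
  retained <- is.na(pv$first_fail)
  artifactIntended <- pv$first_fail[!isTrue] == expected[lbl[!isTrue]]
  list(n_calls = nrow(pv),
       n_true = sum(isTrue),
       retention = sum(retained & isTrue) / sum(isTrue),
       n_artifacts = sum(!isTrue),
       artifacts_removed_as_intended = sum(artifactIntended,
                                           na.rm = TRUE),
       all_artifacts_intended = all(!is.na(artifactIntended)) &&
         all(artifactIntended),
       audit_reconciles = sum(res$audit@removedCounts) +
         res$audit@nRetained == res$audit@nInput,
       audit = res$audit)
}

#' Sparse 2x2 Firth worked example
#'
#' Two groups of 10 subjects with 2 and 0 events. In this saturated 2x2
#' setting the Firth (Jeffreys-penalized) estimate equals the classical
#' add-one-half correction, giving a closed-form group log-odds-ratio
#' log\[(2.5 x 10.5) / (8.5 x 0.5)\] = 1.8207.
#'
#' @param level CI level.
#' @return list with the fit, the group coefficient, its profile CI and the
#'   closed-form value.
#' @export
firthToyExample <- function(level = 0.95) {
  y <- c(rep(1, 2), rep(0, 8), rep(0, 10))
  g <- c(rep(1, 10), rep(0, 10))
  X <- cbind("(Intercept)" = 1, group = g)
  fit <- fitFirthLogistic(X, y, level = level)
  list(fit = fit, coef = unname(coef(fit)["group"]),
       ci = unname(fit@ci["group", ]),
       closed_form = log((2.5 * 10.5) / (8.5 * 0.5)))
}

#' Profile-CI coverage experiment
#'
#' Simulates cohorts with a known high-dose odds ratio on CH presence and
#' measures how often the Firth profile-penalized-likelihood CI covers the
#' true log odds ratio.
#'
#' @param n_reps replicate cohorts (default 500).
#' @param n subjects per cohort (default 360).
#' @param true_or true odds ratio (default 2.5).
#' @param p0 baseline CH prevalence (default 0.08, the >2% VAF scale).
#' @param exposed_fraction fraction in the high-dose group (default 0.37).
#' @param level CI level.
#' @param seed master seed.
#' @return list with `coverage` and the replicate records.
#' @export
ciCoverageExperiment <- function(n_reps = 500L, n = 360L, true_or = 2.5,
                                 p0 = 0.08, exposed_fraction = 0.37,
                                 level = 0.95, seed = 1L) {
  set.seed(.subSeed(seed, "coverage"))
  beta <- log(true_or)
  covered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    x <- stats::rbinom(n, 1, exposed_fraction)
    y <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(p0) + beta * x))
    X <- cbind("(Intercept)" = 1, high = x)
    fit <- fitFirthLogistic(X, y, ci = "wald", level = level)
    ci <- profilePenalizedCI(fit, "high", level = level)
    covered[r] <- ci[1] <= beta && beta <= ci[2]
  }
  list(coverage = mean(covered), n_reps = n_reps, n = n,
       true_or = true_or)
}

.dndsSimPanel <- function(seed, n_genes = 12L, length_codons = 250L) {
  panel <- simulateCdsPanel(n_genes, length_codons, seed = seed)
  opp <- lapply(panel, enumerateSiteOpportunities)
  names(opp) <- vapply(panel, function(g) g@gene, character(1))
  opp
}

.dndsSimOnce <- function(opp, rates, omega_tru = NULL) {
  genes <- names(opp)
  synClass <- stats::setNames(numeric(length(substitutionClasses())),
                              substitutionClasses())
  counts <- data.frame(gene = genes, n_syn = 0, n_mis = 0, n_tru = 0,
                       stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    cm <- opp[[i]]@counts
    lam <- cm * rates[rownames(cm)]
    wt <- if (!is.null(omega_tru) && !is.null(omega_tru[[genes[i]]]))
      omega_tru[[genes[i]]] else 1
    draw_syn <- stats::rpois(nrow(cm), lam[, "synonymous"])
    synClass <- synClass + stats::setNames(draw_syn, rownames(cm))
    counts$n_syn[i] <- sum(draw_syn)
    counts$n_mis[i] <- stats::rpois(1, sum(lam[, "missense"]))
    counts$n_tru[i] <- stats::rpois(1, wt * sum(lam[, "truncating"]))
  }
  list(counts = counts, syn_class = synClass)
}

#' dN/dS neutral-calibration experiment
#'
#' Draws mutations from a known per-class neutral rate spectrum, refits the
#' neutral model and returns the global dN/dS, which should be close to 1.
#'
#' @param seed master seed.
#' @param target_mutations approximate total mutation count (default 6000).
#' @return list with the global omega vector and the mutation total.
#' @export
dndsCalibrationExperiment <- function(seed = 1L, target_mutations = 6000) {
  opp <- .dndsSimPanel(seed)
  totalOpp <- sum(vapply(opp, function(o) sum(o@counts), numeric(1)))
  set.seed(.subSeed(seed, "dnds-neutral"))
  base <- target_mutations / totalOpp
  rates <- stats::setNames(
    base * exp(stats::rnorm(96, 0, 0.4) - 0.08), substitutionClasses())
  sim <- .dndsSimOnce(opp, rates)
  fitted <- fitNeutralContextModel(sim$syn_class, opp)
  list(global = globalDnds(sim$counts, opp, fitted),
       n_mutations = sum(sim$counts[, c("n_syn", "n_mis", "n_tru")]))
}

#' dN/dS selection power and false-positive experiment
#'
#' Replicated simulations in which two genes carry truncating-class positive
#' selection (omega = 5) and the rest are neutral. Measures how often the
#' selected genes reach q < 0.10 in the truncating class only, and the
#' fraction of null genes crossing q < 0.10.
#'
#' @param n_reps replicates (default 200).
#' @param omega_tru simulated truncating omega (default 5).
#' @param q_threshold significance level on BH q (default 0.10).
#' @param seed master seed.
#' @return list with `power`, `null_fpr`, and per-gene expected counts.
#' @export
dndsPowerExperiment <- function(n_reps = 200L, omega_tru = 5,
                                q_threshold = 0.10, seed = 1L) {
  opp <- .dndsSimPanel(seed)
  genes <- names(opp)
  sel <- genes[1:2]
  set.seed(.subSeed(seed, "dnds-power"))
  ## per-gene synonymous expectation ~30: rate chosen per gene size
  oppSyn <- sum(vapply(opp, function(o) sum(o@counts[, "synonymous"]),
                       numeric(1)))
  base <- 30 * length(genes) / oppSyn
  rates <- stats::setNames(
    base * exp(stats::rnorm(96, 0, 0.3) - 0.045), substitutionClasses())
  hits <- logical(n_reps)
  fprs <- numeric(n_reps)
  omegaSel <- numeric(0)
  for (r in seq_len(n_reps)) {
    sim <- .dndsSimOnce(opp, rates,
                        omega_tru = stats::setNames(
                          rep(list(omega_tru), 2), sel))
    fitted <- fitNeutralContextModel(sim$syn_class, opp)
    est <- estimateDnds(sim$counts, opp, fitted)
    selRows <- est[est$gene %in% sel, ]
    nullRows <- est[!est$gene %in% sel, ]
    hits[r] <- all(selRows$q_tru < q_threshold, na.rm = FALSE) &&
      !any(selRows$q_mis < q_threshold, na.rm = TRUE)
    fprs[r] <- mean(nullRows$q_tru < q_threshold, na.rm = TRUE)
    omegaSel <- c(omegaSel, selRows$omega_tru)
  }
  list(power = mean(hits), null_fpr = mean(fprs),
       median_omega_selected = stats::median(omegaSel), n_reps = n_reps)
}

#' Dose-cutoff recovery experiment
#'
#' Simulates cohorts whose CH risk steps up at a known dose (8.0 GBq,
#' odds ratio 4, baseline prevalence 10%, doses uniform on 0-16 GBq so
#' every candidate has subject mass) and measures how often the optimizer
#' selects a cutoff within one 0.5-GBq grid step of the truth.
#'
#' @param n_reps replicates (default 200).
#' @param n subjects per cohort (default 360).
#' @param true_cutoff simulated step location (default 8.0).
#' @param true_or step odds ratio (default 4).
#' @param grid candidate cutoffs.
#' @param seed master seed.
#' @return list with `recovery` (fraction within one grid step) and the
#'   selected cutoffs.
#' @export
doseCutoffExperiment <- function(n_reps = 200L, n = 360L, true_cutoff = 8.0,
                                 true_or = 4, grid = seq(6, 10, by = 0.5),
                                 seed = 1L) {
  set.seed(.subSeed(seed, "cutoff"))
  step <- min(diff(sort(grid)))
  best <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    dose <- stats::runif(n, 0, 16)
    y <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.10) +
                                             log(true_or) *
                                             (dose >= true_cutoff)))
    best[r] <- optimizeDoseCutoff(dose, y == 1, grid)$best
  }
  list(recovery = mean(abs(best - true_cutoff) <= step + 1e-9),
       selected = best, n_reps = n_reps)
}

#' Longitudinal dynamics experiment
#'
#' Runs the pairing/classification/summary chain on the default simulated
#' paired cohort (24 patients, each with pre- and post-therapy samples)
#' and returns the per-patient mean counts of vanished/decreased and
#' emerged/increased mutations.
#'
#' @param n_pairs patients with both samples (default 24).
#' @param seed master seed.
#' @return list with the cohort means and per-patient table.
#' @export
longitudinalExperiment <- function(n_pairs = 24L, seed = 1L) {
  sim <- simulatePairedCohort(n_pairs = n_pairs, seed = seed)
  res <- runLongitudinal(sim$variants, sim$cohort)
  list(means = res$summary$means, per_patient = res$summary$per_patient,
       n_pairs = n_pairs)
}
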