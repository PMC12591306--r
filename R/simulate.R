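## Synthetic-data module: cohorts, CDS panels, truth mutation sets,
## artifact-laden raw calls, and paired pre/post samples. Generator defaults
## are the study conditions (group sizes and covariate moments of the
## 358-subject cohort); effect sizes with no published value are one-time
## realistic choices documented in the methods vignette.

## Per-operation substreams derived from the master seed, so each stage is
## reproducible on its own.
.subSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Cohort simulation parameters
#'
#' Defaults reproduce the study cohort's structure: 110 controls (no RAIT),
#' 115 low-dose (< 7.4 GBq) and 133 high-dose (>= 7.4 GBq) subjects, with
#' the published per-group age means/SDs, female fractions, smoking
#' fractions, dose distributions (low uniform on 1.11-7.4 GBq; high
#' shifted-exponential with mean 23.9 GBq) and elapsed-time moments.
#'
#' @param n_control,n_low,n_high group sizes.
#' @param age_mean,age_sd per-group age at CH test (years).
#' @param female_fraction,smoking_fraction per-group fractions.
#' @param dose_low_range low-group uniform dose support (GBq).
#' @param dose_high_min,dose_high_mean high-group shifted-exponential
#'   minimum and mean (GBq).
#' @param elapsed_mean,elapsed_sd per-treated-group months since first RAIT
#'   (low, high).
#' @return named list of parameters for [simulateCohort()].
#' @export
cohortSimParams <- function(n_control = 110L, n_low = 115L, n_high = 133L,
                            age_mean = c(60.0, 52.4, 56.4),
                            age_sd = c(14.5, 14.0, 13.9),
                            female_fraction = c(0.855, 0.861, 0.692),
                            smoking_fraction = c(0.973, 0.948, 0.925),
                            dose_low_range = c(1.11, 7.4),
                            dose_high_min = 7.4, dose_high_mean = 23.9,
                            elapsed_mean = c(75.9, 116.4),
                            elapsed_sd = c(74.8, 76.3)) {
  stopifnot(n_control >= 0, n_low >= 0, n_high >= 0,
            dose_low_range[1] > 0, dose_low_range[2] <= dose_high_min,
            dose_high_mean > dose_high_min)
  list(n = c(control = as.integer(n_control), low = as.integer(n_low),
             high = as.integer(n_high)),
       age_mean = age_mean, age_sd = age_sd,
       female_fraction = female_fraction,
       smoking_fraction = smoking_fraction,
       dose_low_range = dose_low_range, dose_high_min = dose_high_min,
       dose_high_mean = dose_high_mean,
       elapsed_mean = elapsed_mean, elapsed_sd = elapsed_sd)
}

.rgammaMoments <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Simulate a cohort covariate table
#'
#' Deterministic for a fixed seed; group sizes are exact. Ages are normal,
#' truncated at 20 years; treated subjects get elapsed months from a
#' gamma distribution matching the published moments, truncated at 12
#' months (the inclusion criterion), and an age at first RAIT consistent
#' with age and elapsed time (at least 19 years).
#'
#' @param params list from [cohortSimParams()].
#' @param seed master seed.
#' @return data.frame of cohort rows with a `group` column.
#' @export
simulateCohort <- function(params = cohortSimParams(), seed = 1L) {
  set.seed(.subSeed(seed, "cohort"))
  groups <- c("control", "low", "high")
  rows <- lapply(seq_along(groups), function(gi) {
    n <- params$n[[groups[gi]]]
    if (n == 0) return(NULL)
    age <- stats::rnorm(n, params$age_mean[gi], params$age_sd[gi])
    while (any(age < 20)) age[age < 20] <-
      stats::rnorm(sum(age < 20), params$age_mean[gi], params$age_sd[gi])
    dose <- switch(groups[gi],
      control = rep(0, n),
      low = stats::runif(n, params$dose_low_range[1],
                         params$dose_low_range[2]),
      high = params$dose_high_min +
        stats::rexp(n, rate = 1 / (params$dose_high_mean -
                                     params$dose_high_min)))
    if (groups[gi] == "control") {
      elapsed <- rep(NA_real_, n); age_rait <- rep(NA_real_, n)
    } else {
      ei <- gi - 1
      elapsed <- .rgammaMoments(n, params$elapsed_mean[ei],
                                params$elapsed_sd[ei])
      elapsed <- pmax(elapsed, 12)
      elapsed <- pmin(elapsed, (age - 19) * 12)
      age_rait <- age - elapsed / 12
    }
    data.frame(
      group = groups[gi], age_ch = age, age_rait = age_rait,
      sex = ifelse(stats::rbinom(n, 1, params$female_fraction[gi]) == 1,
                   "female", "male"),
      smoking = stats::rbinom(n, 1, params$smoking_fraction[gi]) == 1,
      dose_gbq = dose, elapsed_months = elapsed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sample_id <- sprintf("S%03d", seq_len(nrow(out)))
  out$paired_pre_sample <- NA_character_
  out[, c("sample_id", "group", "age_ch", "age_rait", "sex", "smoking",
          "dose_gbq", "elapsed_months", "paired_pre_sample")]
}

#' Mutation and artifact effect configuration
#'
#' Per-gene-and-class background mutation rates, multiplicative age hazards
#' per decade (above/below age 50), multiplicative dose hazards per
#' 1.11 GBq applied to a consequence class, the clone-size (VAF)
#' distribution (log-normal on the percent scale with a 0.5% detection
#' floor, matching the right-skewed spectrum of detected clones), sequencing
#' depth, and per-sample artifact rates. Age hazards default above one for
#' the age-associated genes (DNMT3A, TET2, PPM1D); dose hazards default
#' above one only for truncating PPM1D and missense TP53, the DNA-damage-
#' response signature of radioiodine exposure.
#'
#' @param base_rates named per-class expected mutations per gene per
#'   subject.
#' @param age_effect named per-gene multiplicative hazard per decade
#'   (genes not listed use `age_default`).
#' @param age_default default per-decade hazard.
#' @param dose_effect named list `gene -> c(class_group = hazard)` per
#'   1.11 GBq, where class_group is "truncating" or "missense".
#' @param vaf_meanlog,vaf_sdlog log-normal parameters of VAF in percent.
#' @param vaf_floor detection floor (fraction).
#' @param depth_mean,depth_sd,depth_min consensus depth distribution.
#' @param artifact_rates named per-sample Poisson means for the injected
#'   artifact classes.
#' @param recurrent_keys,recurrent_fraction number of recurrent technical
#'   keys and the fraction of samples each is injected into.
#' @return named list for the simulators.
#' @export
effectConfig <- function(base_rates = c(synonymous = 0.08, missense = 0.21,
                                        nonsense = 0.012, frameshift = 0.012,
                                        splice_site = 0.006,
                                        inframe_indel = 0.006),
                         age_effect = c(DNMT3A = 1.3, TET2 = 1.3,
                                        PPM1D = 1.2),
                         age_default = 1.05,
                         dose_effect = list(
                           PPM1D = c(truncating = 1.06),
                           TP53 = c(missense = 1.05)),
                         vaf_meanlog = log(0.45), vaf_sdlog = 0.62,
                         vaf_floor = 0.005,
                         depth_mean = 1926, depth_sd = 350, depth_min = 600,
                         artifact_rates = c(germline_leak = 4,
                                            strand_bias = 2.5,
                                            orientation_bias = 2.5,
                                            masked_region = 2,
                                            low_depth = 2),
                         recurrent_keys = 2L, recurrent_fraction = 0.15) {
  stopifnot(all(base_rates >= 0), all(artifact_rates >= 0),
            vaf_floor >= 0, vaf_floor <= 1)
  list(base_rates = base_rates, age_effect = age_effect,
       age_default = age_default, dose_effect = dose_effect,
       vaf_meanlog = vaf_meanlog, vaf_sdlog = vaf_sdlog,
       vaf_floor = vaf_floor, depth_mean = depth_mean, depth_sd = depth_sd,
       depth_min = depth_min, artifact_rates = artifact_rates,
       recurrent_keys = recurrent_keys,
       recurrent_fraction = recurrent_fraction)
}

.defaultPanelGenes <- c("DNMT3A", "TET2", "PPM1D", "TP53", "ASXL1", "RUNX1",
                        "SH2B3", "JAK2", "CALR", "CBL")

#' Simulate a CDS panel
#'
#' Each gene gets a random CDS of `length_codons` codons (ATG start, no
#' internal stop) plus a terminal stop codon, placed contiguously on its
#' own contig (`chr_<gene>`) on the + strand starting at position 1001.
#'
#' @param n_genes number of genes.
#' @param length_codons codons per gene before the stop (>= 2).
#' @param seed master seed.
#' @param gene_names symbols to use (defaults to ten CH-panel genes,
#'   seven of them from the loss-of-function driver list).
#' @return list of [GeneModel-class].
#' @export
simulateCdsPanel <- function(n_genes = 10L, length_codons = 300L, seed = 1L,
                             gene_names = NULL) {
  stopifnot(length_codons >= 2)
  if (is.null(gene_names))
    gene_names <- if (n_genes <= length(.defaultPanelGenes))
      .defaultPanelGenes[seq_len(n_genes)]
    else c(.defaultPanelGenes,
           sprintf("GENE%02d", seq_len(n_genes - length(.defaultPanelGenes))))
  stopifnot(length(gene_names) == n_genes)
  set.seed(.subSeed(seed, "panel"))
  allCodons <- names(GENETIC_CODE)
  nonStop <- allCodons[GENETIC_CODE != "*"]
  stops <- allCodons[GENETIC_CODE == "*"]
  lapply(gene_names, function(g) {
    body <- sample(nonStop, length_codons - 1, replace = TRUE)
    cds <- paste(c("ATG", body, sample(stops, 1)), collapse = "")
    GeneModel(gene = g, cds = cds, chrom = paste0("chr_", g),
              cds_start = 1001L, strand = "+",
              flank5 = sample(.dnaBases, 1), flank3 = sample(.dnaBases, 1))
  })
}

.truncVaf <- function(n, effects) {
  out <- numeric(0)
  floor_pct <- 100 * effects$vaf_floor
  while (length(out) < n) {
    x <- stats::rlnorm(n, effects$vaf_meanlog, effects$vaf_sdlog)
    out <- c(out, x[x > floor_pct])
  }
  out[seq_len(n)] / 100
}

.doseHazard <- function(effects, gene, cls) {
  grp <- if (cls %in% c("nonsense", "frameshift", "splice_site"))
    "truncating" else if (cls == "missense") "missense" else NA_character_
  de <- effects$dose_effect[[gene]]
  if (is.na(grp) || is.null(de) || is.na(de[grp])) 1 else unname(de[grp])
}

.siteLists <- function(panel, mask = NULL) {
  lapply(panel, function(g) {
    opp <- enumerateSiteOpportunities(g)
    sites <- opp@sites
    sites$pos <- g@cdsStart + sites$cds_pos - 1L
    if (!is.null(mask)) {
      gr <- GRanges(g@chrom, IRanges(sites$pos, sites$pos))
      hit <- unique(queryHits(suppressWarnings(
        findOverlaps(gr, maskRanges(mask)))))
      if (length(hit)) sites <- sites[-hit, , drop = FALSE]
    }
    sites
  })
}

.aaAt <- function(gene, cds_pos) {
  cod <- (cds_pos - 1L) %/% 3L + 1L
  codon <- substr(gene@cds, 3 * cod - 2, 3 * cod)
  list(idx = cod, codon = codon, aa = GENETIC_CODE[[codon]])
}

#' Simulate the true CH mutation set of a cohort
#'
#' Per subject, gene and consequence class, the mutation count is Poisson
#' with rate `base * age_hazard^((age - 50)/10) * dose_hazard^(dose/1.11)`.
#' SNV classes draw real sites from the gene's substitution opportunities
#' (so ref/alt/protein change are consistent with the CDS); indel classes
#' construct alleles at random CDS positions. Sites overlapping `mask` are
#' never chosen. Clone sizes are truncated log-normal above the detection
#' floor.
#'
#' @param cohort data.frame from [simulateCohort()].
#' @param effects list from [effectConfig()].
#' @param panel list of [GeneModel-class].
#' @param seed master seed.
#' @param mask optional [RegionMask-class] excluded from site choice.
#' @return data.frame of truth mutations (one row per planted clone) with
#'   `label = "true_CH"`.
#' @export
simulateTruthMutations <- function(cohort, effects, panel, seed = 1L,
                                   mask = NULL) {
  stopifnot(length(panel) >= 1)
  set.seed(.subSeed(seed, "truth"))
  geneNames <- vapply(panel, function(g) g@gene, character(1))
  names(panel) <- geneNames
  sites <- .siteLists(panel, mask)
  names(sites) <- geneNames
  classes <- names(effects$base_rates)
  rows <- list()
  for (si in seq_len(nrow(cohort))) {
    age <- cohort$age_ch[si]; dose <- cohort$dose_gbq[si]
    for (g in geneNames) {
      ageHz <- if (g %in% names(effects$age_effect))
        effects$age_effect[[g]] else effects$age_default
      ageMult <- ageHz^((age - 50) / 10)
      for (cls in classes) {
        rate <- effects$base_rates[[cls]] * ageMult *
          .doseHazard(effects, g, cls)^(dose / 1.11)
        nmut <- stats::rpois(1, rate)
        if (nmut == 0) next
        for (k in seq_len(nmut)) {
          row <- .drawMutation(panel[[g]], sites[[g]], cls)
          if (is.null(row)) next
          row$sample_id <- cohort$sample_id[si]
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), consequence = character(),
                      protein_change = character(), true_vaf = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$true_vaf <- .truncVaf(nrow(out), effects)
  out$label <- "true_CH"
  out <- out[!duplicated(paste(out$sample_id, out$chrom, out$pos, out$ref,
                               out$alt)), ]
  rownames(out) <- NULL
  out[, c("sample_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
          "protein_change", "true_vaf", "label")]
}

.drawMutation <- function(gene, sites, cls) {
  pickSite <- function(impacts) {
    cand <- which(sites$impact %in% impacts)
    if (!length(cand)) return(NULL)
    sites[cand[sample.int(length(cand), 1)], , drop = FALSE]
  }
  base <- data.frame(sample_id = NA_character_, chrom = gene@chrom,
                     pos = NA_integer_, ref = NA_character_,
                     alt = NA_character_, gene = gene@gene,
                     consequence = cls, protein_change = NA_character_,
                     stringsAsFactors = FALSE)
  L <- nchar(gene@cds)
  if (cls %in% c("synonymous", "missense", "nonsense", "splice_site")) {
    impacts <- switch(cls, synonymous = "synonymous",
                      missense = "missense", nonsense = "truncating",
                      splice_site = "missense")
    st <- pickSite(impacts)
    if (is.null(st)) return(NULL)
    base$pos <- st$pos
    base$ref <- st$ref
    base$alt <- st$alt
    aa <- .aaAt(gene, st$cds_pos)
    mutCodon <- aa$codon
    substr(mutCodon, (st$cds_pos - 1) %% 3 + 1,
           (st$cds_pos - 1) %% 3 + 1) <- st$alt
    altAa <- GENETIC_CODE[[mutCodon]]
    if (cls == "nonsense" && aa$aa == "*") base$consequence <- "stop_loss"
    base$protein_change <- sprintf("p.%s%d%s", aa$aa, aa$idx,
                                   if (altAa == "*") "*" else altAa)
  } else {
    cdsPos <- sample.int(L - 6L, 1) + 3L
    refBase <- substr(gene@cds, cdsPos, cdsPos)
    if (cls == "frameshift") {
      ins <- sample.int(2, 1) == 1
      if (ins) {
        base$ref <- refBase
        base$alt <- paste0(refBase, sample(.dnaBases, 1))
      } else {
        base$ref <- substr(gene@cds, cdsPos, cdsPos + 1L)
        base$alt <- refBase
      }
    } else {  # inframe_indel: 3-bp insertion
      base$ref <- refBase
      base$alt <- paste0(refBase,
                         paste(sample(.dnaBases, 3, replace = TRUE),
                               collapse = ""))
    }
    base$pos <- gene@cdsStart + cdsPos - 1L
    aa <- .aaAt(gene, cdsPos)
    base$protein_change <- sprintf("p.%s%dfs", aa$aa, aa$idx)
    if (cls == "inframe_indel")
      base$protein_change <- sprintf("p.%s%ddup", aa$aa, aa$idx)
  }
  base
}

.exactHalves <- function(x) {
  a <- x %/% 2L
  cbind(a, x - a)
}

.drawDepth <- function(n, effects) {
  pmax(effects$depth_min,
       as.integer(round(stats::rnorm(n, effects$depth_mean,
                                     effects$depth_sd))))
}

#' Render raw variant calls from a truth set, with injected artifacts
#'
#' True clones get consensus depth from the configured distribution,
#' binomial alt counts at the true VAF, and unbiased (binomial 0.5)
#' strand/orientation splits; draws whose observed VAF does not exceed the
#' detection floor are not emitted (a caller with a 0.5% cutoff never
#' reports them) and leave the truth set. Injected artifacts violate
#' exactly one filtering rule each — germline-leak (population frequency
#' > 1%, VAF near 50%), strand bias (all alt reads on one strand),
#' orientation bias (all alt reads F1R2), error-prone-region calls (inside
#' the mask), low-depth calls (depth <= 400) and recurrent technical calls
#' (same key in more than 10% of samples) — and carry exactly balanced
#' counts on the dimensions they do not violate.
#'
#' @param truth data.frame from [simulateTruthMutations()].
#' @param effects list from [effectConfig()].
#' @param cohort cohort data.frame (defines the sample set).
#' @param panel list of [GeneModel-class] (artifact site choice).
#' @param mask optional [RegionMask-class]; needed for masked-region
#'   artifacts.
#' @param seed master seed.
#' @return list: `variants` ([VariantSet-class] of raw calls, with a
#'   `truth_label` column) and `truth` (sidecar table of emitted calls:
#'   sample_id, chrom, pos, ref, alt, label).
#' @export
renderRawCalls <- function(truth, effects, cohort, panel, mask = NULL,
                           seed = 1L) {
  set.seed(.subSeed(seed, "render"))
  geneNames <- vapply(panel, function(g) g@gene, character(1))
  names(panel) <- geneNames
  rows <- list()
  addRow <- function(df) rows[[length(rows) + 1]] <<- df

  ## --- true clones ---
  if (nrow(truth)) {
    depth <- .drawDepth(nrow(truth), effects)
    alt <- stats::rbinom(nrow(truth), depth, truth$true_vaf)
    obsVaf <- alt / depth
    emit <- obsVaf > effects$vaf_floor
    t2 <- truth[emit, , drop = FALSE]
    depth <- depth[emit]; alt <- alt[emit]
    n <- nrow(t2)
    if (n) {
      af <- stats::rbinom(n, alt, 0.5)
      rf <- stats::rbinom(n, depth - alt, 0.5)
      f1 <- stats::rbinom(n, alt, 0.5)
      addRow(data.frame(
        sample_id = t2$sample_id, chrom = t2$chrom, pos = t2$pos,
        ref = t2$ref, alt = t2$alt, depth = depth, alt_count = alt,
        vaf = alt / depth, ref_fwd = rf, ref_rev = depth - alt - rf,
        alt_fwd = af, alt_rev = alt - af, f1r2 = f1, f2r1 = alt - f1,
        gene = t2$gene, consequence = t2$consequence,
        protein_change = t2$protein_change,
        popaf_exome = 0, popaf_genome = 0, cosmic_count = 0L,
        dbsnp_member = FALSE,
        CADD = pmin(45, pmax(0, stats::rnorm(n, 15, 8))),
        truth_label = "true_CH", stringsAsFactors = FALSE))
    }
  }

  ## --- artifact machinery ---
  sites <- .siteLists(panel, mask)   # outside-mask SNV sites
  names(sites) <- geneNames
  randSnv <- function() {
    g <- geneNames[sample.int(length(geneNames), 1)]
    st <- sites[[g]]
    st <- st[st$impact == "missense", , drop = FALSE]
    st <- st[sample.int(nrow(st), 1), , drop = FALSE]
    list(gene = g, chrom = panel[[g]]@chrom, pos = st$pos, ref = st$ref,
         alt = st$alt)
  }
  artifactRow <- function(sample_id, loc, depth, alt, vaf, label,
                          popaf = 0, strand_biased = FALSE,
                          orient_biased = FALSE) {
    sh <- .exactHalves(alt)
    rh <- .exactHalves(depth - alt)
    oh <- .exactHalves(alt)
    data.frame(
      sample_id = sample_id, chrom = loc$chrom, pos = loc$pos,
      ref = loc$ref, alt = loc$alt, depth = depth, alt_count = alt,
      vaf = vaf,
      ref_fwd = rh[, 1], ref_rev = rh[, 2],
      alt_fwd = if (strand_biased) alt else sh[, 1],
      alt_rev = if (strand_biased) 0L else sh[, 2],
      f1r2 = if (orient_biased) alt else oh[, 1],
      f2r1 = if (orient_biased) 0L else oh[, 2],
      gene = loc$gene, consequence = "missense",
      protein_change = NA_character_,
      popaf_exome = popaf, popaf_genome = 0, cosmic_count = 0L,
      dbsnp_member = popaf > 0,
      CADD = pmin(45, pmax(0, stats::rnorm(1, 12, 8))),
      truth_label = label, stringsAsFactors = FALSE)
  }
  ar <- effects$artifact_rates
  maskedLoc <- NULL
  if (!is.null(mask) && length(maskRanges(mask))) {
    mr <- maskRanges(mask)
    mr <- mr[as.character(seqnames(mr)) %in%
               vapply(panel, function(g) g@chrom, character(1))]
    if (length(mr)) maskedLoc <- function() {
      i <- sample.int(length(mr), 1)
      chromName <- as.character(seqnames(mr))[i]
      g <- panel[[which(vapply(panel, function(p) p@chrom == chromName,
                               logical(1)))[1]]]
      p <- sample(seq(start(mr)[i], end(mr)[i]), 1)
      cdsPos <- min(max(p - g@cdsStart + 1L, 1L), nchar(g@cds))
      p <- g@cdsStart + cdsPos - 1L
      refBase <- substr(g@cds, cdsPos, cdsPos)
      list(gene = g@gene, chrom = g@chrom, pos = p, ref = refBase,
           alt = sample(setdiff(.dnaBases, refBase), 1))
    }
  }
  for (si in seq_len(nrow(cohort))) {
    sid <- cohort$sample_id[si]
    for (lbl in names(ar)) {
      k <- stats::rpois(1, ar[[lbl]])
      if (lbl == "masked_region" && is.null(maskedLoc)) k <- 0
      for (j in seq_len(k)) {
        depth <- .drawDepth(1, effects)
        switch(lbl,
          germline_leak = {
            vaf <- stats::runif(1, 0.45, 0.55)
            addRow(artifactRow(sid, randSnv(), depth,
                               as.integer(round(vaf * depth)), vaf,
                               "germline_leak",
                               popaf = stats::runif(1, 0.02, 0.3)))
          },
          strand_bias = {
            alt <- max(15L, stats::rbinom(1, depth, 0.02))
            addRow(artifactRow(sid, randSnv(), depth, alt, alt / depth,
                               "strand_bias", strand_biased = TRUE))
          },
          orientation_bias = {
            alt <- max(12L, stats::rbinom(1, depth, 0.02))
            addRow(artifactRow(sid, randSnv(), depth, alt, alt / depth,
                               "orientation_bias", orient_biased = TRUE))
          },
          masked_region = {
            alt <- max(8L, stats::rbinom(1, depth, 0.02))
            addRow(artifactRow(sid, maskedLoc(), depth, alt, alt / depth,
                               "masked_region"))
          },
          low_depth = {
            depth <- sample(100:400, 1)
            alt <- max(4L, stats::rbinom(1, depth, 0.04))
            addRow(artifactRow(sid, randSnv(), depth, alt, alt / depth,
                               "low_depth"))
          })
      }
    }
  }
  ## recurrent technical keys, cohort-level
  nRec <- effects$recurrent_keys
  if (nRec > 0 && nrow(cohort)) {
    nInject <- max(floor(effects$recurrent_fraction * nrow(cohort)),
                   floor(0.10 * nrow(cohort)) + 1L)
    nInject <- min(nInject, nrow(cohort))
    for (r in seq_len(nRec)) {
      loc <- randSnv()
      who <- sample(cohort$sample_id, nInject)
      for (sid in who) {
        depth <- .drawDepth(1, effects)
        alt <- max(10L, stats::rbinom(1, depth, 0.015))
        addRow(artifactRow(sid, loc, depth, alt, alt / depth, "recurrent"))
      }
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- emptyVariantFrame()
  vs <- VariantSet(df)
  truthOut <- variants(vs)[, c("sample_id", "chrom", "pos", "ref", "alt",
                               "truth_label")]
  names(truthOut)[6] <- "label"
  list(variants = vs, truth = truthOut)
}

#' Simulate a paired pre/post-therapy cohort
#'
#' Each patient contributes a pre-RAIT and a post-RAIT sample linked by
#' `paired_pre_sample`. Post-therapy clone sizes are the pre-therapy VAFs
#' under multiplicative log-normal drift; clones drop out at `drop_rate`
#' (or by drifting below the detection floor) and new clones appear with
#' Poisson mean `add_mean`. Defaults emulate the scale of the study's
#' 24-pair longitudinal set (about 15 tracked mutations per patient, all
#' low-dose recipients).
#'
#' @param n_pairs number of patients with both samples (default 24).
#' @param clones_mean expected pre-therapy clones per patient.
#' @param drift_sd SD of log VAF drift between venipunctures.
#' @param drop_rate probability a pre-therapy clone disappears.
#' @param add_mean expected newly detected clones per patient.
#' @param panel list of [GeneModel-class] used for gene labels/positions.
#' @param effects list from [effectConfig()] (VAF distribution, floor).
#' @param seed master seed.
#' @return list: `cohort` (2 rows per patient) and `variants`
#'   ([VariantSet-class] of both timepoints).
#' @export
simulatePairedCohort <- function(n_pairs = 24L, clones_mean = 14,
                                 drift_sd = 0.3, drop_rate = 0.10,
                                 add_mean = 1.5, panel = NULL,
                                 effects = effectConfig(), seed = 1L) {
  stopifnot(n_pairs >= 1)
  set.seed(.subSeed(seed, "paired"))
  if (is.null(panel)) panel <- simulateCdsPanel(seed = seed)
  geneNames <- vapply(panel, function(g) g@gene, character(1))
  names(panel) <- geneNames
  sites <- .siteLists(panel)
  names(sites) <- geneNames
  newClone <- function() {
    g <- geneNames[sample.int(length(geneNames), 1)]
    st <- sites[[g]]
    st <- st[st$impact != "synonymous", , drop = FALSE]
    st <- st[sample.int(nrow(st), 1), , drop = FALSE]
    data.frame(chrom = panel[[g]]@chrom, pos = st$pos, ref = st$ref,
               alt = st$alt, gene = g, stringsAsFactors = FALSE)
  }
  floorFrac <- effects$vaf_floor
  cohortRows <- list(); varRows <- list()
  mkVar <- function(sid, clone, vaf) {
    depth <- 2000L
    data.frame(sample_id = sid, chrom = clone$chrom, pos = clone$pos,
               ref = clone$ref, alt = clone$alt, depth = depth,
               alt_count = as.integer(round(vaf * depth)), vaf = vaf,
               gene = clone$gene, consequence = "missense",
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_pairs)) {
    preId <- sprintf("P%02d_pre", i); postId <- sprintf("P%02d_post", i)
    age <- stats::rnorm(1, 52.4, 14.0)
    age <- max(age, 25)
    elapsed <- stats::runif(1, 12, 120)
    dose <- stats::runif(1, 1.11, 7.4)
    cohortRows[[length(cohortRows) + 1]] <- data.frame(
      sample_id = c(preId, postId), group = c("control", "low"),
      age_ch = c(age - elapsed / 12, age),
      age_rait = c(NA, age - elapsed / 12),
      sex = "female", smoking = FALSE, dose_gbq = c(0, dose),
      elapsed_months = c(NA, elapsed),
      paired_pre_sample = c(NA_character_, preId),
      stringsAsFactors = FALSE)
    nPre <- stats::rpois(1, clones_mean)
    clones <- if (nPre) do.call(rbind, replicate(nPre, newClone(),
                                                 simplify = FALSE)) else NULL
    if (!is.null(clones)) {
      clones <- clones[!duplicated(paste(clones$chrom, clones$pos,
                                         clones$alt)), , drop = FALSE]
      vafPre <- .truncVaf(nrow(clones), effects)
      for (k in seq_len(nrow(clones)))
        varRows[[length(varRows) + 1]] <- mkVar(preId, clones[k, ],
                                                vafPre[k])
      keep <- stats::runif(nrow(clones)) >= drop_rate
      vafPost <- vafPre * exp(stats::rnorm(nrow(clones), 0, drift_sd))
      for (k in which(keep & vafPost > floorFrac))
        varRows[[length(varRows) + 1]] <- mkVar(postId, clones[k, ],
                                                vafPost[k])
    }
    nNew <- stats::rpois(1, add_mean)
    if (nNew) for (k in seq_len(nNew)) {
      cl <- newClone()
      varRows[[length(varRows) + 1]] <- mkVar(postId, cl,
                                              .truncVaf(1, effects))
    }
  }
  cohort <- do.call(rbind, cohortRows)
  vdf <- if (length(varRows)) do.call(rbind, varRows) else
    emptyVariantFrame()
  list(cohort = cohort, variants = VariantSet(vdf))
}
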