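## Maximum-likelihood dN/dS with a strand-collapsed 96-class trinucleotide
## neutral substitution model. Reduced relative to full covariate-based
## implementations: SNVs only (frameshift indels stay in the association
## analyses but not here), no gene covariates. Truncating class = nonsense +
## stop-loss (+ splice-site when annotated); stop-retaining changes in the
## stop codon count as synonymous.

.dnaBases <- c("A", "C", "G", "T")

#' The 96 strand-collapsed trinucleotide substitution classes
#'
#' Classes are labelled `L[R>A]R2` style as `"LRA>R2"`... concretely
#' `paste0(left, ref, right, ">", alt)` after collapsing purine-reference
#' substitutions onto their reverse complement, so every class has a
#' pyrimidine (C/T) reference base.
#'
#' @return character vector of the 96 class labels.
#' @export
substitutionClasses <- function() {
  out <- character(0)
  for (ref in c("C", "T")) for (alt in setdiff(.dnaBases, ref))
    for (l in .dnaBases) for (r in .dnaBases)
      out <- c(out, paste0(l, ref, r, ">", alt))
  sort(out)
}

.rcBase <- c(A = "T", C = "G", G = "C", T = "A")

#' Collapse a trinucleotide substitution onto its pyrimidine-reference class
#' @param left,ref,right,alt single bases (vectors).
#' @return class labels as in [substitutionClasses()].
#' @export
collapseContext <- function(left, ref, right, alt) {
  flip <- ref %in% c("A", "G")
  l <- ifelse(flip, .rcBase[right], left)
  m <- ifelse(flip, .rcBase[ref], ref)
  r <- ifelse(flip, .rcBase[left], right)
  a <- ifelse(flip, .rcBase[alt], alt)
  paste0(l, m, r, ">", a)
}

.impactLevels <- c("synonymous", "missense", "truncating")

#' Enumerate all single-base substitution opportunities of a gene
#'
#' Walks every CDS position and its three possible base changes, translating
#' the affected codon to classify the impact: synonymous (amino acid
#' unchanged, including stop-retaining changes in the stop codon), missense,
#' or truncating (gain of stop, or loss of the terminal stop). Context for
#' the first and last base comes from the gene model's flanking bases.
#'
#' @param gene a [GeneModel-class].
#' @return A [SiteOpportunities-class]; its `counts` matrix is 96 x 3 and
#'   sums to 3 x CDS length.
#' @export
enumerateSiteOpportunities <- function(gene) {
  cds <- gene@cds
  L <- nchar(cds)
  ncod <- L %/% 3
  bases <- strsplit(cds, "")[[1]]
  codons <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  aa <- GENETIC_CODE[codons]
  if (any(aa[-ncod] == "*")) stop("CDS contains an internal stop codon")
  pos <- rep(seq_len(L), each = 3)
  refb <- bases[pos]
  altb <- unlist(lapply(bases, function(b) setdiff(.dnaBases, b)),
                 use.names = FALSE)
  leftb <- c(gene@flank5, bases[-L])[pos]
  rightb <- c(bases[-1], gene@flank3)[pos]
  codIdx <- (pos - 1L) %/% 3L + 1L
  offset <- (pos - 1L) %% 3L + 1L
  mutCodon <- codons[codIdx]
  substr(mutCodon, offset, offset) <- altb
  mutAa <- GENETIC_CODE[mutCodon]
  refAa <- aa[codIdx]
  impact <- ifelse(mutAa == refAa, "synonymous",
                   ifelse(mutAa == "*" | refAa == "*", "truncating",
                          "missense"))
  cls <- collapseContext(leftb, refb, rightb, altb)
  counts <- table(factor(cls, levels = substitutionClasses()),
                  factor(impact, levels = .impactLevels))
  new("SiteOpportunities", gene = gene@gene,
      counts = unclass(as.matrix(counts)),
      sites = data.frame(cds_pos = pos, ref = refb, alt = altb,
                         impact = impact, class = cls,
                         stringsAsFactors = FALSE))
}

#' Fit the neutral context model from pooled synonymous counts
#'
#' The Poisson maximum-likelihood rate of each substitution class is the
#' pooled observed synonymous count divided by the pooled synonymous
#' opportunities; classes with no synonymous opportunity fall back to the
#' global mean rate.
#'
#' @param syn_counts named numeric vector of observed synonymous mutations
#'   per class (names = class labels; absent classes count 0), pooled across
#'   genes.
#' @param opportunities list of [SiteOpportunities-class], one per gene.
#' @return named numeric vector of per-class rates (mutations per site).
#' @export
fitNeutralContextModel <- function(syn_counts, opportunities) {
  cls <- substitutionClasses()
  opp <- Reduce(`+`, lapply(opportunities, function(o) o@counts))
  obs <- stats::setNames(numeric(length(cls)), cls)
  obs[names(syn_counts)] <- syn_counts
  total <- sum(obs)
  if (total == 0)
    stop("no synonymous observations: the neutral model needs a larger ",
         "input set")
  oppSyn <- opp[cls, "synonymous"]
  global <- total / sum(oppSyn)
  rate <- ifelse(oppSyn > 0, obs / oppSyn, global)
  stats::setNames(rate, cls)
}

#' Neutral expected mutation counts per impact class for one gene
#' @param opp a [SiteOpportunities-class].
#' @param rates per-class rates from [fitNeutralContextModel()].
#' @return named numeric vector (synonymous, missense, truncating).
#' @export
expectedCounts <- function(opp, rates) {
  cls <- substitutionClasses()
  colSums(opp@counts[cls, ] * rates[cls])
}

#' Per-gene maximum-likelihood dN/dS estimates
#'
#' For each gene and impact class c in (missense, truncating), omega_c is
#' estimated under a Poisson model with a per-gene rate factor theta
#' calibrated on the gene's synonymous counts (`calibration = "gene"`,
#' default): `omega_c = (n_c / E_c) / (n_syn / E_syn)`. The likelihood-ratio
#' test of omega_c = 1 profiles theta under both hypotheses (1 df). With
#' `calibration = "global"` theta is fixed at 1 and omega_c = n_c / E_c.
#' Genes with observed impact mutations but a zero-calibrated expectation
#' get omega flagged infinite and are excluded from FDR adjustment.
#'
#' @param counts data.frame with columns `gene`, `n_syn`, `n_mis`, `n_tru`.
#' @param opportunities named list of [SiteOpportunities-class] per gene.
#' @param rates neutral model from [fitNeutralContextModel()].
#' @param calibration "gene" or "global".
#' @return data.frame with omega, p and BH q per impact class and gene.
#' @export
estimateDnds <- function(counts, opportunities, rates,
                         calibration = c("gene", "global")) {
  calibration <- match.arg(calibration)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    g <- counts$gene[i]
    E <- expectedCounts(opportunities[[g]], rates)
    one <- function(n_c, E_c, n_syn, E_syn) {
      if (calibration == "global") {
        omega <- n_c / E_c
        lrt <- 2 * ((if (n_c > 0) n_c * log(n_c / E_c) else 0) - (n_c - E_c))
      } else {
        if (E_syn <= 0 || (n_syn == 0 && n_c > 0))
          return(c(omega = Inf, p = NA_real_))
        theta1 <- n_syn / E_syn
        omega <- if (n_c == 0) 0 else (n_c / E_c) / theta1
        ll <- function(mu_s, mu_c)
          (if (n_syn > 0) n_syn * log(mu_s) else 0) - mu_s +
          (if (n_c > 0) n_c * log(mu_c) else 0) - mu_c
        theta0 <- (n_syn + n_c) / (E_syn + E_c)
        ## under the alternative the impact class is saturated (mu_c = n_c)
        llAlt <- (if (n_syn > 0) n_syn * log(theta1 * E_syn) else 0) -
          theta1 * E_syn +
          (if (n_c > 0) n_c * log(n_c) else 0) - n_c
        llNull <- ll(theta0 * E_syn, theta0 * E_c)
        lrt <- 2 * (llAlt - llNull)
      }
      p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
      c(omega = omega, p = p)
    }
    mis <- one(counts$n_mis[i], E[["missense"]],
               counts$n_syn[i], E[["synonymous"]])
    tru <- one(counts$n_tru[i], E[["truncating"]],
               counts$n_syn[i], E[["synonymous"]])
    data.frame(gene = g, omega_mis = mis[["omega"]], p_mis = mis[["p"]],
               omega_tru = tru[["omega"]], p_tru = tru[["p"]],
               exp_syn = E[["synonymous"]], exp_mis = E[["missense"]],
               exp_tru = E[["truncating"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  finiteM <- is.finite(out$omega_mis) & !is.na(out$p_mis)
  finiteT <- is.finite(out$omega_tru) & !is.na(out$p_tru)
  out$q_mis <- NA_real_
  out$q_tru <- NA_real_
  out$q_mis[finiteM] <- adjustFdr(out$p_mis[finiteM])
  out$q_tru[finiteT] <- adjustFdr(out$p_tru[finiteT])
  out
}

#' Global (group-level) dN/dS
#'
#' Ratio of pooled observed nonsynonymous mutations to their pooled neutral
#' expectation, with the synonymous-calibrated plug-in rates.
#'
#' @inheritParams estimateDnds
#' @return named vector: global omega for missense, truncating, and both
#'   combined.
#' @export
globalDnds <- function(counts, opportunities, rates) {
  E <- sapply(counts$gene, function(g)
    expectedCounts(opportunities[[g]], rates))
  obs_mis <- sum(counts$n_mis); obs_tru <- sum(counts$n_tru)
  exp_mis <- sum(E["missense", ]); exp_tru <- sum(E["truncating", ])
  c(missense = obs_mis / exp_mis,
    truncating = obs_tru / exp_tru,
    all = (obs_mis + obs_tru) / (exp_mis + exp_tru))
}

#' Benjamini-Hochberg adjusted q-values
#' @param pvalues numeric vector in \[0, 1\].
#' @return BH step-up adjusted q-values.
#' @export
adjustFdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Tally observed mutations per gene and impact class for dN/dS
#'
#' Counts SNV calls by gene: synonymous, missense, and truncating (nonsense,
#' stop-loss and splice-site). Frameshift and in-frame indels are excluded
#' (the neutral model is substitution-only).
#'
#' @param vs a filtered [VariantSet-class] including the synonymous stream.
#' @param genes gene symbols to tally (default: all in `vs`).
#' @return data.frame with `gene`, `n_syn`, `n_mis`, `n_tru`.
#' @export
countDndsInput <- function(vs, genes = NULL) {
  df <- variants(vs)
  df <- df[df$variant_class %in% "SNV", , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(df$gene))
  tally <- function(g, cons) sum(df$gene == g & df$consequence %in% cons)
  data.frame(
    gene = genes,
    n_syn = vapply(genes, tally, numeric(1), "synonymous"),
    n_mis = vapply(genes, tally, numeric(1), "missense"),
    n_tru = vapply(genes, tally, numeric(1),
                   c("nonsense", "stop_loss", "splice_site")),
    stringsAsFactors = FALSE)
}

#' Map SNV calls onto substitution classes using the panel
#'
#' Needed to feed observed synonymous counts per context class into
#' [fitNeutralContextModel()]. Positions outside any panel CDS are dropped.
#'
#' @param vs a [VariantSet-class] (SNVs are used).
#' @param panel list of [GeneModel-class].
#' @return data.frame with gene, cds_pos, class and impact per mapped SNV.
#' @export
classifySnvContext <- function(vs, panel) {
  df <- variants(vs)
  df <- df[df$variant_class %in% "SNV", , drop = FALSE]
  byGene <- stats::setNames(panel, vapply(panel, function(g) g@gene,
                                          character(1)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    g <- byGene[[df$gene[i]]]
    if (is.null(g)) return(NULL)
    cdsPos <- df$pos[i] - g@cdsStart + 1L
    if (cdsPos < 1 || cdsPos > nchar(g@cds)) return(NULL)
    bases <- strsplit(g@cds, "")[[1]]
    left <- if (cdsPos == 1) g@flank5 else bases[cdsPos - 1]
    right <- if (cdsPos == nchar(g@cds)) g@flank3 else bases[cdsPos + 1]
    data.frame(gene = df$gene[i], cds_pos = cdsPos,
               class = collapseContext(left, bases[cdsPos], right,
                                       df$alt[i]),
               impact = df$consequence[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the dN/dS analysis on a filtered variant set
#'
#' Convenience wrapper: maps SNVs to context classes, fits the neutral model
#' on pooled synonymous calls, and returns per-gene and global estimates.
#'
#' @param vs filtered [VariantSet-class] (synonymous stream included).
#' @param panel list of [GeneModel-class].
#' @param calibration passed to [estimateDnds()].
#' @return list with `per_gene`, `global` and the fitted `rates`.
#' @export
runDnds <- function(vs, panel, calibration = "gene") {
  opp <- lapply(panel, enumerateSiteOpportunities)
  names(opp) <- vapply(panel, function(g) g@gene, character(1))
  ctx <- classifySnvContext(vs, panel)
  if (is.null(ctx) || !nrow(ctx)) stop("no panel SNVs to analyse")
  synTab <- table(ctx$class[ctx$impact == "synonymous"])
  rates <- fitNeutralContextModel(
    stats::setNames(as.numeric(synTab), names(synTab)), opp)
  counts <- countDndsInput(vs, genes = names(opp))
  list(per_gene = estimateDnds(counts, opp, rates, calibration),
       global = globalDnds(counts, opp, rates),
       rates = rates)
}
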