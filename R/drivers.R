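## ARCH-PD putative-driver rule engine: deterministic classification of
## annotated nonsynonymous variants against an ordered criteria list.
## Criterion 7 of the published list (clustering near validated loci) is
## excluded for lack of objective evidence, mirroring the source ruleset.

#' Genes in which truncating mutations drive myeloid disease by
#' loss of function
#'
#' The 17-gene list used by ARCH-PD criterion 1.
#' @export
archLofGenes <- c("NF1", "DNMT3A", "TET2", "IKZF1", "RAD21", "WT1", "KMT2D",
                  "SH2B3", "TP53", "CEBPA", "ASXL1", "RUNX1", "BCOR",
                  "KDM6A", "STAG2", "PHF6", "KMT2C")

#' Resources consumed by the ARCH-PD rule engine
#'
#' The hotspot residue table ships seeded with three well-known myeloid
#' hotspots (DNMT3A R882, FLT3 D835, CBL Y371) and is explicitly incomplete:
#' faithful reproduction of published classifications requires the user to
#' supply the full residue list and exact CALR exon-9 coordinates from the
#' primary resources. `calr_exon9` defaults to the GRCh37 interval of CALR
#' exon 9 (approximate; override for other builds or panels).
#'
#' @param lof_genes character vector for criterion 1 (default
#'   [archLofGenes]).
#' @param hotspot_residues data.frame(gene, residue) for criterion 5.
#' @param calr_exon9 GRanges of the CALR exon-9 interval for criterion 2.
#' @param cosmic_min_c6,cosmic_min_c8 COSMIC occurrence thresholds
#'   (criterion 6: at least 10; criterion 8: more than 100).
#' @param vaf_max VAF bound for criterion 6 (0.42).
#' @param popaf_max population-frequency bound for criteria 6/8 (0.003).
#' @return list of resources for [classifyArchPD()].
#' @export
driverResources <- function(lof_genes = archLofGenes,
                            hotspot_residues = data.frame(
                              gene = c("DNMT3A", "FLT3", "CBL"),
                              residue = c(882L, 835L, 371L)),
                            calr_exon9 = GRanges("chr19",
                                                 IRanges(13054528, 13055304)),
                            cosmic_min_c6 = 10L, cosmic_min_c8 = 100L,
                            vaf_max = 0.42, popaf_max = 0.003) {
  if (!length(lof_genes)) stop("lof_genes must be non-empty")
  list(lof_genes = lof_genes, hotspot_residues = hotspot_residues,
       calr_exon9 = calr_exon9, cosmic_min_c6 = cosmic_min_c6,
       cosmic_min_c8 = cosmic_min_c8, vaf_max = vaf_max,
       popaf_max = popaf_max)
}

#' Is a consequence class truncating?
#'
#' Truncating = nonsense, frameshift or splice-site (the convention adopted
#' throughout; in-frame indels and stop-loss are not truncating here).
#'
#' @param consequence character vector of consequence classes.
#' @return logical vector.
#' @export
isTruncating <- function(consequence) {
  unknown <- !consequence %in% .consequenceLevels
  if (any(unknown))
    stop("unknown consequence class: ",
         paste(unique(consequence[unknown]), collapse = ", "))
  consequence %in% c("nonsense", "frameshift", "splice_site")
}

#' Residue number parsed from an HGVS-p string
#' @param protein_change e.g. "p.R882H"; NA or unparseable gives NA.
#' @return integer vector of residue positions.
#' @export
hgvspResidue <- function(protein_change) {
  pc <- ifelse(is.na(protein_change), "", protein_change)
  vapply(regmatches(pc, gregexpr("[0-9]+", pc)),
         function(x) if (length(x)) as.integer(x[1]) else NA_integer_,
         integer(1))
}

#' FLT3 internal-tandem-duplication annotation flag
#'
#' Consumed as an annotation-level rule (read-level ITD detection is
#' upstream): an in-frame insertion of at least 3 bp in FLT3.
#'
#' @param df variant data.frame.
#' @return logical vector.
#' @export
flt3ItdFlag <- function(df) {
  inslen <- nchar(df$alt) - nchar(df$ref)
  df$gene %in% "FLT3" & df$variant_class %in% "insertion" &
    inslen >= 3 & inslen %% 3 == 0
}

#' Classify variants against the ARCH-PD putative-driver criteria
#'
#' Criteria are evaluated in order and the first match is reported:
#' \describe{
#'   \item{C1}{truncating mutation in a loss-of-function myeloid gene}
#'   \item{C2}{truncating mutation in CALR exon 9}
#'   \item{C3}{JAK2 V617F}
#'   \item{C4}{FLT3 internal tandem duplication}
#'   \item{C5}{nonsynonymous change at a known hotspot residue}
#'   \item{C6}{nonsynonymous, COSMIC count >= 10, VAF < 42%,
#'     max population frequency < 0.003}
#'   \item{C8}{nonsynonymous, COSMIC count > 100, max population frequency
#'     < 0.003, any VAF}
#' }
#' Missing COSMIC counts are treated as 0 and missing population
#' frequencies as 0 (the maximum of the exome and genome values is used).
#' Synonymous variants are never drivers.
#'
#' @param vs a [VariantSet-class].
#' @param resources list from [driverResources()].
#' @return data.frame with `is_driver`, `criterion` ("C1".."C8" or "none")
#'   and a human-readable `rationale`.
#' @export
classifyArchPD <- function(vs, resources = driverResources()) {
  df <- variants(vs)
  n <- nrow(df)
  nonsyn <- !df$consequence %in% "synonymous"
  trunc <- df$consequence %in% c("nonsense", "frameshift", "splice_site")
  cosmic <- ifelse(is.na(df$cosmic_count), 0L, df$cosmic_count)
  popmax <- pmax(ifelse(is.na(df$popaf_exome), 0, df$popaf_exome),
                 ifelse(is.na(df$popaf_genome), 0, df$popaf_genome))
  residue <- hgvspResidue(df$protein_change)

  c1 <- trunc & df$gene %in% resources$lof_genes
  c2 <- rep(FALSE, n)
  if (length(resources$calr_exon9)) {
    inCalr <- rep(FALSE, n)
    calr <- which(df$gene %in% "CALR")
    if (length(calr)) {
      spans <- GRanges(df$chrom[calr],
                       IRanges(df$pos[calr],
                               df$pos[calr] + nchar(df$ref[calr]) - 1L))
      hit <- unique(queryHits(suppressWarnings(
        findOverlaps(spans, resources$calr_exon9))))
      inCalr[calr[hit]] <- TRUE
    }
    c2 <- trunc & inCalr
  }
  c3 <- df$gene %in% "JAK2" & grepl("V617F", df$protein_change)
  c4 <- flt3ItdFlag(df)
  c5 <- rep(FALSE, n)
  hs <- resources$hotspot_residues
  if (!is.null(hs) && nrow(hs)) {
    hkey <- paste(hs$gene, hs$residue)
    c5 <- nonsyn & paste(df$gene, residue) %in% hkey
  }
  c6 <- nonsyn & cosmic >= resources$cosmic_min_c6 &
    df$vaf < resources$vaf_max & popmax < resources$popaf_max
  c8 <- nonsyn & cosmic > resources$cosmic_min_c8 &
    popmax < resources$popaf_max

  crit <- rep("none", n)
  rationale <- rep("no criterion matched", n)
  rules <- list(
    C8 = list(c8, "COSMIC >100 occurrences, rare in population, any VAF"),
    C6 = list(c6, "COSMIC >=10 occurrences, VAF <42%, rare in population"),
    C5 = list(c5, "nonsynonymous change at a known hotspot residue"),
    C4 = list(c4, "FLT3 internal tandem duplication"),
    C3 = list(c3, "JAK2 V617F"),
    C2 = list(c2, "truncating variant in CALR exon 9"),
    C1 = list(c1, "truncating variant in a loss-of-function myeloid gene"))
  for (nm in names(rules)) {   # reverse order so low-numbered criteria win
    hitv <- rules[[nm]][[1]]
    crit[hitv] <- nm
    rationale[hitv] <- rules[[nm]][[2]]
  }
  data.frame(is_driver = crit != "none", criterion = crit,
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Append driver calls to a variant table
#' @param vs a [VariantSet-class].
#' @inheritParams classifyArchPD
#' @return VariantSet with `is_driver` and `criterion` columns added.
#' @export
annotateDrivers <- function(vs, resources = driverResources()) {
  calls <- classifyArchPD(vs, resources)
  df <- variants(vs)
  df$is_driver <- calls$is_driver
  df$criterion <- calls$criterion
  VariantSet(df)
}
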