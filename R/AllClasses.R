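## Central S4 containers.

#' Column set every VariantSet carries
#'
#' Required identification/count columns are validated; annotation columns are
#' created as NA when absent. Extra columns (e.g. further pathogenicity
#' scores, truth labels from the simulator) are preserved untouched.
#'
#' @format Character vector of canonical column names.
#' @export
variantColumns <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "variant_class",
  "depth", "alt_count", "vaf",
  "ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "f1r2", "f2r1",
  "gene", "consequence", "protein_change",
  "popaf_exome", "popaf_genome", "cosmic_count", "dbsnp_member",
  "CADD", "filter_status"
)

.consequenceLevels <- c("synonymous", "missense", "nonsense", "frameshift",
                        "inframe_indel", "splice_site", "stop_loss", "other")
.variantClasses <- c("SNV", "insertion", "deletion", "MNV")

#' Per-sample variant calls with counts and annotations
#'
#' One row per called alternate allele in one sample. Positions are 1-based
#' (VCF convention); `vaf` is a fraction in \[0, 1\]; `filter_status` holds a
#' `;`-separated list of failed-filter labels (empty string = pass).
#'
#' @slot variants data.frame with at least [variantColumns].
#' @export
setClass("VariantSet", representation(variants = "data.frame"))

setValidity("VariantSet", function(object) {
  df <- object@variants
  msg <- character()
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
            "depth", "alt_count", "vaf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("missing required columns:", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$pos < 1, na.rm = TRUE)) msg <- c(msg, "pos must be >= 1")
    if (any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE))
      msg <- c(msg, "vaf must lie in [0, 1]")
    if (any(df$alt_count > df$depth, na.rm = TRUE))
      msg <- c(msg, "alt_count must not exceed depth")
    if (!all(df$variant_class %in% .variantClasses, na.rm = TRUE))
      msg <- c(msg, "unknown variant_class")
    sc <- df$alt_fwd + df$alt_rev + df$ref_fwd + df$ref_rev
    if (any(sc > df$depth, na.rm = TRUE))
      msg <- c(msg, "strand counts must sum to <= depth")
    oc <- df$f1r2 + df$f2r1
    if (any(oc > df$depth, na.rm = TRUE))
      msg <- c(msg, "orientation counts must sum to <= depth")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a VariantSet from a data.frame
#'
#' Missing annotation columns are added as NA; `variant_class` is derived from
#' ref/alt lengths when absent; `vaf` is computed as `alt_count / depth` when
#' absent; `filter_status` defaults to "" (pass).
#'
#' @param variants data.frame of per-allele calls.
#' @return A [VariantSet-class] object.
#' @export
VariantSet <- function(variants = emptyVariantFrame()) {
  df <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(df$variant_class) && nrow(df))
    df$variant_class <- inferVariantClass(df$ref, df$alt)
  if (is.null(df$vaf) && !is.null(df$depth) && !is.null(df$alt_count))
    df$vaf <- ifelse(df$depth > 0, df$alt_count / df$depth, NA_real_)
  for (col in variantColumns) {
    if (is.null(df[[col]])) {
      df[[col]] <- if (col == "filter_status") {
        rep("", nrow(df))
      } else if (col %in% c("pos", "depth", "alt_count", "ref_fwd", "ref_rev",
                            "alt_fwd", "alt_rev", "f1r2", "f2r1",
                            "cosmic_count")) {
        rep(NA_integer_, nrow(df))
      } else if (col %in% c("vaf", "popaf_exome", "popaf_genome", "CADD")) {
        rep(NA_real_, nrow(df))
      } else if (col == "dbsnp_member") {
        rep(NA, nrow(df))
      } else rep(NA_character_, nrow(df))
    }
  }
  df$filter_status[is.na(df$filter_status)] <- ""
  extra <- setdiff(names(df), variantColumns)
  df <- df[, c(variantColumns, extra), drop = FALSE]
  rownames(df) <- NULL
  new("VariantSet", variants = df)
}

#' @rdname VariantSet
#' @export
emptyVariantFrame <- function() {
  df <- data.frame(sample_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character(),
                   variant_class = character(), depth = integer(),
                   alt_count = integer(), vaf = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Infer the variant class from allele lengths
#'
#' @param ref,alt reference and alternate allele strings.
#' @return "SNV", "insertion", "deletion" or "MNV".
#' @export
inferVariantClass <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1 & la == 1, "SNV",
         ifelse(la > lr, "insertion",
                ifelse(la < lr, "deletion", "MNV")))
}

#' @describeIn VariantSet underlying data.frame
#' @param object,x a VariantSet.
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))

#' @export
setMethod("variants", "VariantSet", function(object) object@variants)

#' @describeIn VariantSet number of variant rows
#' @export
setMethod("length", "VariantSet", function(x) nrow(x@variants))

#' @describeIn VariantSet subset rows, keeping the class
#' @param i row index.
#' @export
setMethod("[", "VariantSet", function(x, i) {
  new("VariantSet", variants = x@variants[i, , drop = FALSE])
})

setMethod("show", "VariantSet", function(object) {
  df <- object@variants
  cat("VariantSet with", nrow(df), "calls in",
      length(unique(df$sample_id)), "samples\n")
  if (nrow(df)) {
    flt <- sum(nzchar(df$filter_status))
    cat("  genes:", paste(head(sort(unique(df$gene)), 8), collapse = ", "),
        if (length(unique(df$gene)) > 8) "..." else "", "\n")
    cat("  flagged by filters:", flt, "\n")
  }
  invisible(NULL)
})

#' Error-prone-region mask
#'
#' Holds flanked and merged intervals on 1-based closed coordinates
#' (converted once from 0-based half-open BED at read time).
#'
#' @slot ranges GRanges of masked intervals after flanking and merging.
#' @slot flank non-negative integer flank (bp) already applied.
#' @export
setClass("RegionMask",
         representation(ranges = "GRanges", flank = "integer"))

setValidity("RegionMask", function(object) {
  if (length(object@flank) != 1 || is.na(object@flank) || object@flank < 0)
    return("flank must be a single non-negative integer")
  TRUE
})

#' Construct a RegionMask from intervals
#'
#' @param chrom,start0,end0 contigs and 0-based half-open interval bounds.
#' @param flank_bp flank (bp) added to each side before merging (default 5).
#' @return A [RegionMask-class].
#' @export
RegionMask <- function(chrom = character(), start0 = integer(),
                       end0 = integer(), flank_bp = 5L) {
  if (any(start0 >= end0))
    stop("mask intervals must satisfy start < end")
  s <- pmax(0L, as.integer(start0) - as.integer(flank_bp))
  e <- as.integer(end0) + as.integer(flank_bp)
  gr <- GenomicRanges::reduce(
    GRanges(chrom, IRanges(start = s + 1L, end = e)))
  new("RegionMask", ranges = gr, flank = as.integer(flank_bp))
}

#' @describeIn RegionMask masked intervals as GRanges (1-based closed)
#' @param object a RegionMask.
#' @export
setGeneric("maskRanges", function(object) standardGeneric("maskRanges"))

#' @export
setMethod("maskRanges", "RegionMask", function(object) object@ranges)

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask:", length(object@ranges), "merged intervals,",
      "flank", object@flank, "bp\n")
  invisible(NULL)
})

#' Coding gene model for the sequencing panel
#'
#' The CDS (including the terminal stop codon) must have length divisible by
#' three and translate without internal stops. `cdsStart` anchors CDS base 1
#' on `chrom` so that genomic variant positions map onto codons; synthetic
#' panels place each gene contiguously on its own contig on the + strand.
#' `flank5`/`flank3` supply the trinucleotide context for the terminal CDS
#' bases.
#'
#' @slot gene gene symbol.
#' @slot cds coding sequence (character, ACGT).
#' @slot chrom contig carrying the CDS.
#' @slot cdsStart 1-based genomic position of the first CDS base.
#' @slot strand "+" or "-".
#' @slot flank5,flank3 single bases flanking the CDS.
#' @export
setClass("GeneModel",
         representation(gene = "character", cds = "character",
                        chrom = "character", cdsStart = "integer",
                        strand = "character",
                        flank5 = "character", flank3 = "character"))

setValidity("GeneModel", function(object) {
  cds <- object@cds
  if (nchar(cds) %% 3 != 0) return("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds)) return("CDS must contain only ACGT")
  aa <- translateCds(cds)
  ncod <- nchar(cds) / 3
  internal <- substr(aa, 1, ncod - 1)
  if (grepl("\\*", internal)) return("CDS contains an internal stop codon")
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  TRUE
})

#' @rdname GeneModel-class
#' @param gene,cds,chrom,cds_start,strand,flank5,flank3 slot values.
#' @export
GeneModel <- function(gene, cds, chrom = paste0("chr_", gene),
                      cds_start = 1001L, strand = "+",
                      flank5 = "A", flank3 = "A") {
  new("GeneModel", gene = gene, cds = toupper(cds), chrom = chrom,
      cdsStart = as.integer(cds_start), strand = strand,
      flank5 = flank5, flank3 = flank3)
}

#' Translate a CDS with the standard genetic code
#' @param cds coding sequence (character).
#' @return Amino-acid string ("*" = stop).
#' @export
translateCds <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(GENETIC_CODE[codons], collapse = "")
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@gene, ":", nchar(object@cds) / 3, "codons on",
      object@chrom, object@strand, "at", object@cdsStart, "\n")
  invisible(NULL)
})

#' Audit of a filtering run
#'
#' Removal counts use first-failure attribution in the pipeline's canonical
#' order, so `sum(removedCounts) + nRetained == nInput` always holds.
#'
#' @slot nInput,nRetained totals before/after filtering.
#' @slot removedCounts named integer vector, removals per filter label.
#' @slot perVariant data.frame with the ordered failed-filter list per call.
#' @export
setClass("FilterAudit",
         representation(nInput = "integer", nRetained = "integer",
                        removedCounts = "integer", perVariant = "data.frame"))

setValidity("FilterAudit", function(object) {
  if (sum(object@removedCounts) + object@nRetained != object@nInput)
    return("removed + retained must equal input")
  TRUE
})

#' @describeIn FilterAudit removals per filter label
#' @param object a FilterAudit.
#' @export
setGeneric("removedCounts", function(object) standardGeneric("removedCounts"))

#' @export
setMethod("removedCounts", "FilterAudit", function(object)
  object@removedCounts)

setMethod("show", "FilterAudit", function(object) {
  cat("FilterAudit:", object@nInput, "in,", object@nRetained, "retained\n")
  rc <- object@removedCounts
  for (nm in names(rc)) cat(sprintf("  %-16s %d\n", nm, rc[[nm]]))
  invisible(NULL)
})

#' Firth penalized logistic regression fit
#'
#' @slot coef,se named coefficient and standard-error vectors (log-odds).
#' @slot vcov inverse Fisher information at the optimum.
#' @slot ci matrix (lower, upper) of profile-penalized-likelihood CIs.
#' @slot p penalized likelihood-ratio p-values per coefficient.
#' @slot level CI level.
#' @slot penloglik,loglik penalized and unpenalized log-likelihood at optimum.
#' @slot iter Newton iterations used.
#' @slot converged logical convergence flag.
#' @slot X,y design matrix and response kept for profiling.
#' @export
setClass("FirthFit",
         representation(coef = "numeric", se = "numeric", vcov = "matrix",
                        ci = "matrix", p = "numeric", level = "numeric",
                        penloglik = "numeric", loglik = "numeric",
                        iter = "integer", converged = "logical",
                        X = "matrix", y = "numeric"))

setMethod("show", "FirthFit", function(object) {
  cat("Firth penalized logistic fit",
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  tab <- data.frame(coef = object@coef, se = object@se,
                    lower = object@ci[, 1], upper = object@ci[, 2],
                    p = object@p)
  print(round(tab, 4))
  invisible(NULL)
})

#' @describeIn FirthFit coefficient vector
#' @param object a FirthFit.
#' @export
setMethod("coef", "FirthFit", function(object) object@coef)

#' Per-gene site opportunity spectrum for dN/dS
#'
#' Counts of the 3L possible single-base substitutions of a CDS, classified
#' by strand-collapsed trinucleotide substitution class (96 classes) and
#' coding impact (synonymous / missense / truncating, where truncating =
#' nonsense + stop-loss).
#'
#' @slot gene gene symbol.
#' @slot counts 96 x 3 matrix of substitution opportunities.
#' @slot sites per-substitution table (cds_pos, ref, alt, impact, class).
#' @export
setClass("SiteOpportunities",
         representation(gene = "character", counts = "matrix",
                        sites = "data.frame"))

setMethod("show", "SiteOpportunities", function(object) {
  cat("SiteOpportunities for", object@gene, ":",
      sum(object@counts), "substitutions;",
      paste(colnames(object@counts),
            colSums(object@counts), collapse = ", "), "\n")
  invisible(NULL)
})
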