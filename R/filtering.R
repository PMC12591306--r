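## Four-strategy somatic variant filter with first-failure audit:
## (1) sequence bias (read-orientation + strand), (2) germline exclusion,
## (3) error-prone-region masking, (4) depth/count confidence plus
## cross-sample recurrence, followed by the VAF detection floor.

filterOrder <- c("orientation_bias", "strand_bias", "germline",
                 "region_mask", "low_confidence", "recurrent", "vaf_floor")

#' Test a variant set for read-orientation and strand bias
#'
#' Orientation bias: two-sided exact binomial test of the alt F1R2 count
#' against half of the alt F1R2+F2R1 total. Strand bias: two-sided Fisher
#' exact test on the (ref fwd, ref rev) x (alt fwd, alt rev) table. Variants
#' with missing counts on a dimension are untestable on that dimension and
#' pass it.
#'
#' @param vs a [VariantSet-class].
#' @param alpha_orientation,alpha_strand test levels (defaults 0.001; see the
#'   methods vignette for why per-variant levels are stringent).
#' @return data.frame with p-values and fail/untestable flags per variant.
#' @export
assessSequenceBias <- function(vs, alpha_orientation = 0.001,
                               alpha_strand = 0.001) {
  df <- variants(vs)
  cnt <- df[, c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "f1r2", "f2r1")]
  if (any(cnt < 0, na.rm = TRUE))
    stop("negative strand/orientation counts")
  n <- nrow(df)
  orient_p <- rep(NA_real_, n)
  strand_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- df$f1r2[i]; b <- df$f2r1[i]
    if (!is.na(a) && !is.na(b) && a + b > 0)
      orient_p[i] <- stats::binom.test(a, a + b, p = 0.5)$p.value
    tab <- matrix(c(df$ref_fwd[i], df$ref_rev[i],
                    df$alt_fwd[i], df$alt_rev[i]), 2)
    if (!anyNA(tab) && sum(tab) > 0)
      strand_p[i] <- stats::fisher.test(tab)$p.value
  }
  data.frame(
    orientation_p = orient_p, strand_p = strand_p,
    orientation_fail = !is.na(orient_p) & orient_p < alpha_orientation,
    strand_fail = !is.na(strand_p) & strand_p < alpha_strand,
    untestable = is.na(orient_p) & is.na(strand_p))
}

#' Germline exclusion
#'
#' Drops calls with gnomAD exome or genome frequency above `popaf_max`
#' (default 1%), calls with VAF above `vaf_germline` (default 35%), and
#' calls above `vaf_review` (default 20%) whose `chrom:pos:ref:alt` key is in
#' the germline review resource (the reproducible stand-in for a manual
#' dbSNP inspection).
#'
#' @param vs a [VariantSet-class].
#' @param review_keys character vector of known-germline keys.
#' @param config a [PipelineConfig-class].
#' @return data.frame with `keep` and `reason`
#'   (`popAF` / `VAF35` / `review-germline` / NA).
#' @export
applyGermlineFilters <- function(vs, review_keys = character(),
                                 config = chConfig()) {
  df <- variants(vs)
  popmax <- configValue(config, "popaf_max")
  pe <- ifelse(is.na(df$popaf_exome), 0, df$popaf_exome)
  pg <- ifelse(is.na(df$popaf_genome), 0, df$popaf_genome)
  key <- variantKey(df)
  reason <- rep(NA_character_, nrow(df))
  reason[df$vaf > configValue(config, "vaf_review") &
           key %in% review_keys] <- "review-germline"
  reason[df$vaf > configValue(config, "vaf_germline")] <- "VAF35"
  reason[pe > popmax | pg > popmax] <- "popAF"
  data.frame(keep = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Key identifying a variant allele across samples
#' @param df variant data.frame (or [VariantSet-class]).
#' @return `chrom:pos:ref:alt` strings.
#' @export
variantKey <- function(df) {
  if (is(df, "VariantSet")) df <- variants(df)
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Error-prone-region exclusion
#'
#' A variant is removed iff its reference span (`pos .. pos + nchar(ref) - 1`,
#' 1-based) intersects a masked interval (already flanked and merged).
#'
#' @param vs a [VariantSet-class].
#' @param mask a [RegionMask-class].
#' @return logical vector, TRUE = masked (remove).
#' @export
applyRegionMask <- function(vs, mask) {
  df <- variants(vs)
  if (!nrow(df)) return(logical(0))
  spans <- GRanges(df$chrom, IRanges(df$pos, df$pos + nchar(df$ref) - 1L))
  hits <- suppressWarnings(findOverlaps(spans, maskRanges(mask)))
  out <- logical(nrow(df))
  out[unique(queryHits(hits))] <- TRUE
  out
}

#' Depth and supporting-read confidence filter
#'
#' Retained calls require depth strictly above 400x and alt reads strictly
#' above 2 (SNV/MNV) or 5 (insertion/deletion); thresholds from `config`.
#'
#' @param vs a [VariantSet-class].
#' @param config a [PipelineConfig-class].
#' @return logical vector, TRUE = keep.
#' @export
applyConfidenceFilters <- function(vs, config = chConfig()) {
  df <- variants(vs)
  min_alt <- ifelse(df$variant_class %in% c("insertion", "deletion"),
                    configValue(config, "min_alt_indel_exclusive"),
                    configValue(config, "min_alt_snv_exclusive"))
  df$depth > configValue(config, "min_depth_exclusive") &
    df$alt_count > min_alt
}

#' Cross-sample recurrence filter
#'
#' A variant key observed in strictly more than `fraction` of the cohort's
#' samples (distinct samples, not call instances) is removed everywhere as a
#' recurrent technical call.
#'
#' @param vs a [VariantSet-class] pooled over samples.
#' @param n_samples total number of samples in the cohort.
#' @param fraction sample fraction threshold (default 0.10).
#' @return logical vector, TRUE = recurrent (remove).
#' @export
applyRecurrenceFilter <- function(vs, n_samples, fraction = 0.10) {
  stopifnot(n_samples >= 1)
  df <- variants(vs)
  if (!nrow(df)) return(logical(0))
  key <- variantKey(df)
  nsamp <- tapply(df$sample_id, key, function(s) length(unique(s)))
  recurrent <- names(nsamp)[nsamp / n_samples > fraction]
  key %in% recurrent
}

#' Split off nonsynonymous variants
#'
#' Association analyses use only nonsynonymous calls; the synonymous stream
#' is kept for dN/dS. Unknown consequence classes are retained with a
#' warning.
#'
#' @param vs a [VariantSet-class].
#' @return list with `nonsynonymous` and `synonymous` VariantSets.
#' @export
selectNonsynonymous <- function(vs) {
  df <- variants(vs)
  unknown <- !df$consequence %in% .consequenceLevels
  if (any(unknown))
    warning(sum(unknown), " variants with unknown consequence retained")
  syn <- df$consequence %in% "synonymous"
  list(nonsynonymous = vs[!syn], synonymous = vs[syn])
}

#' Run the full filter pipeline
#'
#' Applies, in canonical order, the orientation/strand bias tests, germline
#' exclusion, region masking, depth/count confidence, cross-sample
#' recurrence (evaluated on the post-germline set) and the VAF detection
#' floor. Each removed call is attributed to the first filter it fails; the
#' retained set is the same whatever the evaluation order since all filters
#' but recurrence are per-variant predicates.
#'
#' @param vs raw calls pooled over samples ([VariantSet-class]).
#' @param mask a [RegionMask-class] (or NULL to skip masking).
#' @param config a [PipelineConfig-class].
#' @param review_keys germline review resource (keys).
#' @param n_samples cohort size for the recurrence filter; defaults to the
#'   number of distinct sample ids in `vs`.
#' @return list with `retained` (VariantSet), `flagged` (all input calls with
#'   `filter_status` filled in) and `audit` ([FilterAudit-class]).
#' @export
runFilterPipeline <- function(vs, mask = NULL, config = chConfig(),
                              review_keys = character(),
                              n_samples = NULL) {
  df <- variants(vs)
  n <- nrow(df)
  if (is.null(n_samples))
    n_samples <- max(1L, length(unique(df$sample_id)))
  fails <- matrix(FALSE, n, length(filterOrder),
                  dimnames = list(NULL, filterOrder))
  if (n) {
    bias <- assessSequenceBias(vs, configValue(config, "alpha_orientation"),
                               configValue(config, "alpha_strand"))
    fails[, "orientation_bias"] <- bias$orientation_fail
    fails[, "strand_bias"] <- bias$strand_fail
    germ <- applyGermlineFilters(vs, review_keys, config)
    fails[, "germline"] <- !germ$keep
    if (!is.null(mask)) fails[, "region_mask"] <- applyRegionMask(vs, mask)
    fails[, "low_confidence"] <- !applyConfidenceFilters(vs, config)
    postGerm <- which(germ$keep)
    rec <- applyRecurrenceFilter(vs[postGerm], n_samples,
                                 configValue(config, "recurrence_fraction"))
    fails[postGerm, "recurrent"] <- rec
    aboveFloor <- df$vaf > configValue(config, "vaf_floor")
    fails[, "vaf_floor"] <- is.na(aboveFloor) | !aboveFloor
  }
  failedAny <- rowSums(fails) > 0
  first <- apply(fails, 1, function(f)
    if (any(f)) filterOrder[which(f)[1]] else NA_character_)
  status <- apply(fails, 1, function(f)
    paste(filterOrder[f], collapse = ";"))
  df$filter_status <- status
  flagged <- VariantSet(df)
  removed <- table(factor(first[failedAny], levels = filterOrder))
  audit <- new("FilterAudit",
               nInput = n, nRetained = as.integer(sum(!failedAny)),
               removedCounts = stats::setNames(as.integer(removed),
                                               filterOrder),
               perVariant = data.frame(
                 sample_id = df$sample_id, key = variantKey(df),
                 first_fail = first, all_fails = status,
                 stringsAsFactors = FALSE))
  list(retained = flagged[!failedAny], flagged = flagged, audit = audit)
}
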