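## Longitudinal clone dynamics: pair pre/post-therapy samples by variant
## key, classify each mutation's trajectory, summarize per patient.

#' Outer-join variants of a pre/post sample pair
#'
#' Variant identity across timepoints is exact (chrom, pos, ref, alt); no
#' clone tracking across distinct mutations is attempted.
#'
#' @param pre,post [VariantSet-class] objects for the two timepoints
#'   (filtered calls).
#' @param patient_id patient identifier recorded on the output.
#' @param months_between months between the venipunctures.
#' @return data.frame with one row per variant key present at either
#'   timepoint: vaf_pre / vaf_post are NA when undetected.
#' @export
pairVariants <- function(pre, post, patient_id, months_between = NA_real_) {
  dpre <- variants(pre); dpost <- variants(post)
  if (nrow(dpre) && length(unique(dpre$sample_id)) > 1)
    stop("pre sample contains calls from multiple samples")
  if (nrow(dpost) && length(unique(dpost$sample_id)) > 1)
    stop("post sample contains calls from multiple samples")
  kpre <- variantKey(dpre); kpost <- variantKey(dpost)
  keys <- union(kpre, kpost)
  gene <- stats::setNames(c(dpre$gene, dpost$gene), c(kpre, kpost))
  data.frame(patient_id = rep(patient_id, length(keys)), key = keys,
             gene = unname(gene[keys]),
             vaf_pre = dpre$vaf[match(keys, kpre)],
             vaf_post = dpost$vaf[match(keys, kpost)],
             months_between = rep(months_between, length(keys)),
             stringsAsFactors = FALSE)
}

#' Classify clone trajectories
#'
#' A mutation undetectable after therapy, or with a VAF lower by more than
#' `epsilon`, is vanished/decreased; a new mutation, or one with a VAF
#' higher by more than `epsilon`, is emerged/increased; anything else
#' (including exact ties at `epsilon = 0`) is unchanged.
#'
#' @param paired data.frame from [pairVariants()].
#' @param epsilon VAF tolerance for calling a change (default 0).
#' @return `paired` with a `category` factor column.
#' @export
classifyDynamics <- function(paired, epsilon = 0) {
  if (any(is.na(paired$vaf_pre) & is.na(paired$vaf_post)))
    stop("paired record with both VAFs missing")
  cat <- ifelse(is.na(paired$vaf_post) |
                  (!is.na(paired$vaf_pre) &
                     paired$vaf_post < paired$vaf_pre - epsilon),
                "vanished_decreased",
                ifelse(is.na(paired$vaf_pre) |
                         paired$vaf_post > paired$vaf_pre + epsilon,
                       "emerged_increased", "unchanged"))
  paired$category <- factor(cat, levels = c("vanished_decreased",
                                            "emerged_increased",
                                            "unchanged"))
  paired
}

#' Per-patient and cohort-level dynamics summary
#'
#' @param paired classified data.frame from [classifyDynamics()].
#' @return list: `per_patient` counts per category (sorted by patient) and
#'   `means` cohort averages per category.
#' @export
summarizeDynamics <- function(paired) {
  if (!nrow(paired)) stop("no paired variants to summarize")
  tab <- table(paired$patient_id, paired$category)
  per <- data.frame(patient_id = rownames(tab),
                    vanished_decreased = as.integer(tab[, "vanished_decreased"]),
                    emerged_increased = as.integer(tab[, "emerged_increased"]),
                    unchanged = as.integer(tab[, "unchanged"]),
                    stringsAsFactors = FALSE)
  per <- per[order(per$patient_id), , drop = FALSE]
  rownames(per) <- NULL
  list(per_patient = per,
       means = c(vanished_decreased = mean(per$vanished_decreased),
                 emerged_increased = mean(per$emerged_increased),
                 unchanged = mean(per$unchanged)))
}

#' Pair and classify a whole cohort of linked samples
#'
#' Uses the cohort table's `paired_pre_sample` links to pair each post
#' sample with its pre sample, then classifies and summarizes.
#'
#' @param vs filtered [VariantSet-class] containing both timepoints.
#' @param cohort cohort data.frame; rows whose `paired_pre_sample` is set
#'   are post samples.
#' @param epsilon VAF tolerance passed to [classifyDynamics()].
#' @return list: `paired` (classified records) and `summary`.
#' @export
runLongitudinal <- function(vs, cohort, epsilon = 0) {
  post <- cohort[!is.na(cohort$paired_pre_sample), , drop = FALSE]
  if (!nrow(post)) stop("cohort has no paired_pre_sample links")
  df <- variants(vs)
  pieces <- lapply(seq_len(nrow(post)), function(i) {
    preId <- post$paired_pre_sample[i]
    postId <- post$sample_id[i]
    if (!preId %in% cohort$sample_id)
      stop("paired_pre_sample ", preId, " not in cohort")
    pre <- VariantSet(df[df$sample_id == preId, , drop = FALSE])
    pst <- VariantSet(df[df$sample_id == postId, , drop = FALSE])
    classifyDynamics(pairVariants(pre, pst, patient_id = postId,
                                  months_between = post$elapsed_months[i]),
                     epsilon = epsilon)
  })
  paired <- do.call(rbind, pieces)
  list(paired = paired, summary = summarizeDynamics(paired))
}
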