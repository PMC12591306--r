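## End-to-end orchestration: simulate (optionally), filter, classify,
## estimate selection, run associations and longitudinal dynamics, and
## write per-stage TSVs plus a JSON run manifest.

#' Run the full CH analysis chain on a variant set
#'
#' @param vs raw calls ([VariantSet-class], pooled over samples).
#' @param cohort cohort covariate table.
#' @param mask optional [RegionMask-class].
#' @param panel optional list of [GeneModel-class] (enables dN/dS).
#' @param config a [PipelineConfig-class].
#' @param review_keys germline review resource keys.
#' @return list with the filtered set, audit, driver annotations,
#'   per-subject summaries, CH presence at each configured cutoff, dN/dS
#'   results (if a panel is given) and longitudinal dynamics (if the cohort
#'   has paired samples).
#' @export
runChPipeline <- function(vs, cohort, mask = NULL, panel = NULL,
                          config = chConfig(), review_keys = character()) {
  flt <- runFilterPipeline(vs, mask, config, review_keys,
                           n_samples = nrow(cohort))
  streams <- selectNonsynonymous(flt$retained)
  drv <- annotateDrivers(streams$nonsynonymous)
  subjects <- maxVafPerIndividual(streams$nonsynonymous,
                                  sample_ids = cohort$sample_id)
  cutoffs <- configValue(config, "vaf_cutoffs")
  presence <- vapply(cutoffs, function(co) chPresence(subjects, co),
                     logical(nrow(subjects)))
  colnames(presence) <- paste0("vaf_gt_", cutoffs)
  dnds <- if (!is.null(panel))
    tryCatch(runDnds(flt$retained, panel), error = function(e) NULL)
  longitudinal <- if (any(!is.na(cohort$paired_pre_sample)))
    runLongitudinal(flt$retained, cohort)
  list(filtered = flt$retained, audit = flt$audit,
       nonsynonymous = streams$nonsynonymous,
       synonymous = streams$synonymous, drivers = drv,
       subjects = subjects, presence = presence, dnds = dnds,
       longitudinal = longitudinal)
}

#' Write a JSON run manifest
#'
#' Records the configuration (and a content hash of it), the seed and the
#' output files of a pipeline run.
#'
#' @param config a [PipelineConfig-class].
#' @param seed the seed used.
#' @param outputs named character vector of written files.
#' @param path manifest path.
#' @export
writeRunManifest <- function(config, seed, outputs, path) {
  vals <- config@values
  hash <- sum(utf8ToInt(paste(names(vals),
                              vapply(vals, paste, character(1),
                                     collapse = ","),
                              collapse = ";")))
  jsonlite::write_json(
    list(config = vals, config_hash = hash, seed = seed,
         outputs = as.list(outputs)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
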