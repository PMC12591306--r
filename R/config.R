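## Pipeline configuration: every numeric threshold used downstream, with the
## study's published values as defaults, serializable to/from YAML.

.configDefaults <- list(
  vaf_floor = 0.005,          # detection floor: calls retained require VAF > floor
  vaf_germline = 0.35,        # VAF above which a call is treated as germline
  vaf_review = 0.20,          # VAF above which the germline review resource applies
  popaf_max = 0.01,           # gnomAD exome/genome frequency cap for somatic calls
  min_depth_exclusive = 400,  # retained calls require depth > this
  min_alt_snv_exclusive = 2,  # retained SNV/MNV calls require alt reads > this
  min_alt_indel_exclusive = 5,# retained indel calls require alt reads > this
  recurrence_fraction = 0.10, # keys in > this sample fraction are technical
  alpha_orientation = 0.001,  # exact binomial orientation-bias test level
  alpha_strand = 0.001,       # Fisher strand-bias test level
  dose_cutoff_gbq = 7.4,      # low/high RAIT dose split (GBq)
  age_split_years = 50,       # young/old stratification
  q_threshold = 0.10,         # BH significance level for selection
  vaf_cutoffs = c(0.005, 0.01, 0.02, 0.05),
  flank_bp = 5,               # error-prone-region flanking
  dose_unit_gbq = 1.11,       # dose reporting unit (per-1.11 GBq effects)
  age_unit_years = 10,        # age reporting unit (per-decade effects)
  seed = 1L
)

#' Pipeline thresholds and options
#'
#' All tunable thresholds of the filtering/association pipeline in one
#' object. Defaults are the study conditions: a 0.5% VAF detection floor,
#' germline exclusion at population allele frequency > 1% or VAF > 35% (with
#' a review resource applied above 20%), confidence requirements of depth
#' > 400x and > 2 (SNV) / > 5 (indel) supporting reads, recurrence exclusion
#' above 10% of samples, a 7.4 GBq low/high dose split, and dose/age effect
#' units of 1.11 GBq and 10 years.
#'
#' @slot values named list of thresholds (see [chConfig()] for names).
#' @export
setClass("PipelineConfig", representation(values = "list"))

setValidity("PipelineConfig", function(object) {
  v <- object@values
  miss <- setdiff(names(.configDefaults), names(v))
  if (length(miss))
    return(paste("missing config entries:", paste(miss, collapse = ", ")))
  bad <- function(x) !is.numeric(x) || any(is.na(x))
  for (nm in setdiff(names(.configDefaults), "seed"))
    if (bad(v[[nm]])) return(paste("non-numeric config entry:", nm))
  if (v$vaf_floor < 0 || v$vaf_floor > 1) return("vaf_floor outside [0, 1]")
  if (v$vaf_germline <= v$vaf_review)
    return("vaf_germline must exceed vaf_review")
  if (v$popaf_max < 0 || v$popaf_max > 1) return("popaf_max outside [0, 1]")
  if (v$recurrence_fraction <= 0 || v$recurrence_fraction > 1)
    return("recurrence_fraction outside (0, 1]")
  if (v$dose_cutoff_gbq < 0) return("dose_cutoff_gbq must be >= 0")
  if (any(v$vaf_cutoffs < 0 | v$vaf_cutoffs > 1))
    return("vaf_cutoffs outside [0, 1]")
  TRUE
})

#' Build a pipeline configuration
#'
#' @param ... named overrides of the defaults listed in
#'   [PipelineConfig-class]; unknown names are an error.
#' @return A [PipelineConfig-class].
#' @examples
#' cfg <- chConfig(dose_cutoff_gbq = 9.8)
#' configValue(cfg, "dose_cutoff_gbq")
#' @export
chConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.configDefaults))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  vals <- .configDefaults
  vals[names(over)] <- over
  new("PipelineConfig", values = vals)
}

#' @describeIn chConfig look up one threshold
#' @param config a PipelineConfig.
#' @param name threshold name.
#' @export
configValue <- function(config, name) {
  stopifnot(is(config, "PipelineConfig"))
  if (!name %in% names(config@values)) stop("unknown config entry: ", name)
  config@values[[name]]
}

#' @describeIn chConfig write the configuration to a YAML file
#' @param path file path.
#' @export
writeConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  yaml::write_yaml(config@values, path)
  invisible(path)
}

#' @describeIn chConfig read a configuration back from YAML
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(chConfig, vals[names(vals) %in% names(.configDefaults)])
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (nm in names(object@values))
    cat(sprintf("  %-24s %s\n", nm,
                paste(object@values[[nm]], collapse = ", ")))
  invisible(NULL)
})
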