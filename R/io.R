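## Readers and writers for the formats the pipeline exchanges:
## single-sample VCF (calls), TSV (cohort covariates, filtered variants),
## BED (error-prone-region masks), FASTA (CDS panel).

#' Read per-sample variant calls from a VCF file
#'
#' Parses a single-sample VCF whose INFO fields follow the documented
#' contract: `DP` (consensus depth, required), `AO` (alt reads, per allele),
#' `SRF`/`SRR` (ref strand counts), `SAF`/`SAR` (alt strand counts, per
#' allele), `F1R2`/`F2R1` (alt read-orientation counts, per allele), `ANN`
#' (per allele, `GENE|CONSEQUENCE|HGVSp`), `GNOMAD_AF_EX`, `GNOMAD_AF_GE`,
#' `COSMIC_CNT`, `DBSNP` (flag) and `CADD`. Multi-allelic records are split
#' into one row per ALT allele with per-allele counts.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_id identifier recorded in the `sample_id` column.
#' @return A [VariantSet-class] with one row per ALT allele.
#' @export
readVariantCalls <- function(path, sample_id) {
  vcf <- VariantAnnotation::readVcf(path, genome = "panel")
  hdr <- VariantAnnotation::info(VariantAnnotation::header(vcf))
  if (!"DP" %in% rownames(hdr))
    stop("missing DP: VCF INFO must carry consensus depth")
  vcf <- VariantAnnotation::expand(vcf)
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  if (is.null(info$DP) || anyNA(info$DP))
    stop("missing DP: depth absent for one or more records")
  unlist1 <- function(x) {
    if (is.list(x) || inherits(x, "List"))
      x <- vapply(as.list(x), function(v)
        if (length(v)) as.character(v[1]) else NA_character_, character(1))
    x
  }
  getAorNA <- function(key, mode = "integer") {
    x <- info[[key]]
    if (is.null(x)) return(rep(as.vector(NA, mode = mode), n))
    if (is.list(x) || inherits(x, "List")) x <- unlist1(x)
    x
  }
  ann <- unlist1(info$ANN)
  if (is.null(ann)) ann <- rep(NA_character_, n)
  annParts <- strsplit(ifelse(is.na(ann), "||", ann), "|", fixed = TRUE)
  pick <- function(k) vapply(annParts, function(p)
    if (length(p) >= k && nzchar(p[k])) p[k] else NA_character_, character(1))
  depth <- as.integer(info$DP)
  alt_count <- as.integer(getAorNA("AO"))
  df <- data.frame(
    sample_id = rep(sample_id, n),
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    depth = depth,
    alt_count = alt_count,
    vaf = ifelse(depth > 0, alt_count / depth, NA_real_),
    ref_fwd = as.integer(getAorNA("SRF")),
    ref_rev = as.integer(getAorNA("SRR")),
    alt_fwd = as.integer(getAorNA("SAF")),
    alt_rev = as.integer(getAorNA("SAR")),
    f1r2 = as.integer(getAorNA("F1R2")),
    f2r1 = as.integer(getAorNA("F2R1")),
    gene = pick(1), consequence = pick(2), protein_change = pick(3),
    popaf_exome = as.numeric(getAorNA("GNOMAD_AF_EX", "numeric")),
    popaf_genome = as.numeric(getAorNA("GNOMAD_AF_GE", "numeric")),
    cosmic_count = as.integer(getAorNA("COSMIC_CNT")),
    CADD = as.numeric(getAorNA("CADD", "numeric")),
    stringsAsFactors = FALSE)
  dbsnp <- info$DBSNP
  df$dbsnp_member <- if (is.null(dbsnp)) NA else as.logical(dbsnp)
  VariantSet(df)
}

#' Write a per-sample VCF in the dialect [readVariantCalls()] consumes
#'
#' @param vs a [VariantSet-class] restricted to one sample.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(vs, path) {
  df <- variants(vs)
  if (length(unique(df$sample_id)) > 1)
    stop("writeVariantVcf expects calls from a single sample")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Consensus depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alt read count\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"Ref forward reads\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"Ref reverse reads\">",
    "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt forward reads\">",
    "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt reverse reads\">",
    "##INFO=<ID=F1R2,Number=A,Type=Integer,Description=\"Alt F1R2 reads\">",
    "##INFO=<ID=F2R1,Number=A,Type=Integer,Description=\"Alt F2R1 reads\">",
    "##INFO=<ID=ANN,Number=A,Type=String,Description=\"GENE|CONSEQUENCE|HGVSp\">",
    "##INFO=<ID=GNOMAD_AF_EX,Number=A,Type=Float,Description=\"gnomAD exome AF\">",
    "##INFO=<ID=GNOMAD_AF_GE,Number=A,Type=Float,Description=\"gnomAD genome AF\">",
    "##INFO=<ID=COSMIC_CNT,Number=A,Type=Integer,Description=\"COSMIC occurrences\">",
    "##INFO=<ID=DBSNP,Number=0,Type=Flag,Description=\"dbSNP member\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD score\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmtNum <- function(x) ifelse(is.na(x), NA_character_,
                               sprintf("%.6g", as.numeric(x)))
  kv <- function(key, val) ifelse(is.na(val), NA_character_,
                                  paste0(key, "=", val))
  annField <- paste0(ifelse(is.na(df$gene), "", df$gene), "|",
                     ifelse(is.na(df$consequence), "", df$consequence), "|",
                     ifelse(is.na(df$protein_change), "", df$protein_change))
  parts <- cbind(kv("DP", df$depth), kv("AO", df$alt_count),
                 kv("SRF", df$ref_fwd), kv("SRR", df$ref_rev),
                 kv("SAF", df$alt_fwd), kv("SAR", df$alt_rev),
                 kv("F1R2", df$f1r2), kv("F2R1", df$f2r1),
                 kv("ANN", annField),
                 kv("GNOMAD_AF_EX", fmtNum(df$popaf_exome)),
                 kv("GNOMAD_AF_GE", fmtNum(df$popaf_genome)),
                 kv("COSMIC_CNT", df$cosmic_count),
                 ifelse(!is.na(df$dbsnp_member) & df$dbsnp_member,
                        "DBSNP", NA_character_),
                 kv("CADD", fmtNum(df$CADD)))
  infoStr <- apply(parts, 1, function(p) paste(p[!is.na(p)], collapse = ";"))
  ord <- order(df$chrom, df$pos)
  body <- paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS",
                infoStr, sep = "\t")[ord]
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read the cohort covariate table
#'
#' Expects a TSV with header columns `sample_id`, `age_ch`, `sex`, `smoking`,
#' `dose_gbq` (required) and `age_rait`, `elapsed_months`,
#' `paired_pre_sample` (optional; empty cells become NA, never zero).
#'
#' @param path TSV file.
#' @return data.frame of typed cohort rows.
#' @export
readCohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "age_ch", "sex", "smoking", "dose_gbq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table missing required columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in cohort table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  if (any(df$dose_gbq < 0, na.rm = TRUE))
    stop("negative dose_gbq in cohort table")
  if (any(df$age_ch <= 0, na.rm = TRUE))
    stop("age_ch must be positive")
  for (opt in c("age_rait", "elapsed_months"))
    if (is.null(df[[opt]])) df[[opt]] <- NA_real_
  if (is.null(df$paired_pre_sample)) df$paired_pre_sample <- NA_character_
  df$smoking <- as.logical(df$smoking)
  df
}

#' @rdname readCohort
#' @param cohort cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an error-prone-region mask from BED
#'
#' BED intervals are 0-based half-open; each is extended by `flank_bp` on
#' both sides (clamped at zero), then overlapping intervals are merged.
#'
#' @param path BED file with at least three columns, no header.
#' @param flank_bp flank in bp (default 5).
#' @return A [RegionMask-class].
#' @export
readRegionMask <- function(path, flank_bp = 5L) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED mask needs at least 3 columns")
  bad <- which(df[[2]] >= df[[3]])
  if (length(bad))
    stop("BED interval with start >= end at line ", bad[1])
  RegionMask(chrom = as.character(df[[1]]), start0 = as.integer(df[[2]]),
             end0 = as.integer(df[[3]]), flank_bp = flank_bp)
}

#' @rdname readRegionMask
#' @param chrom,start0,end0 raw (unflanked) 0-based half-open intervals.
#' @export
writeRegionBed <- function(chrom, start0, end0, path) {
  utils::write.table(data.frame(chrom, start0, end0), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read filtered variants as TSV
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces every field exactly.
#'
#' @param vs a [VariantSet-class].
#' @param path TSV file.
#' @export
writeVariantsTsv <- function(vs, path) {
  df <- variants(vs)
  out <- df
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                           sprintf("%.17g", df[[col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeVariantsTsv
#' @export
readVariantsTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = NA, quote = "")
  df$filter_status[is.na(df$filter_status)] <- ""
  for (col in c("vaf", "popaf_exome", "popaf_genome", "CADD"))
    if (!is.null(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  for (col in c("sample_id", "chrom", "ref", "alt", "gene", "consequence",
                "protein_change"))
    if (!is.null(df[[col]])) df[[col]] <- as.character(df[[col]])
  VariantSet(df)
}

#' Write/read a CDS panel as FASTA
#'
#' Gene placement metadata (contig, CDS start, strand, flanking bases) is
#' kept in the FASTA headers so a panel round-trips through one file.
#'
#' @param panel list of [GeneModel-class] objects.
#' @param path FASTA file.
#' @export
writePanelFasta <- function(panel, path) {
  seqs <- DNAStringSet(vapply(panel, function(g) g@cds, character(1)))
  names(seqs) <- vapply(panel, function(g)
    sprintf("%s chrom=%s start=%d strand=%s flank5=%s flank3=%s",
            g@gene, g@chrom, g@cdsStart, g@strand, g@flank5, g@flank3),
    character(1))
  writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writePanelFasta
#' @export
readPanelFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    hdr <- strsplit(names(seqs)[i], " ")[[1]]
    fields <- hdr[-1]
    kv <- strsplit(fields, "=")
    vals <- setNames(vapply(kv, `[`, character(1), 2),
                     vapply(kv, `[`, character(1), 1))
    GeneModel(gene = hdr[1], cds = as.character(seqs[[i]]),
              chrom = vals[["chrom"]], cds_start = as.integer(vals[["start"]]),
              strand = vals[["strand"]], flank5 = vals[["flank5"]],
              flank3 = vals[["flank3"]])
  })
}
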