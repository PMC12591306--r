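# Builders for small in-code fixtures.

# One or more variant rows with sensible defaults; override any column.
makeVariants <- function(n = 1, ...) {
  base <- data.frame(
    sample_id = rep("S1", n), chrom = rep("chr1", n),
    pos = seq(100L, by = 10L, length.out = n),
    ref = rep("A", n), alt = rep("G", n),
    depth = rep(1000L, n), alt_count = rep(20L, n),
    ref_fwd = rep(490L, n), ref_rev = rep(490L, n),
    alt_fwd = rep(10L, n), alt_rev = rep(10L, n),
    f1r2 = rep(10L, n), f2r1 = rep(10L, n),
    gene = rep("DNMT3A", n), consequence = rep("missense", n),
    protein_change = rep(NA_character_, n),
    popaf_exome = rep(0, n), popaf_genome = rep(0, n),
    cosmic_count = rep(0L, n), dbsnp_member = rep(FALSE, n),
    CADD = rep(10, n), stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  # keep counts consistent with depth/alt_count unless overridden
  ref_n <- base$depth - base$alt_count
  if (!"ref_fwd" %in% names(over)) base$ref_fwd <- ref_n %/% 2L
  if (!"ref_rev" %in% names(over)) base$ref_rev <- ref_n - base$ref_fwd
  for (nm in c("alt_fwd", "f1r2"))
    if (!nm %in% names(over)) base[[nm]] <- base$alt_count %/% 2L
  if (!"alt_rev" %in% names(over))
    base$alt_rev <- base$alt_count - base$alt_fwd
  if (!"f2r1" %in% names(over)) base$f2r1 <- base$alt_count - base$f1r2
  base$vaf <- base$alt_count / base$depth
  if (!is.null(over$vaf)) base$vaf <- over$vaf
  VariantSet(base)
}

# Tiny fixed gene: ATG GCT TGG TAA on its own contig at position 1001.
tinyGene <- function(cds = "ATGGCTTGGTAA", gene = "TG1")
  GeneModel(gene = gene, cds = cds, cds_start = 1001L,
            flank5 = "C", flank3 = "G")

# A config with every removal rule effectively disabled.
disabledConfig <- function()
  chConfig(alpha_orientation = 0, alpha_strand = 0, popaf_max = 1,
           vaf_germline = 1.01, vaf_review = 1.0, min_depth_exclusive = 0,
           min_alt_snv_exclusive = 0, min_alt_indel_exclusive = 0,
           recurrence_fraction = 1, vaf_floor = 0)

# Brute-force penalized log-likelihood for a 2x2 Firth design
# (intercept + group indicator): independent oracle for the Newton fit.
penll2x2 <- function(b0, b1, e1 = 2, n1 = 10, e0 = 0, n0 = 10) {
  mu0 <- plogis(b0); mu1 <- plogis(b0 + b1)
  ll <- e1 * log(mu1) + (n1 - e1) * log(1 - mu1) +
    e0 * log(mu0) + (n0 - e0) * log(1 - mu0)
  w0 <- mu0 * (1 - mu0); w1 <- mu1 * (1 - mu1)
  ll + 0.5 * log(n0 * w0 * n1 * w1)
}
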