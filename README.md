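# chclone

Clonal hematopoiesis (CH) — the expansion of mutated blood-cell clones —
rises with age, and DNA-damaging therapies select for clones carrying
DNA-damage-response mutations, most prominently truncating *PPM1D* and
missense *TP53*. Radioactive iodine therapy (RAIT) for thyroid cancer is a
systemic radiation exposure whose dose-dependent effect on CH can be probed
with error-corrected sequencing, which detects clones down to a variant
allele frequency (VAF) of 0.5%.

`chclone` is an R package for exactly this analysis: it takes per-sample
somatic variant calls from an error-corrected sequencing panel plus a cohort
covariate table (age at CH test, sex, smoking, cumulative RAIT dose in GBq,
elapsed time since first RAIT), and carries them through

* **variant filtering** — four strategies with a per-variant audit trail:
  read-orientation and strand-bias exact tests, germline exclusion (gnomAD
  population frequency > 1%, VAF > 35%, review resource above 20%),
  error-prone-region masking (BED intervals + 5 bp flanks), and
  depth/count confidence (depth > 400×, alt reads > 2 for SNVs / > 5 for
  indels) with cross-sample recurrence removal (> 10% of samples);
* **ARCH-PD driver classification** — the ordered putative-driver rule list
  (truncating variants in 17 loss-of-function myeloid genes, CALR exon 9,
  JAK2 V617F, FLT3-ITD, hotspot residues, COSMIC-count rules with VAF and
  population-frequency bounds);
* **selection inference** — per-gene maximum-likelihood dN/dS under a
  96-class strand-collapsed trinucleotide neutral model,
  ω<sub>c</sub> = (n<sub>c</sub>/E<sub>c</sub>)/(n<sub>syn</sub>/E<sub>syn</sub>),
  likelihood-ratio tests and Benjamini–Hochberg q-values (q < 0.10);
* **association statistics** — Firth penalized logistic regression
  (Jeffreys prior, profile-penalized-likelihood CIs) for sparse CH
  outcomes, log-VAF linear models with age × dose interactions (age per 10
  years, dose per 1.11 GBq), dose-cutoff optimization, Fisher-exact gene
  co-occurrence, and pathogenicity-score/VAF association;
* **longitudinal dynamics** — pairing pre/post-therapy samples and
  classifying each mutation as vanished/decreased, emerged/increased or
  unchanged.

A first-class synthetic-data module simulates the whole study design — a
358-subject cohort (110 controls, 115 low-dose < 7.4 GBq, 133 high-dose
≥ 7.4 GBq), truth-labelled variant calls with six injected artifact
classes, CDS panels, and 24 paired pre/post sample sets — so every stage is
testable without patient data.

## Worked example

Simulate the default cohort, run the pipeline, and ask the study's central
question — does cumulative dose select for truncating *PPM1D* clones?

```r
library(chclone)

cohort <- simulateCohort(seed = 7)            # 110 / 115 / 133 subjects
panel  <- simulateCdsPanel(seed = 7)          # 10-gene CDS panel
eff    <- effectConfig()
mask   <- RegionMask(c("chr_DNMT3A", "chr_TET2"), c(1200L, 1400L),
                     c(1230L, 1430L), flank_bp = 5L)
truth  <- simulateTruthMutations(cohort, eff, panel, seed = 7, mask = mask)
raw    <- renderRawCalls(truth, eff, cohort, panel, mask, seed = 7)
res    <- runChPipeline(raw$variants, cohort, mask, panel)
res$audit
#> FilterAudit: 5901 in, 1130 retained
#>   orientation_bias 912
#>   strand_bias      887
#>   germline         1425
#>   region_mask      730
#>   low_confidence   711
#>   recurrent        106
#>   vaf_floor        0
```

Most raw calls are artifacts; the audit attributes each removal to the
first filter it failed. Truncating-*PPM1D* prevalence then rises with dose
group, and a Firth regression (used because events are sparse) recovers a
positive per-1.11-GBq effect:

```r
fd    <- variants(res$filtered)
ppm1d <- unique(fd$sample_id[fd$gene == "PPM1D" &
          fd$consequence %in% c("nonsense", "frameshift", "splice_site")])
round(100 * tapply(cohort$sample_id %in% ppm1d,
                   assignDoseGroup(cohort$dose_gbq), mean), 1)
#> control     low    high
#>     1.8     4.3    15.8

X   <- cbind(1, dose_u = cohort$dose_gbq / 1.11, age10 = cohort$age_ch / 10)
fit <- fitFirthLogistic(X, as.numeric(cohort$sample_id %in% ppm1d))
exp(coef(fit)["dose_u"])      # odds ratio per 1.11 GBq
#> 1.081                       # 95% profile CI 1.057-1.108
```

The generator planted a hazard of 1.06 per 1.11 GBq, inside the CI. The
dN/dS module flags the same signal as positive selection of the truncating
class only:

```r
res$dnds$per_gene[res$dnds$per_gene$gene == "PPM1D",
                  c("gene", "omega_mis", "omega_tru", "q_mis", "q_tru")]
#>    gene omega_mis omega_tru q_mis    q_tru
#>   PPM1D     0.697      3.83 0.233 7.03e-05
```

ω<sub>tru</sub> ≈ 3.8 with q ≈ 7×10⁻⁵ — truncating-class positive
selection, while the missense class stays unremarkable.

A thin command-line wrapper over the same functions is included at
`inst/scripts/chclone.R`
(`simulate | filter | classify | dnds | associate | longitudinal | run-all`).

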