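---
title: "Methods: clonal hematopoiesis calling and dose-response inference"
author: "chclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal hematopoiesis calling and dose-response inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the statistical
models, the thresholds and why they have the defaults they do, what the
synthetic-data generator does and does not emulate, and the places where a
design choice was genuinely open.

## The analysis problem

Error-corrected sequencing of a blood-panel of CH-related genes yields, per
subject, a list of somatic variant calls with consensus depth, supporting
reads, strand and read-orientation counts, and annotations (gene,
consequence, protein change, population allele frequencies, COSMIC
occurrence counts, pathogenicity scores). The clone size of each mutation
is its variant allele frequency (VAF); the detection floor is 0.5%. The
scientific questions are (i) which calls are real CH mutations, (ii) which
are putative drivers, (iii) whether specific mutation classes are under
positive selection, (iv) how CH presence and clone size relate to age and
cumulative radioactive-iodine dose, and (v) how clones change between
paired pre/post-therapy samples.

## Variant filtering

Filters are per-variant predicates applied in a canonical order
(orientation bias, strand bias, germline, region mask, confidence,
recurrence, detection floor); each removed call is attributed to the first
filter it fails, so audit counts always reconcile
(`removed + retained = input`). The retained set is order-invariant because
every filter except recurrence is variant-local, and recurrence is always
evaluated on the post-germline set (the package's reading of an
under-specified point: counting recurrence before germline removal would
let common germline polymorphisms masquerade as "technical" recurrences).

Thresholds, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `vaf_floor` | 0.005 | detection floor; retained calls need VAF strictly above it |
| `popaf_max` | 0.01 | gnomAD exome/genome frequency above which a call is germline |
| `vaf_germline` | 0.35 | VAF above which a call is germline regardless of databases |
| `vaf_review` | 0.20 | VAF above which the germline review resource applies |
| `min_depth_exclusive` | 400 | consensus depth must strictly exceed this |
| `min_alt_snv_exclusive` / `min_alt_indel_exclusive` | 2 / 5 | supporting reads must strictly exceed these |
| `recurrence_fraction` | 0.10 | keys in more than this fraction of samples are technical |
| `flank_bp` | 5 | flank added to error-prone BED intervals |
| `alpha_orientation` / `alpha_strand` | 0.001 | per-variant bias-test levels |

All inequalities are strict, matching the "exceeding"/">" wording of the
filtering protocol; boundary cases are covered by tests.

**Why the bias-test levels are 0.001, not 0.05.** The orientation test is a
two-sided exact binomial test of the alt-read F1R2/F2R1 split; the strand
test is a Fisher exact test on the ref/alt × forward/reverse table. These
replace external orientation-bias tooling and caller-internal strand
heuristics with transparent, configurable statistics. A per-variant level
of 0.05 would discard 2–4% of perfectly unbiased true calls (the exact
test's realized size at alt counts of 10–40), which is incompatible with
retaining ≥ 99% of true mutations across a cohort of thousands of calls.
At 0.001 the family-wise loss on balanced counts is ≈ 0.1%, while
construction-level violations (all alt reads on one strand or one
orientation, at the supporting-read counts the confidence filter already
requires) remain detected with certainty. Both levels are configurable.

The "manual dbSNP inspection above 20% VAF" step of the original protocol
is automated as an explicit review-resource file of known-germline keys, so
runs are reproducible; no interactive mode is provided.

Coordinates: VCF positions are 1-based; BED masks are 0-based half-open and
converted once at read time (flank, then merge). An indel intersects the
mask if any reference base it spans is masked — the conservative reading of
"regions excluded".

## ARCH-PD driver classification

The rule engine evaluates the ordered criteria C1–C6, C8 and reports the
first match; criterion 7 (clustering near functionally validated loci) is
excluded, following the source ruleset's own exclusion. Literal readings:
"at least 10 times" in COSMIC is `>= 10`; "more than 100 times" is `> 100`;
the VAF bound is `< 0.42` and the population-frequency bound `< 0.003`,
taking the maximum of the exome and genome values with missing values as 0
(conservative inclusion, mirroring the filter module's "either database"
logic). FLT3-ITD is consumed as an annotation-level flag (in-frame
insertion of ≥ 3 bp in FLT3); read-level ITD detection is upstream of this
package. The hotspot residue table ships seeded with three canonical
myeloid hotspots (DNMT3A R882, FLT3 D835, CBL Y371) and is explicitly
incomplete — users reproducing published classifications must supply the
full residue list and exact CALR exon-9 coordinates for their genome build.

## dN/dS selection inference

The neutral mutation model has 96 strand-collapsed trinucleotide
substitution classes. For each gene, all 3L single-base substitutions of
the CDS are enumerated and classified by codon translation as synonymous,
missense, or truncating; two conventions had to be fixed and are tested:
stop-retaining changes in the stop codon count as synonymous, and stop-loss
counts as truncating-class impact. Class rates are Poisson maximum
likelihood from pooled observed synonymous counts over synonymous
opportunities, with empty classes shrunk to the global mean rate.

Per gene, a rate factor θ shared across classes absorbs gene-level
mutability: under the alternative θ is estimated from the synonymous counts
alone and ω<sub>c</sub> = (n<sub>c</sub>/E<sub>c</sub>)/(n<sub>syn</sub>/E<sub>syn</sub>);
under the null (ω<sub>c</sub> = 1) θ is profiled on the synonymous plus
impact-class counts; the likelihood-ratio statistic has 1 df. Genes with
observed impact mutations but no synonymous support get ω flagged infinite
and are excluded from the BH adjustment (q per impact class across genes,
significance at q < 0.10). A `calibration = "global"` mode (θ ≡ 1,
ω<sub>c</sub> = n<sub>c</sub>/E<sub>c</sub>) is available: it is the
lower-variance choice when gene-level mutability is known to be
homogeneous, and the group-level global dN/dS is always the plug-in ratio
Σn/ΣE.

This is a deliberately reduced model relative to full dNdScv-style
implementations: substitutions only (frameshift indels stay in the
association analyses but not in dN/dS), no gene-level covariate regression,
96 rather than 192 rate classes. Exact reproduction of published per-gene
significance lists is therefore not expected; directional behaviour
(truncating-class positive selection under dose enrichment) is what the
validation suite checks.

## Firth penalized logistic regression

CH presence at a 2% VAF cutoff is a sparse outcome (tens of events), and
dose-group splits can separate completely, so ordinary ML estimates can be
infinite. The package maximizes the Jeffreys-penalized likelihood
ℓ*(β) = ℓ(β) + ½ log det I(β) by Newton iteration on the Firth-modified
score U*(β) = Xᵀ(y − μ + h ∘ (½ − μ)), with step-halving on ℓ* and an
overflow-safe likelihood evaluated on the linear predictor. P-values are
penalized likelihood-ratio tests (each coefficient profiled at zero);
confidence intervals default to profile penalized likelihood — endpoints
where twice the profile drop equals the χ²(1) quantile, bracketed outward
in standard-error steps and solved by bisection — with Wald intervals
available by flag. In the saturated 2×2 case the Firth estimate equals the
classical add-one-half correction, which the tests exploit as a closed-form
oracle alongside dense grid search of ℓ*.

Model conventions: age enters per 10 years and continuous dose per
1.11 GBq (the dosing unit, 30 mCi); clone-size models regress the natural
log of the maximum VAF in percent (no pseudocount is needed because
detected VAFs are ≥ 0.5%); subjects with no retained mutations are excluded
from VAF-level models (and counted) but kept in presence models. Adjustment
sets follow the study design: age models adjust for sex and smoking; dose
models additionally for age and elapsed time. No multiplicity correction is
applied across per-gene association models (none is prescribed);
co-occurrence tests and dN/dS use BH.

**Dose-cutoff optimization.** The statistic behind the published optimal
cutoff is not stated, so the optimizer's default criterion — the penalized
likelihood-ratio statistic of the dichotomized dose from a Firth fit — is
the package's own interpretation, recorded in the output, with Youden's J
as an alternative. Candidates leaving fewer than `min_group_n = 5` subjects
on either side are skipped.

## Longitudinal dynamics

Variant identity across timepoints is the exact (chrom, pos, ref, alt) key;
no clone tracking across distinct mutations is attempted. A mutation absent
after therapy or with a lower VAF is vanished/decreased; a new or higher
mutation is emerged/increased. Exact ties are "unchanged" — a category the
classification rule needs for determinism even though the source dichotomy
does not name it — with a configurable tolerance ε (default 0, so swapping
the two timepoints exactly mirrors the vanished and emerged counts).

## The synthetic-data generator

The generator's defaults are the study conditions: group sizes 110/115/133;
per-group age means (SD) 60.0 (14.5), 52.4 (14.0), 56.4 (13.9) years
truncated at 20; female fractions 0.855/0.861/0.692; smoking fractions
0.973/0.948/0.925; doses 0 (control), uniform on (1.11, 7.4) GBq (low), and
7.4 GBq plus an exponential matching the 23.9 GBq mean (high); elapsed
months gamma-matched to means (SD) 75.9 (74.8) and 116.4 (76.3), truncated
at the 12-month inclusion bound, with age at first RAIT derived
consistently (age minus elapsed time, at least 19 years).

Mutation counts are Poisson per subject × gene × consequence class, with
multiplicative age hazards per decade (defaults above 1 for DNMT3A, TET2,
PPM1D) and dose hazards per 1.11 GBq (defaults above 1 only for truncating
PPM1D and missense TP53). No quantitative per-gene hazard is published, so
the defaults were chosen once to make the simulated cohort's marginal
statistics land near the published ones: ≈ 3.3 expected detected mutations
per subject (so ≈ 96% of subjects carry a detectable clone), a truncated
log-normal clone-size distribution (meanlog log 0.45, sdlog 0.62 on the
percent scale, floored at 0.5%), and a truncating-PPM1D dose hazard of 1.06
per 1.11 GBq (kept below the rate of the exponential dose tail so the mean
multiplier is finite; larger values make tail subjects dominate). A single
log-normal cannot reproduce all three published prevalence quantiles
(> 0.5/1/2% VAF) simultaneously — the real spectrum is a heterogeneous
mixture — so the defaults favour the 0.5% and 2% ends; the 1% prevalence
runs high in simulation.

Raw-call rendering draws consensus depth (normal, mean 1926×, SD 350,
floored at 600 for true clones), binomial supporting reads at the true VAF,
and binomial-0.5 strand/orientation splits for true calls. A call is
emitted only if its *observed* VAF exceeds the floor — a caller with a 0.5%
cutoff never reports sub-floor draws — and unemitted draws leave the truth
set, so truth-recovery is measured on detectable clones. Injected artifacts
violate exactly one rule each (population frequency > 1% with VAF ≈ 50%;
all alt reads on one strand; all alt reads F1R2; positions inside the mask;
depth ≤ 400; identical keys in > 10% of samples) and carry exactly balanced
counts on the dimensions they do not violate, so their first-failure
attribution is guaranteed by construction. Per-sample artifact rates
default to ≈ 13 artifacts against ≈ 3 true calls, reflecting that raw
low-VAF caller output is artifact-dominated.

The paired-cohort generator (24 patients, all low-dose, matching the
longitudinal design) perturbs pre-therapy VAFs by multiplicative log-normal
drift, drops clones at 10%, and adds Poisson(1.5) new clones against ≈ 14
pre-existing ones — chosen once so the per-patient dynamics scale matches
the published averages of 7.7 vanished/decreased vs 7.8 emerged/increased.

What the generator does **not** emulate: read-level errors and UMI
consensus (its calls are already error-corrected), genuine trinucleotide
mutational signatures in the truth process (truth sites are uniform within
impact classes), linkage between mutations in one clone, clonal phylogenies,
and gene-length heterogeneity of real panels (synthetic CDS are uniform
random coding sequences). Passing tests therefore demonstrate the
correctness of the package's statistics under its stated models, not the
biological fidelity of any particular parameter value.

## Numerical and design notes

* Random streams are per-operation substreams derived from the master seed,
  so each stage is reproducible on its own; all derived seeds stay below
  2³¹.
* Firth Newton iterations use a Cholesky-verified information matrix,
  reject non-finite penalized likelihoods during step-halving, and flag
  non-convergence honestly; rank-deficient designs fail naming the
  collinear columns.
* Profile-CI endpoints are declared "not bracketed" (an error) if no sign
  change appears within ≈ 30 expanding steps from the estimate.
* Ties in the per-subject maximum VAF are broken by the lowest
  (chrom, pos); CH presence is strict (`max VAF > cutoff`).
* TSV writers serialize doubles at 17 significant digits so write/read
  round trips are exact.
* Gene models carry explicit 5′/3′ flanking bases for terminal
  trinucleotide contexts; synthetic panels place each gene contiguously on
  its own contig, + strand, CDS starting at position 1001.

Validation problem sizes (the package's own choices, balancing Monte-Carlo
error against runtime): 500 replicate cohorts of n = 360 for CI coverage,
200 replicates for dN/dS power and dose-cutoff recovery, ≈ 6000 mutations
for neutral calibration, and a 100-sample cohort (≈ 1700 raw calls) for
filter truth recovery.

## Known limitations

* The dN/dS model is substitution-only and covariate-free; indel selection
  is not assessed.
* ARCH-PD criteria 2 and 5 depend on user-supplied resources for faithful
  reproduction of published driver lists; the shipped seeds are minimal.
* The recurrence filter's placement after germline filtering, the
  dose-cutoff optimization criterion, and the "unchanged" longitudinal
  category are documented interpretations of under-specified protocol
  points; each is configurable or recorded in output.
* Cohort-level published statistics (e.g. odds ratios from the clinical
  dataset) are not reproduction targets: the underlying covariates are not
  public, and the synthetic cohort emulates structure, not individual
  patients.
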