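---
title: "Statistical methods in cytomr: from cytokine GWAS summary statistics to drug-target candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in cytomr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomr)
```

## Overview

`cytomr` re-implements, as reusable and testable components, the inference
chain that takes per-cohort GWAS summary statistics for circulating
cytokine levels to prioritized causal cytokine–disease relationships:
meta-analysis, locus definition, fine-mapping, genetic correlation,
Mendelian randomization (MR) and colocalization. This vignette documents
the models, their assumptions, the tunable parameters, and the design
decisions taken where the methodology left genuine choices open.

## The summary-statistic simulation model

All validation rests on a generator that emulates the *summary statistics*
of a GWAS rather than individual-level genotypes. For a block of m variants
with LD correlation matrix R and joint standardized effects b (SD of trait
per allele on the standardized-genotype scale), the marginal z-statistics
of a GWAS of n individuals follow, to good approximation,

$$ z \sim \mathcal{N}\!\left(\sqrt{n}\,R\,b,\; R\right), $$

the classical "regression with summary statistics" model. The generator
draws z once per cohort with a single Cholesky factor per block (ridge
1e-8 on the diagonal when numerically semi-definite), then converts to
per-allele effects with

$$ \hat\beta = \frac{z}{\sqrt{2f(1-f)(n+z^2)}}, \qquad
   \widehat{se} = \frac{1}{\sqrt{2f(1-f)(n+z^2)}}, $$

where f is the effect-allele frequency. Working at the level of summary
statistics is exact for everything downstream — all estimators in the
package consume only (β, se, f, n, z) — and makes thousand-seed validation
studies affordable on one CPU.

**What the generator emulates.** Three cohorts of very different sizes
(defaults 10,000 / 20,000 / 35,000) measuring partially overlapping
cytokine panels; multiplicative per-cohort assay rescaling (different
affinity assays effectively measure the same analyte on different scales,
even after rank-inverse-normal transformation); cohort-specific effects
that exist in only one assay (the extreme of assay-dependent epitope
artifacts), which drive realistic cross-assay replication failure; LD via
AR(1) blocks, one block per cytokine gene region with exactly zero LD
between blocks; causal cytokine→cytokine links (trait B inherits
θ·b at trait A's causal variants, so the network MR has a planted
directed truth, and mediated cytokine→disease effects emerge
automatically); binary disease outcomes on the log-odds scale with
effective-sample-size standard errors, n_eff = 4/(1/n_case + 1/n_control);
and cis-eQTL exposure sets for transcriptome-wide MR. A configurable 5% of
variants carry palindromic A/T alleles so harmonization logic is
exercised.

**What it does not emulate.** Real haplotype structure (AR(1) decay is a
caricature — no long-range LD, no MHC), population stratification,
sample overlap between exposure and outcome GWASs, imputation error,
allele-frequency mismatch between cohorts, and genotyping artifacts. Tests
passing on this generator therefore demonstrate *internal statistical
correctness* (the estimators recover what the model plants, at the
advertised error rates), not robustness to the confounders of real data.

Determinism is a contract: identical configuration including the seed
yields byte-identical outputs, including the pipeline's on-disk TSVs. The
default conditions plant three cis signals per cytokine (joint effects
0.12, 0.09, 0.07, together ≈ 2.7% of trait variance, matching the upper
range of variance explained per cytokine in published panels) at the
25/50/75% positions of each 200-variant, 2 kb-spaced block, so that the
default instrument-selection settings retain three mutually independent
instruments.

## Meta-analysis

Effect estimates from the three assays are not on a common scale, so
cohorts are combined on the z scale with sample-size weights
(z_meta = Σ√nᵢ·zᵢ / √Σnᵢ, the METAL SAMPLESIZE scheme) and standardized
betas are reconstructed afterwards from z, the sample-size-weighted allele
frequency, and total n. Heterogeneity is assessed with Cochran's Q on the
*per-cohort reconstructed standardized* betas — computing Q on raw effects
would conflate scale differences with real heterogeneity. The direction
string spans the configured cohort order ('+', '−', '0', '?'), with
cohorts that never measured a trait contributing a constant '?'. Variants
present in a single cohort are retained with k = 1 and undefined Q.
Two-sided p-values are computed in log space, so p-values down to the
double-precision underflow limit (~1e-308) convert to finite z.

A note on the inflation statistic: λ is the median observed χ²₁ divided by
qchisq(0.5, 1) = qnorm(0.75)² ≈ 0.4549364. With all p = 0.5 the statistic
is exactly 1 by construction. At desk scale the demonstration genome is
small (1,600 variants) and a third of it carries planted signal, so
pipeline λ values sit well above 1; null calibration (λ ∈ [0.95, 1.05]) is
checked on dedicated 20,000-variant null panels with mild LD (ρ = 0.2),
where the median is estimated from effectively independent tests.

## Loci, replication, fine-mapping

Clumping is greedy: repeatedly promote the smallest-p unassigned variant
below the significance threshold (5e-8 genome-wide) and assign to it all
unassigned variants within 1 Mb at r² ≥ 0.001 (locus calling) or 0.1
(instruments). Ties on p break by (chromosome, position). The greedy
procedure is verified against an exhaustive re-implementation on 1,000
random instances of up to 12 variants. Lead variants within 1 Mb of each
other merge transitively into one locus (chained nearest-neighbour rule),
and a locus is *cis* when its lead lies within the closed interval of its
encoding gene ± 300 kb.

Replication of a reference cohort's genome-wide significant variants in a
target cohort requires presence, p < 0.05, and sign concordance. Variants
absent from the target's panel are excluded from the denominator by
default (configurable) — comparisons between assays with different
coverage would otherwise conflate non-replication with non-measurement.

Fine-mapping uses a deliberate single-causal-variant simplification: the
per-variant Wakefield log approximate Bayes factor

$$ \log ABF = \tfrac12\left[\log\frac{V}{V+W} + z^2\frac{W}{V+W}\right],
   \quad V = se^2, $$

normalized in log space over the locus gives posterior inclusion
probabilities, and the 95% credible set is the minimal descending-PIP
prefix reaching the coverage target (ties by position). The prior effect
standard deviation defaults to W = 0.15² for standardized quantitative
traits (0.2² for binary log-odds). Loci carrying several independent
signals are summarized by their strongest one; multi-effect iterative
Bayesian selection is out of scope and the output is labelled
`single_causal_abf` to make the assumption visible. Under the generator's
single-causal loci the 95% set contains the planted variant in ≥ 93% of
500 seeds (coverage is conservative at strong signals).

## LD-score regression

Under a polygenic architecture, E[χ²ⱼ] = 1 + n·h²·ℓⱼ/M with LD score
ℓⱼ = Σₖ r²ⱼₖ. The package fits this with one weighted least-squares pass
(1/ℓ heteroskedasticity weights, free intercept) — a documented
simplification of the reference tool's iterative weighting, adequate at
desk scale. Cross-trait, E[z₁ⱼz₂ⱼ] = √(n₁n₂)·ρ_g·ℓⱼ/M + intercept, and
r_g = ρ_g/√(h₁²·h₂²). Standard errors come from a 20-block delete-one
jackknife over position-contiguous blocks; replicates where a heritability
slope crosses zero are dropped from the SE computation. When either full
sample ĥ² ≤ 0 the result carries status `undefined_h2` and no correlation
number — mirroring how missing heritability evidence should surface as an
explicit status rather than a crash or a spurious value. With no sample
overlap between cohorts (a generator guarantee) the cross-trait intercept
has expectation zero.

## Mendelian randomization

Instruments are cis variants: within the encoding gene ± 300 kb,
associated at p < 5×10⁻⁵ (strict), clumped at r² < 0.1 (0.01 for eQTL
exposures, whose dense cis signals otherwise leak correlated instruments).
Exposure and outcome are harmonized on variant id with allele-swap
correction, strand-complement recovery, and palindromic variants kept only
when both minor-allele frequencies are below 0.42 and orientations agree.

Estimators and their minimum instrument counts: Wald ratio (1), fixed-
effects IVW (2; the main estimator), MR-Egger (3; rows oriented to
β_X ≥ 0, t-based inference on n−2 df, intercept = directional pleiotropy),
weighted median (3; inverse-variance ratio weights, interpolated weighted
empirical median, SE by a 200-replicate seeded parametric bootstrap).
Steiger filtering drops instruments with |β_outcome| > |β_exposure|
(strict), guarding against reverse causation in the cytokine network where
both sides are standardized. In the network driver, any variant in the
outcome's own instrument list is removed from the exposure's instruments,
so no variant instruments two cytokines at once. A sensitivity re-run can
additionally drop instruments with meta-analysis heterogeneity p < 0.05.

Multiple testing is controlled per analysis family with Benjamini–Hochberg
FDR: all ordered cytokine pairs of a network run form one family, all
cytokine × disease tests of a screen form another (a per-disease family is
available by subsetting). Binary-outcome effects are reported as odds
ratios per SD of exposure with exp(β ± 1.96·se) intervals. Directional
concordance of the sensitivity estimators with IVW is tabulated per family.

Calibration under the generator: IVW 95% CI coverage in [0.93, 0.97] and
type-I error in [0.03, 0.07] over 500 simulations with 20 instruments;
Egger intercept type-I in [0.03, 0.07] under balanced pleiotropy; the
weighted median stays within ±0.03 of the truth with 30% invalid
instruments while IVW is visibly biased.

## Colocalization

For a region (the cytokine gene ± 300 kb), per-SNP log ABFs for the two
traits are combined over the five single-causal configurations — no
signal, trait-1 only, trait-2 only, two distinct causal variants, one
shared causal variant — with priors p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵.
All sums run in log space; the distinct-variant term Σ_{i≠j} is computed
by a direct off-diagonal log-sum-exp for regions up to 2,000 SNPs, which
sidesteps the catastrophic cancellation in the algebraic shortcut
L1·L2 − L4 (used, guarded, only above that size). Posteriors are verified
to 1e-10 in log posterior against exact enumeration on regions of ≤ 10
SNPs. A pair is called colocalized when PP4 strictly exceeds 0.8;
sub-threshold PP4 values remain in the report.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → meta → replication → loci → finemap →
LDSC → network MR → disease screen → TWAS → coloc → summary. Each stage
writes a plain TSV; a JSON manifest records configuration, seed, and
per-stage row counts (and deliberately no wall-clock timestamps, so reruns
are byte-identical). The summary recomputes only quantities derivable from
the stage tables: locus counts, the Spearman correlation between lead
minor-allele frequency and |β| (strongly negative whenever effects are not
frequency-dependent by construction, a selection effect of genome-wide
significance), a Mann–Whitney comparison of cis versus trans lead effect
sizes (the test chosen for that comparison; the convention elsewhere is
often unstated), a pleiotropy histogram with an optional HLA-like interval
exclusion, and network/screen/colocalization counts.

Problem sizes were chosen so the whole validation suite runs in minutes on
one CPU: the demonstration pipeline uses 3 cohorts × 8 cytokines ×
200-variant blocks and 2 diseases (seconds per run); recovery studies use
50–100 seeds at 100-variant blocks; LDSC recovery uses M = 5,000 variants
in 25 blocks; credible-set coverage uses 200–500 seeds. These are the
package's own validation conditions, not estimates of real-cohort compute.

## Known limitations

* Single-causal-variant fine-mapping understates credible-set size at
  multi-signal loci; `set_size` and `contains_lead` are emitted so users
  can audit this.
* LDSC uses one weighting pass and a free intercept; estimates at desk
  scale carry wide jackknife intervals, and r̂_g can exceed 1 numerically
  (flagged beyond 1.25).
* The weighted-median bootstrap is parametric and seeded; its SE inherits
  the normality of the per-instrument estimates.
* Harmonization matches on variant id only (the generator guarantees
  shared ids); position-based matching and build liftover are out of
  scope.
* Binary-outcome MR interprets effects as log-odds per SD without
  attenuation correction for case-control ascertainment.
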