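---
title: "Methods: cell-mixture-aware EWAS, DMR calling, meQTL scanning and mediation"
author: "ewaspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-mixture-aware EWAS, DMR calling, meQTL scanning and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewaspipe)
```

## The problem

Epigenome-wide association studies (EWAS) of blood DNA methylation compare
per-CpG beta values — the fraction of methylated signal at a probe, in
[0, 1] — between disease cases and controls. Two features make this harder
than it looks. First, whole blood is a mixture: each sample's beta value is
a proportion-weighted average over leukocyte subtypes (CD4+ and CD8+ T
cells, CD14+ monocytes, ...), and disease shifts those proportions, so
uncorrected case–control contrasts confound composition with methylation.
Second, methylation is under local genetic control: common variants act as
methylation quantitative trait loci (meQTLs), so a disease-associated CpG
may be a downstream readout of a susceptibility allele rather than an
environmental mark. `ewaspipe` implements the full chain of analyses that
addresses both: quality control, reference-based cell deconvolution,
covariate-adjusted differential methylation at single positions (DMPs) and
regions (DMRs), proximity enrichment near GWAS loci, cis-meQTL scanning
with a causal-inference (mediation) chain, and cell-type-resolved
methylation–expression integration — together with a synthetic-cohort
generator whose planted effects make every stage testable without any
external download.

## Modelling scales

Linear models are fitted on M-values, `M = log2((beta + eps)/(1 - beta +
eps))` with `eps = 1e-6` guarding the endpoints; the logit-type transform
approximately stabilizes the variance of proportions, and its
heteroscedasticity on the raw beta scale is the standard argument for
modelling on M. Effect sizes are nevertheless *reported* as delta-beta
(case minus control difference in mean beta, covariate-adjusted), because
a difference of proportions is what practitioners interpret. The reported
delta-beta is the group coefficient of the matching beta-scale regression
— i.e. the adjusted group difference — not a back-transformed M
coefficient.

## Quality control

A probe *fails* in a sample when its detection p-value is at or above
0.01; a probe is removed when it fails in more than 5% of samples, and a
sample is removed when more than 5% of its probes fail. The "more than"
is strict: failing in exactly 5% of samples keeps the probe. Probes
overlapping common SNPs (population MAF at or above 0.01) are removed
from a user-supplied table. The sex check computes each sample's mean
X-chromosome M-value and splits samples with the exact two-cluster 1-D
partition minimizing within-cluster variance; the higher-methylation
cluster is called female (the X-inactivation intermediate-methylation
convention — the polarity is a convention of the bundled generator and
must be configured for a real array). Quantile normalization maps every
sample to the common distribution of row-wise means of the
column-sorted matrix (ties averaged), delegated to
`limma::normalizeQuantiles`; probe-type (Infinium I/II) correction and
explicit batch correction are out of scope — batch is instead available
as a model covariate. We filter first and normalize second.

Missing beta values are handled by complete-case analysis per probe;
no imputation is performed. This is the simplest defensible choice and
is stated here because it silently determines the per-probe sample
size `n` reported in every result table.

## Cell-mixture deconvolution

Leukocyte proportions are estimated per sample by constrained least
squares against a reference matrix `R` of per-cell-type mean beta values
at discriminating CpGs: minimize `||y - R w||^2` subject to `w >= 0` and
`sum(w) <= 1`, solved exactly as a quadratic program
(`quadprog::solve.QP`, the same route minfi takes for the Houseman
estimator). The solution is then renormalized to `sum(w) = 1` so the
proportions can enter design matrices; one cell type — the one with the
largest mean proportion — is dropped from designs to avoid collinearity
with the intercept. No published reference panel is bundled: the
generator emits a synthetic panel (200 probes, one third discriminating
each cell type at beta 0.85 vs 0.15), and real reference tables can be
supplied as a `reference_profile()`.

The epigenetic-age clock is the generic linear form: predicted age is
`transform(a0 + sum_j a_j beta_j)`. Published clocks differ in
coefficients and in their young-age transform, and redistributing
coefficient sets raises licensing and version-drift questions, so
coefficients are always a user (or generator) input; the transform
defaults to the identity. Age acceleration is the residual of predicted
on chronological age, which is mean-zero by construction and invariant
to affine miscalibration of the clock.

## DMPs, multiple testing, DMRs, power

Per probe, ordinary least squares of the M-value on case status plus
covariates (age, sex, cell proportions; optionally batch, smoking,
treatment), with a two-sided t-test on the group coefficient. Plain OLS
is the default — with 120+ samples per arm the empirical-Bayes variance
moderation of limma changes little, and the unmoderated test makes the
null calibration exact, which the test suite checks by simulation;
`moderated = TRUE` switches to limma's moderated t for small cohorts.
Family-wise error over the whole-blood probe set is controlled by Holm's
step-down procedure; separated-cell analyses use Benjamini–Hochberg FDR
(both via `stats::p.adjust`).

A DMR is a maximal run of manifest-consecutive probes in which every
adjacent pair lies within 2 kb, every probe attains Holm p < 0.05, and
all delta-betas share one sign; runs of at least three probes are
reported. Two readings of "within a 2 kb distance" exist — total span
vs adjacent gap — and they agree on every reported region in the
motivating use case; the gap reading is implemented because it is the
one that scales to long regions. A delta-beta of exactly zero matches
neither direction and breaks a run. The caller is validated against an
exhaustive enumeration oracle on 500 random instances.

Study planning uses the exact noncentral-t power of the two-sided
two-sample t-test (df `2n - 2`, noncentrality `d sqrt(n/2)`). At the
genome-wide alpha of 1e-7 and an effect of one standard deviation, 100
subjects per group yield 93.2% power; the minimum per-group size for 80%
power is 84 (both cross-checked against `stats::power.t.test` and a
Monte-Carlo oracle in the tests).

## Genetic integration

**HWE and trend.** Hardy–Weinberg equilibrium is the 1-df chi-square
goodness of fit of genotype counts to `p^2, 2pq, q^2`; the
Cochran–Armitage trend test uses the standard score statistic with
weights (0, 1, 2) and is checked against `stats::prop.trend.test`.

**LD.** Two-locus haplotype frequencies from unphased dosages are
estimated by EM over the double-heterozygote ambiguity (tolerance 1e-10,
at most 1,000 iterations; the log-likelihood is verified non-decreasing).
`D' = |D|/Dmax` uses the sign-dependent `Dmax` convention and
`r^2 = D^2/(pA pa pB pb)`.

**cis-meQTL scan.** Every (probe, SNP) pair with distance at most 1 Mb
and SNP MAF above 0.1 is tested by OLS of the probe's M-values on the
additive dosage plus covariates, with BH-FDR across all tests performed.
The scan is applied to the Holm-significant DMP set, mirroring the
design question "are the disease-associated positions genetically
driven?". Distance is `|pos_probe - pos_snp|`; probes without manifest
coordinates are skipped with a warning.

**Mediation chain.** Four regressions decide whether a SNP's disease
association is consistent with acting through methylation:
(1) logistic phenotype ~ SNP; (2) linear methylation ~ SNP;
(3) logistic phenotype ~ methylation + SNP, methylation term;
(4) the same model's SNP term. "Consistent with mediation" requires
criteria 1–3 to reject and criterion 4 not to (genotype independent of
phenotype given methylation) at a configurable alpha (default 0.05);
1–3 rejecting with 4 also rejecting is labelled "partial" — the
situation where the data cannot rule out a direct genotype effect.
Logistic separation is caught and flagged rather than reported as a
spurious zero p-value.

**Proximity enrichment.** For each half-width (25/50/100/250 kb), loci
are expanded around their midpoints and the per-window count of DMPs is
compared against 1,000 random window sets. Each random window is matched
to its observed counterpart's total probe count — exactly where
possible, within ±20% as a fallback when exact-count candidates are
scarce. The exact-first rule matters: matching only within a tolerance
band is asymmetric under the right-skewed genome-wide count distribution
and makes the test anti-conservative (we measured mean null empirical p
of 0.40 with band-only matching, 0.50 with exact-first). Two p-values
are reported and labelled: the two-sided Wilcoxon rank-sum of observed
versus pooled random per-window counts, and the empirical permutation
p `(1 + #{sets with mean >= observed mean})/(n_random + 1)`, which is
the more defensible summary. Both are bit-reproducible under the
supplied seed and invariant to locus input order.

## Expression integration

Differential expression is OLS of log2 intensity on case status with age
and sex, BH-FDR across genes; the group coefficient is the log2 fold
change. Methylation–expression coupling is Pearson correlation on
matched samples, computed separately within each cell type — the
scientific point being that a coupling present in one cell type (CD8 in
the generator) is diluted or invisible in whole blood and absent in
other types. Upstream normalization (background adjustment, VST,
quantile) is assumed done; the generator emits already-log-scale
intensities.

## The synthetic cohort

`simulate_cohort()` draws, per cell type, probe-level natural-logit
methylomes around cell-type reference means, adds planted effects, and
converts through the logistic function; whole blood is the exact
proportion-weighted mixture of the cell-type beta values (so with
`noise_sd = 0` the mixture identity holds to machine precision, which is
a test). Defaults are the study conditions:

* 120 cases + 120 controls; 10,000 probes on two 60 Mb autosomes plus 60
  chrX probes; 500 SNPs with MAF uniform on (0.1, 0.5); three cell types
  mixed with Dirichlet(6, 3, 3) weights.
* 50 planted DMPs with logit effects ±{0.15, 0.25, 0.35, 0.45}, inducing
  delta-beta of roughly 0.02–0.10 at intermediate methylation — the
  magnitude range of the strongest reported whole-blood IBD effects.
* Five 4-probe DMR blocks at 500 bp spacing, logit effect ±0.35; block
  spans are kept free of background probes so that planted membership is
  recoverable exactly (a stray interleaved probe would legitimately break
  manifest contiguity).
* Ten cis-meQTLs: slope 0.5 (natural-logit units per alternate allele) at
  10 kb, planted at probes with reference beta 0.5 where the logit→M
  map is linear (`M = logit(beta) * log2(e)`), plus a case effect of
  ±0.3 so the meQTL probes are themselves DMPs — the configuration the
  DMP-restricted scan is designed around. On the M scale the planted
  slope is `0.5 * log2(e) = 0.721`.
* One two-SNP LD pair drawn from haplotype frequencies
  (0.30, 0.20, 0.00, 0.50), whose generating values are D' = 1 and
  r^2 = 3/7 ≈ 0.4286 in closed form.
* 163 GWAS susceptibility loci (the catalogue size for this disease),
  with 80% of planted DMPs placed within 25 kb of locus midpoints, and a
  disjoint same-size "other disease" locus set in a reserved band as the
  negative control.
* Expression for 60 subjects across whole blood and three cell types;
  five genes coupled to DMP methylation (`expression = baseline -
  gamma * beta`, gamma = 4 log2 units per unit beta) in CD8 cells only.
* Clock probes linear in age on the beta scale (`beta = 0.2 +
  0.006 * age`), with the matching linear clock returned so prediction
  is exactly invertible up to noise; chrX probes at beta 1/3 (male) vs
  2/3 (female), i.e. M-values one unit either side of zero.
* Noise: per-cell-type logit-scale Gaussian sigma 0.15 (about 0.037 on
  the beta scale at beta 0.5, bracketing the 0.02 probe-level s.d. used
  for the power calculation); detection failures at rate 0.001.

Mediation scenarios are generated by `simulate_mediation()` rather than
inside the cohort: a single cohort disease label cannot simultaneously
realize a "full" (SNP→methylation→phenotype) and a "direct"
(SNP→phenotype, methylation independent) world. Scenario coefficients
(MAF 0.3, methylation shift 0.8 per allele, log-odds 1.5 per M unit,
residual sigma 0.5) were chosen by power arithmetic so the chain's
marginal criteria exceed 90% power at n = 400; at those values the
"full" scenario is labelled consistent-with-mediation in about 90% of
runs (the ~5% loss is criterion 4 falsely rejecting at alpha).

What the generator deliberately does **not** emulate: Infinium probe
chemistry (type I/II bias), array background and dye effects, batch
structure beyond an optional mean shift, realistic LD beyond the planted
pair, genotype–proportion coupling, and count-based expression noise.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to array artefacts.

## Numerical and design notes

* All randomness flows through explicit integer seeds; the pipeline fans
  a single seed into fixed per-stage substreams so toggling one stage
  does not perturb another's draws, and two runs with the same config and
  seed produce byte-identical result tables.
* The deconvolution QP adds a 1e-10 ridge for numerical positive
  definiteness; collinear reference columns produce a warning, not an
  error, because the renormalized solution is still a usable (if
  non-identifiable) summary.
* The enrichment null-calibration check draws 2,000 random probes as its
  null "DMP" set: the conservative permutation p has a tie-induced bias
  of about `1/(4 sqrt(pi * lambda))` for expected window total `lambda`,
  and 2,000 draws push that below 0.02, negligible against the KS
  criterion; the draw count is otherwise immaterial.
* Problem sizes used by the checks: 200 global-null cohorts of 2,000
  probes for the family-wise error rate; 500 random instances for the
  DMR oracle; 20 cohorts for meQTL recovery; 100 reps at 1,000 random
  window sets for enrichment; 50 reps per mediation scenario.
* Holm p-values of exactly adjacent ties, sign ties at delta-beta zero,
  and probes failing the per-probe sample minimum (rank + 3) are all
  resolved conservatively (run broken, record flagged `NA`).

## Known limitations

Real 450K data would additionally need probe-type normalization and
batch correction before these models; the sex-call polarity is
generator-specific; the enrichment matching assumes the manifest is
dense enough to supply exact-count candidate windows (sparse custom
panels will fall back to tolerance matching and should be interpreted
accordingly); and the mediation chain is a consistency screen, not a
causal estimate — unmeasured confounding between methylation and
disease, or conditioning-induced (collider) association, can produce a
significant criterion-4 test even when the SNP acts purely through
methylation, as the cohort analysis script illustrates.
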