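# ewaspipe

An integrative, cell-mixture-aware pipeline for epigenome-wide
association studies (EWAS) of blood DNA methylation in case–control
cohorts, written for analysts working with Illumina-style beta-value
matrices, paired genotypes and expression arrays.

Whole-blood methylation signals confound two things practitioners care
about separately: true disease-associated methylation change, and shifts
in leukocyte composition. And a disease-associated CpG may itself be the
readout of a nearby susceptibility variant. `ewaspipe` implements the
analysis chain that untangles this:

* **QC** — detection-p probe/sample filters (probe fails at detection
  *P* ≥ 0.01, removed when failing in >5% of samples; samples removed
  when >5% of probes fail), SNP-probe removal, an X-methylation sex
  check, quantile normalization, beta ↔ M-value conversion
  (`M = log2((β+ε)/(1−β+ε))`).
* **Deconvolution** — leukocyte proportions per sample by constrained
  least squares (min ‖β − Rw‖² s.t. w ≥ 0, Σw ≤ 1, then renormalized),
  plus a linear epigenetic-age clock and age-acceleration residuals.
* **DMPs** — per-CpG OLS of M-values on case status with age, sex and
  cell proportions as covariates; Holm (whole blood) and
  Benjamini–Hochberg (separated cells) adjustment; effects reported as
  Δβ (adjusted case − control difference in mean beta).
* **DMRs** — maximal runs of ≥3 manifest-consecutive probes, adjacent
  gaps ≤2 kb, same direction of change, all Holm *P* < 0.05.
* **Power** — exact noncentral-t two-sample power
  (df = 2n−2, ncp = d·√(n/2)) and minimum-n search.
* **Genetics** — cis-meQTL scan (1 Mb window, MAF > 0.1, covariate-
  adjusted OLS, BH-FDR), Hardy–Weinberg χ², Cochran–Armitage trend,
  two-locus D′/r² via EM over unphased genotypes, and a four-criterion
  causal-inference (mediation) chain for SNP → methylation → disease.
* **Enrichment** — permutation test of DMP counts near GWAS
  susceptibility loci versus 1,000 probe-density-matched random window
  sets at 25/50/100/250 kb, with Wilcoxon and empirical p-values.
* **Expression** — per-gene differential expression and cell-type-
  resolved methylation–expression Pearson correlation.
* **Synthetic cohorts** — `simulate_cohort()` generates a full
  multi-layer cohort (per-cell-type methylomes mixed by Dirichlet
  proportions, planted DMPs/DMRs/meQTLs/LD/expression couplings) with a
  recorded truth table, so the entire pipeline is testable offline.

See `vignettes/ewaspipe-methods.Rmd` for the models, parameter choices
and limitations, and the numbered scripts under `analysis/` for the
end-to-end study narrative.

## Worked example

```r
library(ewaspipe)

cohort <- simulate_cohort(sim_config(seed = 20260927))
meth   <- quantile_normalize(methylation_matrix(cohort$meth$whole_blood$beta))
props  <- estimate_cell_proportions(meth, cohort$reference)
dmps   <- fit_dmp(meth, cohort$sheet, design_spec(cell_props = props))
dmrs   <- call_dmrs(dmps, cohort$manifest)
```

Running the full narrative (`Rscript analysis/01_simulate.R` …
`05_expression.R`) prints, among others:

```
power at n=100/group, d=1, alpha=1e-7: 93.2% (min n for 80%: 84)
DMPs: 80 probes Holm-significant (planted 50 + 10 meQTL + 20 DMR probes)
planted DMP recovery: 100%
DMRs: 5 called; 5/5 planted blocks recovered with exact membership
enrichment near susceptibility loci: empirical p = 0.000999 at 25 kb
negative-control loci: empirical p = 1.000
meQTL scan: 672 tests, 10 FDR-significant, 10/10 planted pairs recovered
planted LD pair: D' = 1.00, r2 = 0.49 (generating D' = 1.00, r2 = 0.43)
mediation chain: 'full' labelled consistent in 94%, 'direct' in 0% of 50 reps
methylation-expression correlation (planted couplings): CD8 -0.61, CD14 -0.01
```

Reading the numbers: a two-sided two-sample t-test at the genome-wide
α = 1 × 10⁻⁷ reaches 93.2% power at 100 subjects per group for a
one-s.d. effect, so the planned cohort size is adequate. All 80
Holm-significant probes are planted effects (no false regions), the five
planted 4-probe regions are recovered with exact membership, DMPs are
strongly enriched within 25 kb of the susceptibility loci but show
nothing against a disjoint control locus set, every planted meQTL is
recovered at FDR 0.05, the planted haplotype structure reproduces its
closed-form D′ = 1, r² = 3/7, and the mediation chain separates a world
where the SNP acts through methylation from one where it acts directly.

`run_pipeline(pipeline_config(outdir, seed))` executes the same stages
end-to-end from one seed and writes one TSV per stage; identical config
and seed give byte-identical tables.

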