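#!/usr/bin/env Rscript
# Stage 2 -- quality control and cell-mixture deconvolution.
#
# Applies the probe/sample detection filters (probe fails at detection
# p >= 0.01; removed when failing in >5% of samples; samples removed
# when >5% of probes fail), checks reported sex against X-chromosome
# methylation, quantile-normalizes, estimates leukocyte proportions by
# constrained least squares against the reference panel, and applies
# the linear epigenetic-age clock. Reports how well the estimated
# proportions track the true mixing weights.

source("analysis/00_config.R")

cohort <- load_cohort()
meth <- cohort$meth$whole_blood

fp <- filter_probes(meth)
fs <- filter_samples(fp$meth)
cat(sprintf("QC: removed %d probes, %d samples\n",
            length(fp$report$probes_removed$detection),
            length(fs$report$samples_removed$failure_fraction)))

sexchk <- infer_sex(fs$meth, cohort$manifest, cohort$sheet)
cat(sprintf("sex check: %d mismatches in %d samples\n",
            sum(sexchk$mismatch), nrow(sexchk)))

norm <- quantile_normalize(methylation_matrix(fs$meth$beta))

props <- estimate_cell_proportions(norm, cohort$reference)
mae <- mean(abs(props$proportions -
                  cohort$proportions[rownames(props$proportions), ]))
cat(sprintf("deconvolution: mean absolute proportion error %.4f\n", mae))
save_table(data.frame(sample_id = rownames(props$proportions),
                      props$proportions, check.names = FALSE),
           "cell_proportions.tsv")

age <- predict_epigenetic_age(norm, cohort$clock)
acc <- age_acceleration(age, cohort$sheet$age)
grp <- cohort$sheet$phenotype != "control"
cat(sprintf("epigenetic age: r = %.3f vs chronological age\n",
            cor(age, cohort$sheet$age)))
cat(sprintf("age acceleration, cases vs controls: %.2f y (t-test p = %.2f)\n",
            mean(acc[grp]) - mean(acc[!grp]), t.test(acc ~ grp)$p.value))
save_table(data.frame(sample_id = cohort$sheet$sample_id,
                      predicted_age = age, acceleration = acc),
           "epigenetic_age.tsv")
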