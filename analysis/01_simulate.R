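#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic cohort.
#
# Generates the desk-scale case-control cohort every later stage
# analyses: 120 IBD cases and 120 controls, 10,000 CpG probes on two
# synthetic autosomes plus a chrX panel, three mixed leukocyte types,
# 500 SNPs, expression for 60 subjects, and 163 GWAS susceptibility
# loci. All planted effects (50 DMPs, five 4-probe DMR blocks, ten
# cis-meQTLs, one LD pair, five expression couplings) are recorded in
# truth tables for later comparison. Writes the full cohort with a
# checksum manifest under results/cohort/.

source("analysis/00_config.R")

cohort <- load_cohort()
print(cohort)
write_cohort(cohort, file.path(RESULTS_DIR, "cohort"))
stopifnot(verify_cohort_checksums(file.path(RESULTS_DIR, "cohort")))

cat(sprintf("planted: %d DMPs, %d DMR blocks, %d meQTLs, %d couplings\n",
            nrow(cohort$truth$dmps),
            length(unique(cohort$truth$dmr_blocks$block)),
            nrow(cohort$truth$meqtls), nrow(cohort$truth$couplings)))
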