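test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(light_config(seed = 42))
  b <- simulate_cohort(light_config(seed = 42))
  expect_identical(a$meth$whole_blood$beta, b$meth$whole_blood$beta)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(light_config(seed = 43))
  expect_false(identical(a$meth$whole_blood$beta, c$meth$whole_blood$beta))
})

test_that("whole blood is the exact mixture of cell-type beta values", {
  co <- simulate_cohort(light_config(seed = 2, noise_sd = 0))
  K <- colnames(co$proportions)
  mix <- Reduce(`+`, lapply(K, function(k)
    co$meth[[k]]$beta *
      matrix(co$proportions[, k], nrow(co$meth[[k]]$beta),
             ncol(co$meth[[k]]$beta), byrow = TRUE)))
  expect_equal(mix, co$meth$whole_blood$beta, tolerance = 1e-12)
})

test_that("with nothing planted and no noise, case and control means agree", {
  co <- simulate_cohort(light_config(seed = 3, noise_sd = 0, n_dmp = 0,
                                     n_dmr_blocks = 0, n_meqtl = 0,
                                     n_snps = 0))
  case <- co$sheet$phenotype != "control"
  # outside the deliberately structured panels (deconvolution panel:
  # cell-type contrasts; clock: age; chrX: sex) every probe's value is a
  # deterministic function of its shared reference, so group means agree
  # to machine precision
  keep <- setdiff(co$manifest$probe_id[co$manifest$chrom != "chrX"],
                  c(co$truth$clock_probes, co$truth$ref_probes))
  b <- co$meth$whole_blood$beta[keep, ]
  diff <- rowMeans(b[, case, drop = FALSE]) -
    rowMeans(b[, !case, drop = FALSE])
  expect_lt(max(abs(diff)), 1e-12)
})

test_that("planted meQTL slopes are recoverable at the generator's scale", {
  co <- simulate_cohort(light_config(seed = 7, n_cases = 200,
                                     n_controls = 200))
  tr <- co$truth$meqtls
  slopes <- vapply(seq_len(nrow(tr)), function(i) {
    m <- beta_to_m(co$meth$whole_blood$beta[tr$probe_id[i], ])
    g <- co$geno$dosage[tr$snp_id[i], ]
    unname(coef(lm(m ~ g))["g"])
  }, numeric(1))
  expected <- tr$slope * log2(exp(1))  # logit units -> M (log2) units
  expect_true(all(abs(slopes / expected - 1) < 0.10))
  # per-genotype M-value means are ordered with the slope sign
  m <- beta_to_m(co$meth$whole_blood$beta[tr$probe_id[1], ])
  g <- co$geno$dosage[tr$snp_id[1], ]
  mg <- tapply(m, g, mean)
  expect_true(all(diff(mg) > 0))
})

test_that("the LD generator reproduces its closed-form D' and r2", {
  # equilibrium haplotypes: D = 0, r2 = 0
  eq <- ld_stats(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(eq$D, 0)
  expect_equal(eq$r2, 0)

  # the planted regime: complete D', r2 = 3/7
  gen <- ld_stats(c(0.30, 0.20, 0.00, 0.50))
  expect_equal(gen$Dprime, 1)
  expect_equal(gen$r2, 0.4285714, tolerance = 1e-6)
  expect_equal(gen$D, 0.15)

  # law of large numbers: sample r2 near the generating value
  sim <- simulate_ld_genotypes(c(0.30, 0.20, 0.00, 0.50), 10000, seed = 8)
  r2_hat <- cor(sim$dosage[1, ], sim$dosage[2, ])^2
  expect_lt(abs(r2_hat - gen$r2), 0.03)

  expect_error(simulate_ld_genotypes(c(-0.1, 0.4, 0.4, 0.3), 10),
               "negative")
})

test_that("the truth table closes: planted effects recoverable at zero noise", {
  co <- simulate_cohort(light_config(seed = 11, noise_sd = 0))
  case <- as.numeric(co$sheet$phenotype != "control")
  # every planted DMP shifts the case mean in the recorded direction
  for (i in seq_len(nrow(co$truth$dmps))) {
    b <- co$meth$CD4$beta[co$truth$dmps$probe_id[i], ]
    d <- mean(b[case == 1]) - mean(b[case == 0])
    expect_equal(sign(d), sign(co$truth$dmps$delta[i]))
  }
  # meQTL regression on the known design recovers the slope near-exactly
  tr <- co$truth$meqtls
  for (i in seq_len(nrow(tr))) {
    m <- log(co$meth$CD4$beta[tr$probe_id[i], ] /
               (1 - co$meth$CD4$beta[tr$probe_id[i], ]))  # natural logit
    g <- co$geno$dosage[tr$snp_id[i], ]
    fit <- lm(m ~ g + case)
    expect_equal(unname(coef(fit)["g"]), tr$slope[i], tolerance = 1e-6)
  }
  # every truth record refers to an existing probe/SNP/gene id
  expect_true(all(co$truth$dmps$probe_id %in% co$manifest$probe_id))
  expect_true(all(co$truth$meqtls$snp_id %in% rownames(co$geno$dosage)))
  expect_true(all(co$truth$couplings$gene_probe_id %in%
                    rownames(co$expression$CD8)))
})

test_that("expression is coupled to methylation only in the target cell type", {
  co <- simulate_cohort(light_config(seed = 13, coupling_gamma = 6,
                                     n_expr_subjects = 60))
  cp <- co$truth$couplings[1, ]
  subj <- colnames(co$expression$CD8)
  b_cd8 <- co$meth$CD8$beta[cp$probe_id, subj]
  r_cd8 <- cor(co$expression$CD8[cp$gene_probe_id, subj], b_cd8)
  r_cd14 <- cor(co$expression$CD14[cp$gene_probe_id, subj],
                co$meth$CD14$beta[cp$probe_id, subj])
  expect_lt(r_cd8, -0.4)
  expect_lt(abs(r_cd14), 0.4)
})

test_that("write_cohort emits verifiable files that read back equal", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(light_config(seed = 17))
  write_cohort(co, dir)
  expect_true(verify_cohort_checksums(dir))
  back <- read_methylation(file.path(dir, "beta_whole_blood.tsv"),
                           file.path(dir, "detp_whole_blood.tsv"))
  expect_equal(back$beta, co$meth$whole_blood$beta, tolerance = 1e-9)
  geno <- read_genotypes(file.path(dir, "genotypes.vcf"))
  expect_equal(geno$dosage, co$geno$dosage)
  loci <- read_loci(file.path(dir, "ibd_loci.bed"))
  expect_equal(loci$start, co$loci$start)
  sheet <- read_sample_sheet(file.path(dir, "samples.csv"))
  expect_equal(sheet$phenotype, co$sheet$phenotype)

  # tampering is caught
  cat("x", file = file.path(dir, "samples.csv"), append = TRUE)
  expect_error(verify_cohort_checksums(dir), "samples.csv")

  # an empty cohort refuses to write
  co0 <- co
  co0$sheet <- co0$sheet[0, ]
  expect_error(write_cohort(co0, dir), "empty")
})

test_that("mediation scenario generator produces the advertised structure", {
  full <- simulate_mediation(2000, "full", seed = 21)
  # SNP shifts methylation; methylation shifts disease odds
  expect_gt(abs(coef(lm(full$m ~ full$dosage))[2]), 0.6)
  expect_gt(mean(full$phenotype[full$m > median(full$m)]),
            mean(full$phenotype[full$m <= median(full$m)]))
  direct <- simulate_mediation(2000, "direct", seed = 22)
  expect_lt(abs(coef(lm(direct$m ~ direct$dosage))[2]), 0.1)
  none <- simulate_mediation(2000, "none", seed = 23)
  expect_lt(abs(cor(none$m, none$phenotype)), 0.08)
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(n_cases = -1), "non-negative")
  expect_error(sim_config(ld_haplotype_freqs = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(sim_config(meqtl_distance_bp = 1e9), "exceeds chromosome")
  expect_error(sim_config(n_probes = 100), "too small")
})
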