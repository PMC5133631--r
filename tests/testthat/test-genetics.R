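test_that("HWE chi-square matches hand computation", {
  r <- hwe_test(c(25, 50, 25))
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  # total homozygote excess: expected (25, 50, 25) -> chisq 100
  r2 <- hwe_test(c(50, 0, 50))
  expect_equal(r2$chisq, 100)
  expect_lt(r2$p, 1e-20)
  expect_warning(r3 <- hwe_test(c(0, 0, 10)), "monomorphic")
  expect_true(is.na(r3$chisq))
})

test_that("Cochran-Armitage trend matches its formula and prop.trend.test", {
  r <- armitage_trend(c(10, 20, 30), c(30, 20, 10))
  expect_equal(r$chisq, 20)
  # agreement with the base-R implementation of the same statistic
  pt <- suppressWarnings(prop.trend.test(c(10, 20, 30), c(40, 40, 40)))
  expect_equal(r$chisq, unname(pt$statistic))
  expect_equal(r$p, pt$p.value)

  # no association
  r0 <- armitage_trend(c(15, 25, 10), c(15, 25, 10))
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p, 1)

  # swapping case/control labels leaves the statistic unchanged
  set.seed(1)
  for (i in 1:20) {
    a <- rmultinom(1, 50, c(0.3, 0.5, 0.2))[, 1]
    b <- rmultinom(1, 60, c(0.4, 0.4, 0.2))[, 1]
    expect_equal(armitage_trend(a, b)$chisq, armitage_trend(b, a)$chisq,
                 tolerance = 1e-12)
  }

  expect_warning(rd <- armitage_trend(c(0, 0, 10), c(0, 0, 5)),
                 "degenerate")
  expect_true(is.na(rd$chisq))
})

test_that("EM haplotype estimation recovers the generating LD", {
  sim <- simulate_ld_genotypes(c(0.30, 0.20, 0.00, 0.50), 10000, seed = 2)
  r <- ld_pair(sim$dosage[1, ], sim$dosage[2, ])
  expect_true(r$converged)
  expect_equal(sum(r$haplotypes), 1, tolerance = 1e-9)
  expect_true(all(r$haplotypes >= 0 & r$haplotypes <= 1))
  expect_lt(abs(r$Dprime - 1), 0.02)
  expect_lt(abs(r$r2 - 0.4286), 0.03)

  # independent markers: near-zero r2
  sim0 <- simulate_ld_genotypes(c(0.25, 0.25, 0.25, 0.25), 10000, seed = 3)
  r0 <- ld_pair(sim0$dosage[1, ], sim0$dosage[2, ])
  expect_lt(r0$r2, 0.01)
})

test_that("without double heterozygotes EM equals direct haplotype counting", {
  # genotypes chosen so no sample is het at both markers: phase is known
  g1 <- c(0, 0, 1, 2, 2, 1, 0, 2, 1, 1, 0, 2)
  g2 <- c(0, 2, 0, 0, 2, 2, 1, 1, 0, 2, 1, 1)
  r <- ld_pair(g1, g2)
  cAB <- sum(2 * (g1 == 2 & g2 == 2) + (g1 == 2 & g2 == 1) +
               (g1 == 1 & g2 == 2))
  expect_equal(unname(r$haplotypes["pAB"]), cAB / (2 * length(g1)),
               tolerance = 1e-9)

  # EM log-likelihood is non-decreasing iteration over iteration
  sim <- simulate_ld_genotypes(c(0.4, 0.1, 0.2, 0.3), 500, seed = 4)
  lls <- vapply(1:8, function(it)
    suppressWarnings(ld_pair(sim$dosage[1, ], sim$dosage[2, ],
                             max_iter = it))$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-10))

  expect_warning(rm <- ld_pair(rep(0, 20), rbinom(20, 2, 0.4)),
                 "monomorphic")
  expect_true(is.na(rm$r2))
  expect_error(ld_pair(c(0, 1), c(1, 0)), ">= 10")
})

test_that("the cis-meQTL scan honours window and MAF rules and the oracle", {
  co <- simulate_cohort(light_config(seed = 5, n_cases = 120,
                                     n_controls = 120))
  al <- align_samples(list(meth = co$meth$whole_blood, geno = co$geno,
                           sheet = co$sheet))
  res <- scan_cis_meqtl(al$layers$meth, al$layers$geno, co$manifest,
                        al$layers$sheet)
  # every reported pair is inside the window and above the MAF threshold
  expect_true(all(res$distance <= 1e6))
  expect_true(all(res$maf > 0.1))
  # planted pairs are found and significant
  tr <- merge(res, co$truth$meqtls, by = c("snp_id", "probe_id"))
  expect_equal(nrow(tr), nrow(co$truth$meqtls))
  expect_true(all(tr$p_fdr < 0.05))

  # zero-covariate scan equals the simple-regression oracle
  res0 <- scan_cis_meqtl(al$layers$meth, al$layers$geno, co$manifest,
                         al$layers$sheet,
                         design = design_spec(covariates = character(0)))
  row <- res0[1, ]
  m <- beta_to_m(al$layers$meth$beta[row$probe_id, ])
  g <- al$layers$geno$dosage[row$snp_id, ]
  fit <- summary(lm(m ~ g))$coefficients
  expect_equal(row$slope, fit["g", 1], tolerance = 1e-9)
  expect_equal(row$p, fit["g", 4], tolerance = 1e-9)

  # a SNP 2 Mb away from every probe yields no test
  far <- genotype_matrix(matrix(rbinom(nrow(co$sheet), 2, 0.4), 1,
                                dimnames = list("rsFAR", co$sheet$sample_id)),
                         chrom = "chr9", pos = 1, ref = "A", alt = "G")
  expect_warning(none <- scan_cis_meqtl(al$layers$meth, far, co$manifest,
                                        al$layers$sheet),
                 "no eligible")
  expect_equal(nrow(none), 0)

  # a low-MAF SNP is excluded even when cis
  rare <- co$geno
  keep_snp <- co$truth$meqtls$snp_id[1]
  rare$dosage <- rare$dosage[keep_snp, , drop = FALSE]
  rare$dosage[1, ] <- rep(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
                          length.out = ncol(rare$dosage))
  rare$info <- rare$info[rare$info$snp_id == keep_snp, ]
  expect_warning(r2 <- scan_cis_meqtl(al$layers$meth, rare, co$manifest,
                                      al$layers$sheet))
  expect_equal(nrow(r2), 0)
})

test_that("the mediation chain discriminates planted scenarios", {
  full <- simulate_mediation(400, "full", seed = 6)
  rf <- mediation_chain(full$dosage, full$m, full$phenotype)
  expect_true(all(rf$p[1:3] < 0.05))

  direct <- simulate_mediation(400, "direct", seed = 7)
  rd <- mediation_chain(direct$dosage, direct$m, direct$phenotype)
  expect_gte(rd$p[3], 0.05)   # methylation carries no signal given SNP
  expect_false(identical(rd$label, "consistent_with_mediation"))

  # degenerate methylation is flagged, not fit
  expect_warning(rc <- mediation_chain(full$dosage, rep(1, 400),
                                       full$phenotype), "constant")
  expect_true(all(is.na(rc$p)))

  expect_error(mediation_chain(full$dosage, full$m, full$m), "binary")
})
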