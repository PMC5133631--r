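test_that("detection-based probe filtering applies the >5% rule exactly", {
  b <- tiny_beta(100, 20, 0.5)
  dp <- matrix(0, 100, 20, dimnames = dimnames(b))
  dp[1, 1:2] <- 0.5    # fails in 10% of samples -> removed
  dp[2, 1] <- 0.5      # fails in exactly 5% -> kept
  m <- methylation_matrix(b, dp)
  res <- filter_probes(m)
  expect_false("cg00000001" %in% rownames(res$meth$beta))
  expect_true("cg00000002" %in% rownames(res$meth$beta))
  expect_equal(res$report$probes_removed$detection, "cg00000001")
  # removed counts match the dimension change
  expect_equal(nrow(m$beta) - nrow(res$meth$beta),
               length(res$report$probes_removed$detection))

  # all-pass matrix is untouched; threshold boundary p = 0.01 counts as fail
  res0 <- filter_probes(methylation_matrix(b, matrix(0, 100, 20,
                                                     dimnames = dimnames(b))))
  expect_equal(dim(res0$meth$beta), dim(b))
  dpb <- dp; dpb[] <- 0; dpb[3, 1:2] <- 0.01
  expect_false("cg00000003" %in%
                 rownames(filter_probes(methylation_matrix(b, dpb))$meth$beta))

  expect_error(filter_probes(methylation_matrix(b)), "detection")
})

test_that("sample filtering applies the >5% failing-probe rule", {
  b <- tiny_beta(100, 20, 0.5)
  dp <- matrix(0, 100, 20, dimnames = dimnames(b))
  dp[1:6, 1] <- 0.5    # 6% of probes fail -> sample removed
  dp[1:5, 2] <- 0.5    # exactly 5% -> kept
  res <- filter_samples(methylation_matrix(b, dp))
  expect_false("S0001" %in% colnames(res$meth$beta))
  expect_true("S0002" %in% colnames(res$meth$beta))

  # removing everything warns rather than crashes
  dp[] <- 0.5
  expect_warning(filter_samples(methylation_matrix(b, dp)),
                 "all samples removed")
})

test_that("SNP-overlap probe removal respects the MAF threshold", {
  m <- methylation_matrix(tiny_beta(5, 3))
  res <- remove_snp_probes(m, c(cg00000001 = 0.02))
  expect_false("cg00000001" %in% rownames(res$meth$beta))
  res2 <- remove_snp_probes(m, c(cg00000001 = 0.005))
  expect_equal(dim(res2$meth$beta), c(5L, 3L))
  # boundary: MAF exactly at threshold is removed (>= rule)
  res3 <- remove_snp_probes(m, c(cg00000002 = 0.01))
  expect_false("cg00000002" %in% rownames(res3$meth$beta))
  # empty table is the identity; unknown probes warn
  expect_equal(dim(remove_snp_probes(m, numeric(0))$meth$beta), c(5L, 3L))
  expect_warning(remove_snp_probes(m, c(nope = 0.5)), "absent")
})

test_that("sex inference calls a planted bimodal X profile perfectly", {
  co <- simulate_cohort(light_config(seed = 5))
  sx <- infer_sex(co$meth$whole_blood, co$manifest, co$sheet)
  expect_true(all(sx$inferred_sex == co$sheet$sex))
  expect_false(any(sx$mismatch))

  # relabelling one male as female flags exactly that sample
  sheet2 <- co$sheet
  male <- which(sheet2$sex == "M")[1]
  sheet2$sex[male] <- "F"
  sx2 <- infer_sex(co$meth$whole_blood, co$manifest, sheet2)
  expect_equal(sx2$sample_id[sx2$mismatch], sheet2$sample_id[male])

  # degenerate: identical X profiles give no calls
  b <- tiny_beta(20, 5, 0.5)
  mf <- probe_manifest(rownames(b), "chrX", seq_len(20) * 100)
  expect_warning(res <- infer_sex(methylation_matrix(b), mf),
                 "identical")
  expect_true(all(is.na(res$inferred_sex)))

  # too few X probes is a precondition error
  mf2 <- probe_manifest(rownames(b), "chr1", seq_len(20) * 100)
  expect_error(infer_sex(methylation_matrix(b), mf2), "at least 10")
})

test_that("quantile normalization matches the hand-computed target", {
  b <- matrix(c(0.1, 0.2, 0.3, 0.2, 0.4, 0.6), 3, 2,
              dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
  qn <- quantile_normalize(methylation_matrix(b))$beta
  expect_equal(unname(qn[, 1]), c(0.15, 0.30, 0.45))
  expect_equal(unname(qn[, 2]), c(0.15, 0.30, 0.45))

  # identical columns are a fixed point; idempotence in general
  b2 <- matrix(runif(30), 10, 3,
               dimnames = list(paste0("cg", 1:10), paste0("s", 1:3)))
  b2[, 2] <- b2[, 1]; b2[, 3] <- b2[, 1]
  expect_equal(quantile_normalize(methylation_matrix(b2))$beta, b2)
  set.seed(9)
  b3 <- matrix(runif(200), 20, 10,
               dimnames = list(paste0("cg", 1:20), paste0("s", 1:10)))
  once <- quantile_normalize(methylation_matrix(b3))
  twice <- quantile_normalize(once)
  expect_equal(twice$beta, once$beta, tolerance = 1e-12)
  # all columns share a mean after normalization
  expect_equal(diff(range(colMeans(once$beta))), 0, tolerance = 1e-12)

  b3[1, 1] <- NA
  expect_error(quantile_normalize(methylation_matrix(b3)), "complete")
})

test_that("beta/M conversion is the stated closed form and inverts", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2, tolerance = 1e-4)
  expect_true(is.finite(beta_to_m(0)))
  expect_equal(beta_to_m(0), log2(1e-6 / (1 + 1e-6)))
  set.seed(4)
  b <- runif(1000, 1e-6, 1 - 1e-6)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
})
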