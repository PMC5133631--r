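test_that("fit_dmp matches a per-probe lm() oracle", {
  co <- simulate_cohort(light_config(seed = 1))
  cp <- estimate_cell_proportions(co$meth$whole_blood, co$reference)
  dmps <- fit_dmp(co$meth$whole_blood, co$sheet,
                  design_spec(cell_props = cp))
  M <- beta_to_m(co$meth$whole_blood$beta)
  for (pid in c(co$truth$dmps$probe_id[1], rownames(M)[500])) {
    oracle <- lm_probe_oracle(M[pid, ], co$sheet, cp)
    row <- dmps[dmps$probe_id == pid, ]
    expect_equal(row$coef, unname(oracle[1]), tolerance = 1e-9)
    expect_equal(row$t, unname(oracle[2]), tolerance = 1e-9)
    expect_equal(row$p, unname(oracle[3]), tolerance = 1e-9)
    # delta_beta equals the beta-scale adjusted group difference
    oracle_b <- lm_probe_oracle(co$meth$whole_blood$beta[pid, ], co$sheet,
                                cp)
    expect_equal(row$delta_beta, unname(oracle_b[1]), tolerance = 1e-9)
  }
})

test_that("planted effects reach Holm significance; nulls stay uniform", {
  co <- simulate_cohort(light_config(seed = 2, n_cases = 120,
                                     n_controls = 120))
  cp <- estimate_cell_proportions(co$meth$whole_blood, co$reference)
  dmps <- fit_dmp(co$meth$whole_blood, co$sheet,
                  design_spec(cell_props = cp))
  planted <- co$truth$dmps
  strong <- planted$probe_id[abs(planted$delta_beta) >= 0.05]
  hit <- dmps$p_holm[match(strong, dmps$probe_id)]
  expect_true(all(hit < 0.05))
  # recovered effect sizes carry the planted sign
  est <- dmps$delta_beta[match(planted$probe_id, dmps$probe_id)]
  expect_true(all(sign(est) == sign(planted$delta)))

  # null probes are calibrated: KS against uniform
  null_ids <- setdiff(dmps$probe_id,
                      c(planted$probe_id, co$truth$dmr_blocks$probe_id,
                        co$truth$meqtls$probe_id))
  ks <- suppressWarnings(ks.test(dmps$p[match(null_ids, dmps$probe_id)],
                                 "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("missing values fall back to complete-case fits", {
  co <- simulate_cohort(light_config(seed = 3))
  b <- co$meth$whole_blood$beta
  b[5, 1:4] <- NA
  meth <- methylation_matrix(b)
  dmps <- fit_dmp(meth, co$sheet)
  expect_equal(dmps$n[5], ncol(b) - 4)
  # matches lm() on the reduced data
  ok <- !is.na(b[5, ])
  sub_sheet <- co$sheet[ok, ]
  oracle <- lm_probe_oracle(beta_to_m(b[5, ok]), sub_sheet)
  expect_equal(dmps$coef[5], unname(oracle[1]), tolerance = 1e-9)
  # a probe with too few complete cases is flagged NA, not dropped
  b[6, seq_len(ncol(b) - 4)] <- NA
  dmps2 <- fit_dmp(methylation_matrix(b), co$sheet)
  expect_true(is.na(dmps2$p[6]))
  expect_equal(nrow(dmps2), nrow(b))
})

test_that("degenerate designs are rejected with named columns", {
  co <- simulate_cohort(light_config(seed = 4))
  sheet <- co$sheet
  sheet$phenotype <- "control"
  expect_error(fit_dmp(co$meth$whole_blood, sheet), "constant")
  sheet2 <- co$sheet
  sheet2$dup <- sheet2$age
  expect_error(fit_dmp(co$meth$whole_blood, sheet2,
                       design_spec(covariates = c("age", "dup"))),
               "aliased.*dup")
  expect_error(fit_dmp(co$meth$whole_blood, co$sheet,
                       design_spec(covariates = "weight")),
               "not present")
})

test_that("Holm and BH adjustments match their step formulas", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.2, "holm"), 0.2)
  expect_equal(adjust_pvalues(0.2, "bh"), 0.2)
  expect_error(adjust_pvalues(c(0.5, 1.2), "holm"), "\\[0,1\\]")
  # elementwise ordering holds on arbitrary input
  set.seed(5)
  p <- runif(200)
  expect_true(all(adjust_pvalues(p, "holm") >= adjust_pvalues(p, "bh")))
  expect_true(all(adjust_pvalues(p, "bh") >= p))
  expect_true(all(adjust_pvalues(p, "holm") <= 1))
})

test_that("empirical-Bayes moderation reproduces limma's t statistics", {
  co <- simulate_cohort(light_config(seed = 6))
  dmps <- fit_dmp(co$meth$whole_blood, co$sheet, moderated = TRUE)
  X <- cbind(1, group = as.numeric(co$sheet$phenotype != "control"),
             age = co$sheet$age, sex = as.numeric(co$sheet$sex == "M"))
  fit <- limma::eBayes(limma::lmFit(beta_to_m(co$meth$whole_blood$beta),
                                    X))
  expect_equal(dmps$t, unname(fit$t[, "group"]), tolerance = 1e-9)
})
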