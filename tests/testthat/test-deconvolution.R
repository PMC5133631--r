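make_reference <- function(K = 3, n_probes = 200, seed = 1) {
  set.seed(seed)
  R <- matrix(0.15, n_probes, K,
              dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                              paste0("cell", seq_len(K))))
  for (j in seq_len(n_probes)) R[j, (j %% K) + 1] <- 0.85
  reference_profile(R)
}

test_that("a pure reference column deconvolves to a unit vector", {
  ref <- make_reference()
  b <- ref$means[, 2, drop = FALSE]
  colnames(b) <- "S0001"
  cp <- estimate_cell_proportions(methylation_matrix(b), ref)
  expect_equal(unname(cp$proportions[1, ]), c(0, 1, 0), tolerance = 1e-6)
  expect_lt(cp$residual[1], 1e-6)
})

test_that("noisy known mixtures are recovered within MAE 0.05", {
  ref <- make_reference()
  set.seed(2)
  W <- cbind(0.5, 0.3, 0.2)[rep(1, 40), ]
  W <- W + matrix(runif(120, -0.1, 0.1), 40, 3)
  W <- W / rowSums(W)
  B <- tcrossprod(ref$means, W) + matrix(rnorm(200 * 40, 0, 0.02), 200, 40)
  B <- pmin(pmax(B, 0), 1)
  dimnames(B) <- list(rownames(ref$means), sprintf("S%04d", 1:40))
  cp <- estimate_cell_proportions(methylation_matrix(B), ref)
  expect_lt(mean(abs(cp$proportions - W)), 0.05)
  # proportions live on the simplex
  expect_true(all(cp$proportions >= 0))
  expect_equal(unname(rowSums(cp$proportions)), rep(1, 40))
})

test_that("deconvolution is equivariant to cell-type reordering", {
  ref <- make_reference()
  co <- simulate_cohort(light_config(seed = 3))
  cp1 <- estimate_cell_proportions(co$meth$whole_blood, co$reference)
  ref_perm <- reference_profile(co$reference$means[, c(3, 1, 2)])
  cp2 <- estimate_cell_proportions(co$meth$whole_blood, ref_perm)
  expect_equal(cp1$proportions, cp2$proportions[, colnames(cp1$proportions)],
               tolerance = 1e-6)
})

test_that("degenerate references warn; disjoint probe sets error", {
  ref <- make_reference()
  dup <- ref$means
  dup[, 2] <- dup[, 1]
  b <- dup[, 1, drop = FALSE]
  colnames(b) <- "S0001"
  expect_warning(
    cp <- estimate_cell_proportions(methylation_matrix(b),
                                    reference_profile(dup)),
    "collinear")
  expect_false(anyNA(cp$proportions))

  b2 <- tiny_beta(5, 2)
  rownames(b2) <- paste0("ch.", 1:5)
  expect_error(estimate_cell_proportions(methylation_matrix(b2), ref),
               "no probes shared")
})

test_that("the linear clock evaluates and recovers a planted age signal", {
  # single-probe direct evaluation
  clk <- clock_model(0, c(cg00000001 = 1))
  b <- tiny_beta(1, 1, 0.6)
  expect_equal(unname(predict_epigenetic_age(methylation_matrix(b), clk)),
               0.6)

  # generator truth: high correlation with chronological age
  co <- simulate_cohort(light_config(seed = 5, n_cases = 60,
                                     n_controls = 60))
  pred <- predict_epigenetic_age(co$meth$whole_blood, co$clock)
  expect_gt(cor(pred, co$sheet$age), 0.9)

  # missing clock probes: tolerated to 20%, refused beyond
  sub <- subset_methylation(co$meth$whole_blood,
                            probes = setdiff(rownames(co$meth$whole_blood$beta),
                                             names(co$clock$weights)[1]))
  expect_warning(p2 <- predict_epigenetic_age(sub, co$clock), "imputed")
  expect_equal(length(p2), nrow(co$sheet))
  gone <- subset_methylation(co$meth$whole_blood,
                             probes = setdiff(rownames(co$meth$whole_blood$beta),
                                              names(co$clock$weights)))
  expect_error(predict_epigenetic_age(gone, co$clock), "80%")
})

test_that("age acceleration is the mean-zero OLS residual", {
  actual <- c(20, 30, 40, 50, 60)
  expect_equal(unname(age_acceleration(actual, actual)), rep(0, 5))
  # a global shift is absorbed by the intercept
  expect_equal(unname(age_acceleration(actual + 5, actual)), rep(0, 5))
  set.seed(6)
  pred <- actual + rnorm(5)
  expect_equal(mean(age_acceleration(pred, actual)), 0, tolerance = 1e-9)
  expect_error(age_acceleration(pred, rep(40, 5)), "constant")

  # a planted +2-year group shift is recovered in the residuals
  set.seed(7)
  n <- 100
  act <- runif(2 * n, 20, 70)
  grp <- rep(c(0, 1), each = n)
  pred <- act + 2 * grp + rnorm(2 * n, 0, 1.5)
  acc <- age_acceleration(pred, act)
  expect_equal(mean(acc[grp == 1]) - mean(acc[grp == 0]), 2,
               tolerance = 0.5)
})

test_that("the QP solution beats the clipped unconstrained projection", {
  ref <- make_reference()
  co <- simulate_cohort(light_config(seed = 9))
  shared <- intersect(rownames(co$meth$whole_blood$beta),
                      rownames(co$reference$means))
  R <- co$reference$means[shared, ]
  cp <- estimate_cell_proportions(co$meth$whole_blood, co$reference)
  for (j in 1:5) {
    y <- co$meth$whole_blood$beta[shared, j]
    w_free <- solve(crossprod(R), crossprod(R, y))
    w_clip <- pmax(w_free, 0)
    if (sum(w_clip) > 0) w_clip <- w_clip / max(sum(w_clip), 1)
    obj <- function(w) sum((y - R %*% w)^2)
    expect_lte(obj(cp$raw[j, ]), obj(w_clip) + 1e-10)
  }
})
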