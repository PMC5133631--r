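# Covariate-adjusted differential methylation at single CpGs, multiple
# testing control, contiguity-based DMR calling, and the two-sample power
# calculator.

#' Specify a differential-methylation design
#'
#' @param case_levels Phenotype levels coded as cases (default all of
#'   IBD/CD/UC); remaining samples are the reference group.
#' @param covariates Sample-sheet columns entered as covariates (default
#'   age and sex).
#' @param cell_props Optional `CellProportions` whose columns (minus the
#'   reference cell type, the one with the largest mean proportion, to
#'   avoid collinearity with the intercept) enter as covariates.
#' @param scale Response scale: `"M"` (default; variance-stabilized) or
#'   `"beta"`.
#' @return Object of class `DesignSpec`.
#' @export
design_spec <- function(case_levels = c("IBD", "CD", "UC"),
                        covariates = c("age", "sex"),
                        cell_props = NULL, scale = c("M", "beta")) {
  scale <- match.arg(scale)
  structure(list(case_levels = case_levels, covariates = covariates,
                 cell_props = cell_props, scale = scale),
            class = "DesignSpec")
}

# Build the n x p design matrix for a sheet; first non-intercept column is
# the case indicator. Errors on rank deficiency, naming aliased columns.
build_design <- function(sheet, design) {
  grp <- as.numeric(sheet$phenotype %in% design$case_levels)
  if (length(unique(grp)) < 2)
    stop("group factor is constant: no contrast between cases and controls")
  X <- cbind(`(Intercept)` = 1, group = grp)
  for (cv in design$covariates) {
    if (!cv %in% colnames(sheet))
      stop("covariate '", cv, "' not present in the sample sheet")
    v <- sheet[[cv]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) < 2) next  # constant factor carries no information
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, "_", levels(f)[-1])
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, matrix(as.numeric(v), ncol = 1,
                           dimnames = list(NULL, cv)))
    }
  }
  if (!is.null(design$cell_props)) {
    W <- design$cell_props$proportions
    W <- W[match(sheet$sample_id, rownames(W)), , drop = FALSE]
    if (anyNA(W))
      stop("cell proportions missing for some sheet samples")
    ref_cell <- colnames(W)[which.max(colMeans(W))]
    W <- W[, setdiff(colnames(W), ref_cell), drop = FALSE]
    colnames(W) <- paste0("prop_", colnames(W))
    X <- cbind(X, W)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Per-probe differential methylation (DMP analysis)
#'
#' Fits, for every probe, an ordinary least-squares model of the response
#' (M-values by default) on case status plus covariates, and tests the
#' group coefficient with a two-sided t-test. The reported effect size
#' `delta_beta` is the group coefficient of the matching beta-scale model
#' — the covariate-adjusted case-minus-control difference in mean beta.
#' Probes with missing values are fitted on complete cases; probes with
#' fewer than rank+3 complete cases are returned with `NA` statistics.
#'
#' @param meth `MethylationMatrix` (QC'd; samples aligned with `sheet`).
#' @param sheet `SampleSheet` in matrix column order.
#' @param design A [design_spec()].
#' @param moderated Use limma's empirical-Bayes moderated t instead of the
#'   plain OLS t (default `FALSE`).
#' @return data.frame with probe_id, delta_beta, coef, t, p, p_holm,
#'   p_fdr, n.
#' @export
fit_dmp <- function(meth, sheet, design = design_spec(), moderated = FALSE) {
  if (!identical(colnames(meth$beta), sheet$sample_id))
    stop("matrix samples and sheet are not aligned; use align_samples()")
  X <- build_design(sheet, design)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) stop("need at least rank+3 samples")
  Y <- if (design$scale == "M") beta_to_m(meth$beta) else meth$beta
  res <- ols_group_tests(Y, X, min_n = p + 3, moderated = moderated)
  db <- ols_group_tests(meth$beta, X, min_n = p + 3)$coef
  out <- data.frame(probe_id = rownames(meth$beta),
                    delta_beta = db, coef = res$coef, t = res$t, p = res$p,
                    p_holm = adjust_pvalues(res$p, "holm"),
                    p_fdr = adjust_pvalues(res$p, "bh"),
                    n = res$n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# t-tests of the "group" column of X for every row of Y (complete-case
# per row). Fast path for rows without missing values.
ols_group_tests <- function(Y, X, min_n, moderated = FALSE) {
  g <- match("group", colnames(X))
  q <- qr(X)
  df <- nrow(X) - ncol(X)
  XtXinv_g <- chol2inv(qr.R(q))[g, g]
  complete <- !apply(is.na(Y), 1, any)
  coefs <- ts <- ps <- rep(NA_real_, nrow(Y))
  ns <- rep(NA_integer_, nrow(Y))
  if (any(complete)) {
    Yc <- Y[complete, , drop = FALSE]
    B <- t(qr.coef(q, t(Yc)))
    R <- t(qr.resid(q, t(Yc)))
    if (moderated) {
      fit <- limma::lmFit(Yc, X)
      fit <- limma::eBayes(fit)
      coefs[complete] <- fit$coefficients[, g]
      ts[complete] <- fit$t[, g]
      ps[complete] <- fit$p.value[, g]
    } else {
      s2 <- rowSums(R^2) / df
      se <- sqrt(s2 * XtXinv_g)
      coefs[complete] <- B[, g]
      ts[complete] <- B[, g] / se
      ps[complete] <- 2 * stats::pt(-abs(ts[complete]), df)
    }
    ns[complete] <- nrow(X)
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    ns[i] <- sum(ok)
    if (sum(ok) < min_n) next
    Xi <- X[ok, , drop = FALSE]
    qi <- qr(Xi)
    if (qi$rank < ncol(Xi)) next
    b <- qr.coef(qi, Y[i, ok])
    r <- qr.resid(qi, Y[i, ok])
    dfi <- sum(ok) - ncol(Xi)
    se <- sqrt(sum(r^2) / dfi * chol2inv(qr.R(qi))[g, g])
    coefs[i] <- b[g]
    ts[i] <- b[g] / se
    ps[i] <- 2 * stats::pt(-abs(ts[i]), dfi)
  }
  list(coef = coefs, t = ts, p = ps, n = ns)
}

#' Multiple-testing adjustment
#'
#' Holm step-down (family-wise error control) or Benjamini-Hochberg
#' step-up (false discovery rate control), with the adjusted values
#' returned in the input order. Thin validated wrapper over
#' `stats::p.adjust`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @param method `"holm"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "holm")
}

#' Call differentially methylated regions (DMRs)
#'
#' A DMR is a maximal run of manifest-consecutive probes in which every
#' adjacent pair lies within `max_gap_bp`, every probe attains a Holm
#' p-value below `alpha`, and all effects share one direction (a
#' `delta_beta` of exactly zero matches neither direction and breaks a
#' run). Runs of at least `min_probes` probes are reported.
#'
#' @param dmps data.frame from [fit_dmp()] (needs probe_id, delta_beta,
#'   p_holm).
#' @param manifest `ProbeManifest` covering the probes.
#' @param min_probes Minimum probes per region (default 3).
#' @param max_gap_bp Maximum adjacent-probe distance in bp (default 2000).
#' @param alpha Holm-adjusted significance threshold (default 0.05).
#' @return data.frame with chrom, start, end, span, n_probes, probe_ids
#'   (comma-separated), direction, min_p_holm, delta_beta (of the most
#'   significant probe).
#' @export
call_dmrs <- function(dmps, manifest, min_probes = 3, max_gap_bp = 2000,
                      alpha = 0.05) {
  mf <- manifest[manifest$probe_id %in% dmps$probe_id, , drop = FALSE]
  if (is.unsorted(order(mf$chrom, mf$pos))) {
    warning("manifest not sorted; sorting internally")
  }
  mf <- mf[order(mf$chrom, mf$pos, mf$probe_id, method = "radix"), ,
           drop = FALSE]
  i <- match(mf$probe_id, dmps$probe_id)
  sig <- !is.na(dmps$p_holm[i]) & dmps$p_holm[i] < alpha
  dir <- sign(dmps$delta_beta[i])
  dir[is.na(dir)] <- 0
  qualifies <- sig & dir != 0
  regions <- list()
  run <- integer(0)
  flush <- function(run) {
    if (length(run) < min_probes) return(NULL)
    ii <- i[run]
    minp <- which.min(dmps$p_holm[ii])
    data.frame(chrom = mf$chrom[run[1]],
               start = mf$pos[run[1]], end = mf$pos[run[length(run)]],
               span = mf$pos[run[length(run)]] - mf$pos[run[1]],
               n_probes = length(run),
               probe_ids = paste(mf$probe_id[run], collapse = ","),
               direction = if (dir[run[1]] > 0) "hyper" else "hypo",
               min_p_holm = dmps$p_holm[ii][minp],
               delta_beta = dmps$delta_beta[ii][minp],
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(mf))) {
    extend <- length(run) > 0 && qualifies[k] &&
      mf$chrom[k] == mf$chrom[run[length(run)]] &&
      mf$pos[k] - mf$pos[run[length(run)]] <= max_gap_bp &&
      dir[k] == dir[run[1]]
    if (extend) {
      run <- c(run, k)
    } else {
      regions[[length(regions) + 1]] <- flush(run)
      run <- if (qualifies[k]) k else integer(0)
    }
  }
  regions[[length(regions) + 1]] <- flush(run)
  regions <- regions[!vapply(regions, is.null, logical(1))]
  if (length(regions) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), span = integer(),
                      n_probes = integer(), probe_ids = character(),
                      direction = character(), min_p_holm = numeric(),
                      delta_beta = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Exact two-sample t-test power
#'
#' Power of the two-sided two-sample t-test with `n` subjects per group
#' at standardized effect size `d`, via the noncentral t distribution
#' (df `2n - 2`, noncentrality `d * sqrt(n/2)`).
#'
#' @param n Subjects per group (>= 2).
#' @param d Effect size in units of the common standard deviation (> 0
#'   for `min_n_two_group`; `d = 0` returns the test size).
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
power_two_group <- function(n, d, alpha) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

#' @rdname power_two_group
#' @param power Target power in (0, 1).
#' @return `min_n_two_group`: smallest integer `n` per group achieving
#'   the target power.
#' @export
min_n_two_group <- function(d, alpha, power) {
  stopifnot(d > 0, power > 0, power < 1)
  hi <- 2
  while (power_two_group(hi, d, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e6) stop("target power unreachable with n <= 1e6")
  }
  lo <- max(2, hi %/% 2)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (power_two_group(mid, d, alpha) >= power) hi <- mid else lo <- mid + 1
  }
  hi
}
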