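# Probe/sample quality control, sex check, normalization, scale conversion.

qc_report <- function(probes_removed = list(), samples_removed = list(),
                      thresholds = list()) {
  structure(list(probes_removed = probes_removed,
                 samples_removed = samples_removed,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (r in names(x$probes_removed))
    cat(sprintf("  probes removed (%s): %d\n", r, length(x$probes_removed[[r]])))
  for (r in names(x$samples_removed))
    cat(sprintf("  samples removed (%s): %d\n", r, length(x$samples_removed[[r]])))
  invisible(x)
}

#' Remove probes failing detection
#'
#' A probe fails in a sample when its detection p-value is at or above
#' `p_thresh`; a probe is removed when it fails in more than
#' `sample_frac` of samples. Failure in exactly `sample_frac` of samples
#' keeps the probe.
#'
#' @param meth `MethylationMatrix` with detection p-values.
#' @param p_thresh Detection p-value threshold (default 0.01).
#' @param sample_frac Tolerated failing-sample fraction (default 0.05).
#' @return List with `meth` (filtered) and `report` (a `qc_report`).
#' @export
filter_probes <- function(meth, p_thresh = 0.01, sample_frac = 0.05) {
  if (is.null(meth$detection_p))
    stop("filter_probes() requires detection p-values")
  fail_frac <- rowMeans(meth$detection_p >= p_thresh, na.rm = TRUE)
  drop <- fail_frac > sample_frac
  out <- subset_methylation(meth, probes = !drop)
  list(meth = out,
       report = qc_report(
         probes_removed = list(detection = rownames(meth$beta)[drop]),
         thresholds = list(p_thresh = p_thresh, sample_frac = sample_frac)))
}

#' Remove samples with widespread probe failure
#'
#' A sample is removed when more than `probe_frac` of its probes have a
#' detection p-value at or above `p_thresh`.
#'
#' @inheritParams filter_probes
#' @param probe_frac Tolerated failing-probe fraction (default 0.05).
#' @return List with `meth` and `report`.
#' @export
filter_samples <- function(meth, probe_frac = 0.05, p_thresh = 0.01) {
  if (is.null(meth$detection_p))
    stop("filter_samples() requires detection p-values")
  fail_frac <- colMeans(meth$detection_p >= p_thresh, na.rm = TRUE)
  drop <- fail_frac > probe_frac
  if (all(drop)) warning("all samples removed by detection-failure filter")
  out <- subset_methylation(meth, samples = !drop)
  list(meth = out,
       report = qc_report(
         samples_removed = list(failure_fraction = colnames(meth$beta)[drop]),
         thresholds = list(probe_frac = probe_frac, p_thresh = p_thresh)))
}

#' Remove probes overlapping common SNPs
#'
#' Probes listed in `snp_table` with minor allele frequency at or above
#' `maf_thresh` are removed; table entries for unknown probes are ignored
#' with a warning.
#'
#' @param meth `MethylationMatrix`.
#' @param snp_table Named numeric vector: probe id -> population MAF.
#' @param maf_thresh Removal threshold (default 0.01, i.e. MAF >= 1\%).
#' @return List with `meth` and `report`.
#' @export
remove_snp_probes <- function(meth, snp_table, maf_thresh = 0.01) {
  unknown <- setdiff(names(snp_table), rownames(meth$beta))
  if (length(unknown) > 0)
    warning("SNP table names ", length(unknown),
            " probe(s) absent from the matrix; ignored")
  hit <- names(snp_table)[snp_table >= maf_thresh]
  hit <- intersect(hit, rownames(meth$beta))
  keep <- !(rownames(meth$beta) %in% hit)
  list(meth = subset_methylation(meth, probes = keep),
       report = qc_report(probes_removed = list(snp_overlap = hit),
                          thresholds = list(maf_thresh = maf_thresh)))
}

#' Infer sample sex from X-chromosome methylation
#'
#' Computes each sample's mean X-chromosome M-value and splits samples
#' into two clusters by the exact 1-D two-cluster partition minimizing
#' within-cluster variance (scan over sorted split points). The cluster
#' with the higher mean is called female — the X-inactivation
#' intermediate-methylation convention; invert for arrays with the
#' opposite polarity.
#'
#' @param meth `MethylationMatrix`.
#' @param manifest `ProbeManifest` covering the matrix's probes.
#' @param sheet Optional `SampleSheet`; when given, mismatching samples
#'   are flagged.
#' @return data.frame with sample_id, x_mean_m, inferred_sex and (when a
#'   sheet is supplied) reported_sex and mismatch.
#' @export
infer_sex <- function(meth, manifest, sheet = NULL) {
  xp <- manifest$probe_id[manifest$chrom == "chrX"]
  xp <- intersect(xp, rownames(meth$beta))
  if (length(xp) < 10)
    stop("sex inference needs at least 10 X-chromosome probes (have ",
         length(xp), ")")
  xm <- colMeans(beta_to_m(meth$beta[xp, , drop = FALSE]), na.rm = TRUE)
  if (max(xm) - min(xm) < 1e-8) {
    warning("X-chromosome profiles are identical across samples; no sex calls")
    return(data.frame(sample_id = names(xm), x_mean_m = xm,
                      inferred_sex = NA_character_,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  cl <- split_1d_two_clusters(xm)
  hi <- which.max(c(mean(xm[cl == 1]), mean(xm[cl == 2])))
  sex <- ifelse(cl == hi, "F", "M")
  out <- data.frame(sample_id = names(xm), x_mean_m = unname(xm),
                    inferred_sex = sex, stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    out$reported_sex <- sheet$sex[match(out$sample_id, sheet$sample_id)]
    out$mismatch <- !is.na(out$reported_sex) &
      out$reported_sex != out$inferred_sex
  }
  out
}

# exact optimal 2-partition of a 1-D vector (contiguous in sorted order)
split_1d_two_clusters <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best <- Inf; best_k <- 1
  for (k in 1:(n - 1)) {
    a <- xs[1:k]; b <- xs[(k + 1):n]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best) { best <- wss; best_k <- k }
  }
  cl <- integer(n)
  cl[o] <- rep(1:2, c(best_k, n - best_k))
  cl
}

#' Quantile-normalize a methylation matrix across samples
#'
#' After normalization every sample (column) has the same sorted values:
#' the row-wise means of the column-sorted matrix, with ties receiving
#' the average. Delegates to `limma::normalizeQuantiles`. Requires a
#' complete matrix (no missing values).
#'
#' @param meth `MethylationMatrix` without missing beta values.
#' @return A quantile-normalized `MethylationMatrix`.
#' @export
quantile_normalize <- function(meth) {
  if (anyNA(meth$beta))
    stop("quantile_normalize() requires a complete matrix; ",
         "subset to complete cases first")
  qn <- limma::normalizeQuantiles(meth$beta, ties = TRUE)
  dimnames(qn) <- dimnames(meth$beta)
  methylation_matrix(qn, meth$detection_p)
}

#' Convert between beta values and M-values
#'
#' `M = log2((beta + eps) / (1 - beta + eps))`; the offset `eps` keeps
#' M finite at beta of exactly 0 or 1. `m_to_beta()` inverts the map and
#' reproduces beta within 1e-9 on `[eps, 1 - eps]`.
#'
#' @param beta Numeric vector/matrix of beta values in \[0, 1\].
#' @param eps Logit offset (default 1e-6).
#' @return Numeric object of the same shape on the M (log2-ratio) scale.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  log2((beta + eps) / (1 - beta + eps))
}

#' @rdname beta_to_m
#' @param m M-values to map back to the beta scale.
#' @export
m_to_beta <- function(m, eps = 1e-6) {
  r <- 2^m
  (r * (1 + eps) - eps) / (1 + r)
}
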