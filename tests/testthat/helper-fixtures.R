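# Shared fixtures and independent oracles, all built in code.

# tiny beta matrix with probe/sample dimnames
tiny_beta <- function(nr = 3, nc = 2, value = 0.5) {
  matrix(value, nr, nc,
         dimnames = list(sprintf("cg%08d", seq_len(nr)),
                         sprintf("S%04d", seq_len(nc))))
}

# a light cohort configuration for fast per-test simulation
light_config <- function(seed = 1, ...) {
  args <- list(n_cases = 30, n_controls = 30, n_probes = 600,
               n_x_probes = 40, n_dmp = 10, n_dmr_blocks = 2,
               n_meqtl = 3, n_snps = 60, n_genes = 30,
               n_coupled_genes = 2, n_expr_subjects = 20,
               n_clock_probes = 10, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# a null configuration: nothing planted, genotype/expression layers off
null_config <- function(seed, n_probes = 2000, n_cases = 120,
                        n_controls = 120) {
  sim_config(n_cases = n_cases, n_controls = n_controls,
             n_probes = n_probes, n_x_probes = 0, n_dmp = 0,
             n_dmr_blocks = 0, n_meqtl = 0, n_snps = 0, n_genes = 0,
             n_clock_probes = 0, detection_fail_rate = 0, seed = seed)
}

# independent DMR oracle: exhaustive enumeration of all maximal
# qualifying windows over the sorted manifest
dmr_oracle <- function(dmps, manifest, min_probes = 3, max_gap_bp = 2000,
                       alpha = 0.05) {
  mf <- manifest[manifest$probe_id %in% dmps$probe_id, , drop = FALSE]
  mf <- mf[order(mf$chrom, mf$pos, mf$probe_id, method = "radix"), ]
  idx <- match(mf$probe_id, dmps$probe_id)
  ok <- !is.na(dmps$p_holm[idx]) & dmps$p_holm[idx] < alpha
  dir <- sign(dmps$delta_beta[idx])
  dir[is.na(dir)] <- 0
  n <- nrow(mf)
  qualifies_window <- function(i, j) {
    if (any(!ok[i:j]) || any(dir[i:j] == 0)) return(FALSE)
    if (length(unique(dir[i:j])) > 1) return(FALSE)
    if (length(unique(mf$chrom[i:j])) > 1) return(FALSE)
    if (j > i && any(diff(mf$pos[i:j]) > max_gap_bp)) return(FALSE)
    TRUE
  }
  out <- character(0)
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 < min_probes) next
    if (!qualifies_window(i, j)) next
    left_ext <- i > 1 && qualifies_window(i - 1, j)
    right_ext <- j < n && qualifies_window(i, j + 1)
    if (!left_ext && !right_ext)
      out <- c(out, paste(mf$probe_id[i:j], collapse = ","))
  }
  sort(out)
}

# random DMP/manifest instance for the DMR property test
random_dmr_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:20, 1)
  chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(ii)
    cumsum(sample(c(100, 500, 1500, 2500, 4000), length(ii),
                  replace = TRUE))))
  manifest <- probe_manifest(sprintf("cg%08d", seq_len(n)), chrom, pos)
  dmps <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n)),
    delta_beta = sample(c(-0.1, -0.05, 0, 0.05, 0.1), n, replace = TRUE),
    p_holm = sample(c(0.001, 0.01, 0.2, 0.8), n, replace = TRUE),
    stringsAsFactors = FALSE)
  list(dmps = dmps, manifest = manifest)
}

# per-probe OLS oracle via stats::lm, for cross-checking fit_dmp
lm_probe_oracle <- function(y, sheet, props = NULL) {
  dat <- data.frame(y = y, group = as.numeric(sheet$phenotype != "control"),
                    age = sheet$age, sex = sheet$sex)
  if (!is.null(props)) {
    W <- props$proportions[sheet$sample_id, , drop = FALSE]
    drop_cell <- colnames(W)[which.max(colMeans(W))]
    W <- W[, setdiff(colnames(W), drop_cell), drop = FALSE]
    dat <- cbind(dat, W)
  }
  fit <- stats::lm(y ~ ., data = dat)
  summary(fit)$coefficients["group", c(1, 3, 4)]
}
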