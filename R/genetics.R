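# Genetic association statistics and integration with methylation:
# Hardy-Weinberg, Cochran-Armitage trend, two-locus LD via EM,
# cis-meQTL scanning, the causal-inference (mediation) chain, and
# permutation enrichment of DMPs near GWAS susceptibility loci.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness of fit of observed genotype counts against `p^2, 2pq, q^2`
#' with the allele frequency estimated from the counts; 1 df.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)`.
#' @return List with `counts`, `chisq`, `p` (both `NA`, with a warning,
#'   for a monomorphic marker).
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype table")
  p_hat <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p_hat %in% c(0, 1)) {
    warning("monomorphic marker; HWE test undefined")
    return(list(counts = counts, chisq = NA_real_, p = NA_real_))
  }
  expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(counts = counts, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cochran-Armitage trend test
#'
#' One-degree-of-freedom test for a dose-response association between an
#' ordered genotype (scores 0/1/2 by default) and case status:
#' `chisq = N (N Sum(w r) - R Sum(w n))^2 /
#'          [R (N - R) (N Sum(w^2 n) - (Sum(w n))^2)]`
#' with `r` case counts, `n` genotype totals, `R` total cases, `N` total
#' samples.
#'
#' @param cases,controls Integer vectors of counts per genotype class.
#' @param weights Genotype scores (default `c(0, 1, 2)`, additive).
#' @return List with `chisq`, `p` and the input counts (`NA` when the
#'   genotype distribution is degenerate).
#' @export
armitage_trend <- function(cases, controls, weights = c(0, 1, 2)) {
  stopifnot(length(cases) == length(controls),
            length(weights) == length(cases))
  r <- as.numeric(cases); nn <- r + as.numeric(controls)
  N <- sum(nn); R <- sum(r)
  if (N == 0 || R == 0 || R == N) stop("need both cases and controls")
  w <- as.numeric(weights)
  denom <- R * (N - R) * (N * sum(w^2 * nn) - sum(w * nn)^2)
  if (denom <= 0) {
    warning("degenerate genotype distribution; trend test undefined")
    return(list(cases = cases, controls = controls, chisq = NA_real_,
                p = NA_real_))
  }
  chisq <- N * (N * sum(w * r) - R * sum(w * nn))^2 / denom
  list(cases = cases, controls = controls, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Two-locus linkage disequilibrium from unphased genotypes
#'
#' Estimates the four haplotype frequencies by expectation-maximization
#' over the double-heterozygote phase ambiguity, then reports
#' `D = pAB - pA pB`, `D' = |D| / Dmax` and `r^2 = D^2 / (pA pa pB pb)`,
#' where allele "A"/"B" denote the alternate alleles of the two markers.
#'
#' @param g1,g2 Dosage vectors (0/1/2, `NA` allowed) for the two markers.
#' @param tol EM convergence tolerance on haplotype frequencies
#'   (default 1e-10).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List with `haplotypes` (pAB, pAb, paB, pab), `D`, `Dprime`,
#'   `r2`, `iterations`, `converged`, `loglik`.
#' @export
ld_pair <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 10) stop("need >= 10 samples with both genotypes")
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) {
    warning("monomorphic marker; LD undefined")
    return(list(haplotypes = rep(NA_real_, 4), D = NA_real_,
                Dprime = NA_real_, r2 = NA_real_, iterations = 0L,
                converged = NA, loglik = NA_real_))
  }
  n <- table(factor(g1, 0:2), factor(g2, 0:2))
  # phase-known haplotype counts (AB = alt/alt)
  cAB <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  cAb <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  caB <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  cab <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  ndh <- n[2, 2]  # double heterozygotes: AB/ab or Ab/aB
  tot <- 2 * sum(n)
  p <- rep(0.25, 4)  # (pAB, pAb, paB, pab)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    p_new <- c(cAB + w * ndh, cAb + (1 - w) * ndh,
               caB + (1 - w) * ndh, cab + w * ndh) / tot
    if (max(abs(p_new - p)) < tol) { p <- p_new; converged <- TRUE; break }
    p <- p_new
    if (iter >= max_iter) break
  }
  names(p) <- c("pAB", "pAb", "paB", "pab")
  ll <- ld_loglik(n, p)
  stats <- ld_stats(p)
  c(list(haplotypes = p), stats,
    list(iterations = iter, converged = converged, loglik = ll))
}

# D, D' and r2 from a haplotype frequency vector (pAB, pAb, paB, pab)
#' Closed-form LD coefficients of a haplotype distribution
#'
#' @param p Numeric vector `(pAB, pAb, paB, pab)` summing to 1.
#' @return List with `D`, `Dprime`, `r2`.
#' @export
ld_stats <- function(p) {
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  pa <- 1 - pA; pb <- 1 - pB
  D <- p[1] - pA * pB
  Dmax <- if (D >= 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  Dprime <- if (Dmax > 0) abs(D) / Dmax else NA_real_
  r2 <- if (pA * pa * pB * pb > 0) D^2 / (pA * pa * pB * pb) else NA_real_
  list(D = unname(D), Dprime = unname(Dprime), r2 = unname(r2))
}

ld_loglik <- function(n, p) {
  # genotype probabilities under random pairing of haplotypes
  P <- matrix(0, 3, 3)
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))  # alt counts per marker
  for (i in 1:4) for (j in 1:4) {
    gi <- hap[i, 1] + hap[j, 1]; gj <- hap[i, 2] + hap[j, 2]
    P[gi + 1, gj + 1] <- P[gi + 1, gj + 1] + p[i] * p[j]
  }
  keep <- n > 0
  sum(n[keep] * log(P[keep]))
}

#' Scan for cis methylation quantitative trait loci
#'
#' Tests every (probe, SNP) pair with `|pos_probe - pos_snp| <= window`
#' on the same chromosome and SNP minor allele frequency above
#' `maf_thresh`: ordinary least squares of the probe's M-values on the
#' additive dosage plus covariates, with Benjamini-Hochberg FDR across
#' all tests performed.
#'
#' @param meth `MethylationMatrix` (typically restricted to DMPs).
#' @param geno `GenotypeMatrix`, samples aligned with `meth`.
#' @param manifest `ProbeManifest` giving probe coordinates; probes
#'   without coordinates are skipped with a warning.
#' @param sheet `SampleSheet` aligned with `meth`.
#' @param window Maximum probe-SNP distance in bp (default 1e6).
#' @param maf_thresh Minimum minor allele frequency, exclusive
#'   (default 0.1).
#' @param design A [design_spec()] supplying the covariates (its group
#'   term is not used here).
#' @return data.frame with snp_id, probe_id, distance, maf, slope, t, p,
#'   p_fdr; zero rows (with a warning) when no pair is eligible.
#' @export
scan_cis_meqtl <- function(meth, geno, manifest, sheet, window = 1e6,
                           maf_thresh = 0.1, design = design_spec()) {
  if (!identical(colnames(meth$beta), sheet$sample_id) ||
      !identical(colnames(geno$dosage), sheet$sample_id))
    stop("layers are not sample-aligned; use align_samples()")
  missing_coord <- setdiff(rownames(meth$beta), manifest$probe_id)
  if (length(missing_coord) > 0)
    warning(length(missing_coord), " probe(s) lack manifest coordinates; skipped")
  mf <- manifest[match(rownames(meth$beta), manifest$probe_id), ]
  maf <- snp_maf(geno)
  snp_keep <- which(maf > maf_thresh)
  # covariate design without the group term
  X <- build_design(sheet, design)
  X <- X[, colnames(X) != "group", drop = FALSE]
  Y <- beta_to_m(meth$beta)
  rows <- list()
  for (s in snp_keep) {
    hits <- which(mf$chrom == geno$info$chrom[s] &
                    abs(mf$pos - geno$info$pos[s]) <= window)
    if (length(hits) == 0) next
    g <- geno$dosage[s, ]
    ok <- !is.na(g)
    Xo <- X[ok, , drop = FALSE]
    q <- qr(Xo)
    gt <- qr.resid(q, g[ok])
    gg <- sum(gt^2)
    if (gg < 1e-12) next  # dosage aliased with covariates
    Yr <- t(qr.resid(q, t(Y[hits, ok, drop = FALSE])))
    b <- drop(Yr %*% gt) / gg
    rss <- rowSums(Yr^2) - b^2 * gg
    df <- sum(ok) - ncol(Xo) - 1
    se <- sqrt(rss / df / gg)
    tt <- b / se
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = geno$info$snp_id[s], probe_id = mf$probe_id[hits],
      distance = abs(mf$pos[hits] - geno$info$pos[s]),
      maf = unname(maf[s]), slope = b, t = tt,
      p = 2 * stats::pt(-abs(tt), df), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("no eligible probe-SNP pairs")
    return(data.frame(snp_id = character(), probe_id = character(),
                      distance = numeric(), maf = numeric(),
                      slope = numeric(), t = numeric(), p = numeric(),
                      p_fdr = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- adjust_pvalues(out$p, "bh")
  rownames(out) <- NULL
  out
}

#' Four-criterion mediation (causal-inference) chain
#'
#' Tests whether a variant's association with a binary phenotype is
#' consistent with operating through methylation:
#' (1) phenotype ~ SNP (logistic); (2) methylation ~ SNP (linear);
#' (3) phenotype ~ methylation + SNP, methylation term (logistic);
#' (4) phenotype ~ methylation + SNP, SNP term (logistic).
#' The verdict is `consistent_with_mediation` when criteria 1-3 reject at
#' `alpha` and criterion 4 does not (genotype independent of phenotype
#' given methylation); `partial` when 1-3 reject but 4 also rejects;
#' `none` otherwise.
#'
#' @param dosage Additive genotype vector (0/1/2).
#' @param m Methylation M-values at the mediating probe.
#' @param phenotype Binary vector (0/1 or logical).
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `MediationResult`: list with `p` (p1..p4),
#'   `criteria` (logical verdicts), `label`, `alpha`, `notes`.
#' @export
mediation_chain <- function(dosage, m, phenotype, covariates = NULL,
                            alpha = 0.05) {
  phenotype <- as.numeric(phenotype)
  if (!all(phenotype %in% c(0, 1))) stop("phenotype must be binary")
  ok <- !is.na(dosage) & !is.na(m) & !is.na(phenotype)
  d <- dosage[ok]; mm <- m[ok]; y <- phenotype[ok]
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)[ok, , drop = FALSE]
  notes <- character(0)
  if (stats::var(mm) == 0) {
    warning("constant methylation vector; mediation chain undefined")
    return(structure(list(p = rep(NA_real_, 4), criteria = rep(NA, 4),
                          label = NA_character_, alpha = alpha,
                          notes = "constant methylation"),
                     class = "MediationResult"))
  }
  term_p <- function(fit, term) {
    ct <- summary(fit)$coefficients
    if (!term %in% rownames(ct)) return(NA_real_)
    ct[term, 4]
  }
  safe_glm <- function(formula, data, term) {
    p <- tryCatch({
      fit <- stats::glm(formula, data = data, family = stats::binomial())
      if (!fit$converged || any(fit$fitted.values > 1 - 1e-10) &&
          any(fit$fitted.values < 1e-10)) {
        notes <<- c(notes, paste0("possible separation in ", term, " model"))
      }
      term_p(fit, term)
    }, warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      fit <- suppressWarnings(stats::glm(formula, data = data,
                                         family = stats::binomial()))
      term_p(fit, term)
    })
    p
  }
  dat <- data.frame(y = y, d = d, m = mm)
  rhs <- if (is.null(cv)) "" else {
    colnames(cv) <- paste0("c", seq_len(ncol(cv)))
    dat <- cbind(dat, as.data.frame(cv))
    paste0(" + ", paste(colnames(cv), collapse = " + "))
  }
  p1 <- safe_glm(stats::as.formula(paste0("y ~ d", rhs)), dat, "d")
  f2 <- stats::lm(stats::as.formula(paste0("m ~ d", rhs)), data = dat)
  p2 <- term_p(f2, "d")
  p3 <- safe_glm(stats::as.formula(paste0("y ~ m + d", rhs)), dat, "m")
  p4 <- safe_glm(stats::as.formula(paste0("y ~ m + d", rhs)), dat, "d")
  p <- c(p1, p2, p3, p4)
  crit <- c(p[1] < alpha, p[2] < alpha, p[3] < alpha, p[4] >= alpha)
  label <- if (any(is.na(crit))) NA_character_
  else if (all(crit[1:3]) && crit[4]) "consistent_with_mediation"
  else if (all(crit[1:3])) "partial"
  else "none"
  structure(list(p = p, criteria = crit, label = label, alpha = alpha,
                 notes = unique(notes)),
            class = "MediationResult")
}

#' @exportS3Method base::print
print.MediationResult <- function(x, ...) {
  cat("Mediation chain (alpha =", x$alpha, ")\n")
  lbl <- c("phenotype ~ SNP", "methylation ~ SNP",
           "phenotype ~ methylation | SNP", "phenotype ~ SNP | methylation")
  for (i in 1:4)
    cat(sprintf("  %d. %-30s p = %.3g\n", i, lbl[i], x$p[i]))
  cat("  verdict:", x$label, "\n")
  invisible(x)
}

#' Enrichment of DMPs near GWAS susceptibility loci
#'
#' For each bin size, loci are extended to windows of half-width
#' `bin_size` around the locus midpoint and the number of DMPs per
#' window is compared against `n_random` random window sets drawn
#' genome-wide, each matched to the observed set in window count and
#' per-window array-probe count (within `match_tol`, rejection
#' sampling). Reports the two-sided Wilcoxon rank-sum p of observed
#' versus pooled random per-window counts, and the empirical permutation
#' p `(1 + #{sets with mean count >= observed mean}) / (n_random + 1)`.
#'
#' @param dmp_probes Character vector of significant probe ids (subset of
#'   the manifest).
#' @param manifest `ProbeManifest` of all analysed probes.
#' @param loci `LocusSet` of susceptibility loci (non-empty).
#' @param bin_sizes Window half-widths in bp (default 25/50/100/250 kb).
#' @param n_random Number of random window sets (default 1000).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param match_tol Relative probe-count matching tolerance (default 0.2).
#' @return data.frame with one row per bin size: bin_size, n_windows,
#'   observed_mean, random_mean, wilcoxon_p, empirical_p.
#' @export
gwas_proximity_enrichment <- function(dmp_probes, manifest, loci,
                                      bin_sizes = c(25e3, 50e3, 100e3, 250e3),
                                      n_random = 1000, seed = 1,
                                      match_tol = 0.2) {
  if (nrow(loci) == 0) stop("locus set is empty")
  if (!all(dmp_probes %in% manifest$probe_id))
    stop("DMP probes must be a subset of the manifest")
  loci <- loci[order(loci$chrom, loci$start, method = "radix"), , drop = FALSE]
  set.seed(seed)
  # per-chromosome sorted positions (all probes and DMPs)
  chroms <- intersect(unique(manifest$chrom), unique(loci$chrom))
  all_chroms <- unique(manifest$chrom)
  pos_by_chr <- split(manifest$pos, manifest$chrom)
  pos_by_chr <- lapply(pos_by_chr, sort)
  is_dmp <- manifest$probe_id %in% dmp_probes
  dmp_by_chr <- split(manifest$pos[is_dmp], manifest$chrom[is_dmp])
  dmp_by_chr <- lapply(dmp_by_chr, sort)
  chr_len <- vapply(pos_by_chr, max, numeric(1))
  count_in <- function(sorted, lo, hi) {
    if (is.null(sorted)) return(rep(0L, length(lo)))
    findInterval(hi, sorted) - findInterval(lo - 1, sorted)
  }
  out <- list()
  for (s in bin_sizes) {
    mid <- floor((loci$start + loci$end) / 2) + 1L  # 1-based midpoint
    lo <- mid - s; hi <- mid + s
    obs_dmp <- obs_all <- integer(nrow(loci))
    for (ch in unique(loci$chrom)) {
      sel <- loci$chrom == ch
      obs_dmp[sel] <- count_in(dmp_by_chr[[ch]], lo[sel], hi[sel])
      obs_all[sel] <- count_in(pos_by_chr[[ch]], lo[sel], hi[sel])
    }
    nw <- nrow(loci)
    # candidate random windows, probe-density matched per observed window
    pool_n <- 5000L
    matched <- NULL
    for (attempt in 1:100) {
      cand_chr <- sample(all_chroms, pool_n, replace = TRUE,
                         prob = chr_len[all_chroms] / sum(chr_len[all_chroms]))
      cand_mid <- floor(stats::runif(pool_n, 1, chr_len[cand_chr])) + 1L
      cand_all <- integer(pool_n)
      cand_dmp <- integer(pool_n)
      for (ch in all_chroms) {
        sel <- cand_chr == ch
        if (!any(sel)) next
        cand_all[sel] <- count_in(pos_by_chr[[ch]], cand_mid[sel] - s,
                                  cand_mid[sel] + s)
        cand_dmp[sel] <- count_in(dmp_by_chr[[ch]], cand_mid[sel] - s,
                                  cand_mid[sel] + s)
      }
      # exact probe-count matches keep the null calibrated (a tolerance
      # band is asymmetric under the skewed genome-wide count
      # distribution); fall back to the band only when exact candidates
      # are scarce
      matched <- lapply(seq_len(nw), function(i) {
        exact <- which(cand_all == obs_all[i])
        if (length(exact) >= 25) return(exact)
        tol <- max(match_tol * obs_all[i], 0.5)
        which(abs(cand_all - obs_all[i]) <= tol)
      })
      enough <- vapply(matched, length, integer(1)) >= 25
      if (all(enough)) break
      pool_n <- pool_n * 2L
    }
    short <- vapply(matched, length, integer(1)) < 1
    if (any(short))
      stop("probe-density matching unattainable for windows: ",
           paste(which(short), collapse = ", "))
    rand_counts <- matrix(0L, n_random, nw)
    for (i in seq_len(nw)) {
      pick <- sample(matched[[i]], n_random, replace = TRUE)
      rand_counts[, i] <- cand_dmp[pick]
    }
    rand_means <- rowMeans(rand_counts)
    emp_p <- (1 + sum(rand_means >= mean(obs_dmp))) / (n_random + 1)
    wil <- suppressWarnings(
      stats::wilcox.test(obs_dmp, as.vector(rand_counts)))
    out[[length(out) + 1]] <- data.frame(
      bin_size = s, n_windows = nw, observed_mean = mean(obs_dmp),
      random_mean = mean(rand_counts), wilcoxon_p = wil$p.value,
      empirical_p = emp_p, seed = seed)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
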