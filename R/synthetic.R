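# Synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes -- per-cell-type reference methylomes mixed by
# sample-specific proportions, case-control effects planted at designated
# CpGs and contiguous regions, additive SNP effects on methylation
# (meQTLs), two-SNP linkage disequilibrium, a linear age signal for the
# epigenetic clock, and expression negatively coupled to methylation in
# one cell type -- and records every planted effect in a truth table.

#' Configure a synthetic cohort
#'
#' Defaults describe a desk-scale blood-methylation case-control study:
#' 120 cases and 120 controls, 10,000 probes on two synthetic autosomes
#' plus a chrX panel for the sex check, three leukocyte types mixed by
#' Dirichlet proportions, and 500 SNPs. Methylation effects are planted
#' on the natural-logit scale (additive and bounded); the logit effect
#' grid `dmp_delta` induces case-control beta differences of roughly
#' 0.02-0.10 at intermediate methylation.
#'
#' @param n_cases,n_controls Subject counts.
#' @param n_probes Total probes (including chrX and special panels).
#' @param n_x_probes Probes placed on chrX for sex inference.
#' @param chrom_lengths Named autosome lengths in bp.
#' @param cell_types Mixed cell types (at least two).
#' @param dirichlet_alpha Dirichlet concentration of mixing proportions.
#' @param n_dmp Planted single-CpG case-control effects.
#' @param dmp_delta Logit-scale effect sizes, recycled across DMPs
#'   (alternating sign).
#' @param dmp_in_loci_frac Fraction of planted DMPs positioned within
#'   25 kb of a GWAS locus midpoint (creates the enrichment signal).
#' @param n_dmr_blocks,dmr_block_size,dmr_spacing_bp,dmr_delta Contiguous
#'   same-direction blocks: count, probes per block, adjacent-probe
#'   spacing (bp), logit effect.
#' @param n_snps SNP count (0 disables the genotype layer).
#' @param maf_range Range for simulated minor allele frequencies.
#' @param n_meqtl Planted cis SNP-probe pairs.
#' @param meqtl_slope Logit units of methylation per alternate allele.
#' @param meqtl_distance_bp Probe-SNP distance of planted pairs.
#' @param meqtl_case_delta Case-control logit shift also planted at the
#'   meQTL probes, making them differentially methylated positions as
#'   well (disease-associated probes under genetic control, the
#'   configuration the meQTL scan is designed around).
#' @param ld_haplotype_freqs Haplotype frequencies (pAB, pAb, paB, pab)
#'   of the planted two-SNP LD pair.
#' @param n_loci,locus_width_bp GWAS susceptibility loci in the fixture
#'   (default 163, the catalogue size for this disease).
#' @param n_genes Expression genes (0 disables the expression layer).
#' @param n_coupled_genes Genes with expression coupled to a DMP's
#'   methylation in `coupling_cell_type` only.
#' @param coupling_gamma Log2 expression lost per unit beta.
#' @param coupling_cell_type Cell type carrying the coupling.
#' @param expr_noise_sd Expression noise (log2 scale).
#' @param n_expr_subjects Subjects with expression data.
#' @param n_clock_probes Probes carrying the linear age signal.
#' @param noise_sd Per-cell-type biological noise, logit scale.
#' @param detection_fail_rate Per-entry probability of a failed
#'   detection p-value.
#' @param batch_effect Logit shift applied to the second batch.
#' @param seed Integer seed; identical configs and seeds give
#'   bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 120, n_controls = 120,
                       n_probes = 10000, n_x_probes = 60,
                       chrom_lengths = c(chr1 = 6e7, chr2 = 6e7),
                       cell_types = c("CD4", "CD8", "CD14"),
                       dirichlet_alpha = c(6, 3, 3),
                       n_dmp = 50,
                       dmp_delta = c(0.15, 0.25, 0.35, 0.45),
                       dmp_in_loci_frac = 0.8,
                       n_dmr_blocks = 5, dmr_block_size = 4,
                       dmr_spacing_bp = 500, dmr_delta = 0.35,
                       n_snps = 500, maf_range = c(0.1, 0.5),
                       n_meqtl = 10, meqtl_slope = 0.5,
                       meqtl_distance_bp = 10e3, meqtl_case_delta = 0.3,
                       ld_haplotype_freqs = c(0.30, 0.20, 0.00, 0.50),
                       n_loci = 163, locus_width_bp = 10e3,
                       n_genes = 200, n_coupled_genes = 5,
                       coupling_gamma = 4, coupling_cell_type = "CD8",
                       expr_noise_sd = 0.3, n_expr_subjects = 60,
                       n_clock_probes = 20,
                       noise_sd = 0.15, detection_fail_rate = 0.001,
                       batch_effect = 0, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_cases, n_controls, n_probes, n_x_probes, n_dmp,
              n_dmr_blocks, n_snps, n_meqtl, n_loci, n_genes)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (length(cell_types) < 2) stop("need at least two cell types")
  if (length(dirichlet_alpha) != length(cell_types))
    stop("dirichlet_alpha must match cell_types")
  if (any(ld_haplotype_freqs < 0))
    stop("haplotype frequencies must be non-negative")
  if (abs(sum(ld_haplotype_freqs) - 1) > 1e-8)
    stop("haplotype frequencies must sum to 1")
  if (n_meqtl > 0 && meqtl_distance_bp >= min(chrom_lengths))
    stop("meQTL distance exceeds chromosome length")
  if (noise_sd < 0 || detection_fail_rate < 0 || detection_fail_rate > 1)
    stop("invalid noise or detection-failure settings")
  special <- n_dmp + n_dmr_blocks * dmr_block_size + n_meqtl +
    n_clock_probes + 200 + n_x_probes
  if (n_probes < special)
    stop("n_probes too small for the requested planted panels (need >= ",
         special, ")")
  structure(cfg, class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' Simulate a full synthetic cohort
#'
#' See [sim_config()] for the generating model. Per-cell-type logit
#' methylomes are drawn around cell-type reference means with Gaussian
#' noise; whole blood is the exact proportion-weighted mixture of the
#' cell-type beta values, so with `noise_sd = 0` the mixture identity
#' holds to machine precision.
#'
#' @param config A [sim_config()].
#' @return List of class `ewas_cohort` with elements `meth` (list of
#'   `MethylationMatrix`: whole_blood plus one per cell type), `sheet`,
#'   `manifest`, `geno` (or `NULL`), `expression` (list of matrices per
#'   cell type, or `NULL`), `cell_sheet`, `loci`, `other_loci`,
#'   `reference` (deconvolution `ReferenceProfile`), `clock`
#'   (`ClockModel`), `proportions` (true mixing weights), `truth`
#'   (planted-effect tables) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_cases + cf$n_controls
  K <- length(cf$cell_types)
  subj <- sprintf("S%04d", seq_len(n))
  phenotype <- sample(rep(c("IBD", "control"), c(cf$n_cases, cf$n_controls)))
  age <- round(stats::runif(n, 18, 70), 1)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  batch <- rep(c("b1", "b2"), length.out = n)
  sheet <- sample_sheet(subj, phenotype, age, sex, batch, "whole_blood")
  case <- as.numeric(phenotype == "IBD")

  ## ---- probe layout ----------------------------------------------------
  chroms <- names(cf$chrom_lengths)
  n_ref <- 200                       # deconvolution panel
  n_auto <- cf$n_probes - cf$n_x_probes
  ids <- sprintf("cg%08d", seq_len(cf$n_probes))
  probe_chrom <- character(cf$n_probes)
  probe_pos <- integer(cf$n_probes)
  # background autosomal probes: uniform over the autosomes
  probe_chrom[1:n_auto] <- sample(chroms, n_auto, replace = TRUE,
                                  prob = cf$chrom_lengths / sum(cf$chrom_lengths))
  probe_pos[1:n_auto] <- floor(stats::runif(
    n_auto, 1, cf$chrom_lengths[probe_chrom[1:n_auto]]))
  xi <- if (cf$n_x_probes > 0) (n_auto + 1):cf$n_probes else integer(0)
  probe_chrom[xi] <- "chrX"
  probe_pos[xi] <- sort(floor(stats::runif(cf$n_x_probes, 1, 5e7)))

  # special autosomal panels claim the first probe indices
  take <- local({ nxt <- 0L; function(k) { r <- nxt + seq_len(k); nxt <<- nxt + k; r } })
  i_dmp <- take(cf$n_dmp)
  i_dmr <- take(cf$n_dmr_blocks * cf$dmr_block_size)
  i_meqtl <- take(cf$n_meqtl)
  i_clock <- take(cf$n_clock_probes)
  i_ref <- take(n_ref)

  ## ---- GWAS loci and DMP placement ------------------------------------
  # positive loci and planted DMPs live in the lower 40% of each autosome;
  # the disjoint negative-control loci live in the upper 30% of chr2
  loci_chrom <- sample(chroms, cf$n_loci, replace = TRUE)
  loci_mid <- floor(stats::runif(cf$n_loci, 1e6,
                                 0.4 * cf$chrom_lengths[loci_chrom]))
  loci <- locus_set(loci_chrom, loci_mid - cf$locus_width_bp / 2,
                    loci_mid + cf$locus_width_bp / 2,
                    paste0("ibd_locus", seq_len(cf$n_loci)))
  other_mid <- floor(stats::runif(cf$n_loci, 0.65 * cf$chrom_lengths[2],
                                  0.95 * cf$chrom_lengths[2]))
  other_loci <- locus_set(rep(chroms[2], cf$n_loci),
                          other_mid - cf$locus_width_bp / 2,
                          other_mid + cf$locus_width_bp / 2,
                          paste0("other_locus", seq_len(cf$n_loci)))
  if (cf$n_dmp > 0) {
    n_in <- round(cf$dmp_in_loci_frac * cf$n_dmp)
    pick <- sample(cf$n_loci, n_in, replace = TRUE)
    probe_chrom[i_dmp[seq_len(n_in)]] <- loci_chrom[pick]
    probe_pos[i_dmp[seq_len(n_in)]] <-
      loci_mid[pick] + floor(stats::runif(n_in, -2e4, 2e4))
    if (n_in < cf$n_dmp) {
      rest <- i_dmp[(n_in + 1):cf$n_dmp]
      probe_chrom[rest] <- sample(chroms, length(rest), replace = TRUE)
      probe_pos[rest] <- floor(stats::runif(
        length(rest), 0.45 * cf$chrom_lengths[probe_chrom[rest]],
        0.6 * cf$chrom_lengths[probe_chrom[rest]]))
    }
  }
  # DMR blocks: tight clusters in the middle band of a random autosome;
  # background probes are evicted from each block's span afterwards so a
  # stray probe cannot break the planted run's manifest contiguity
  if (cf$n_dmr_blocks > 0) {
    excl <- vector("list", cf$n_dmr_blocks)
    for (b in seq_len(cf$n_dmr_blocks)) {
      ch <- sample(chroms, 1)
      start <- floor(stats::runif(1, 0.45 * cf$chrom_lengths[ch],
                                  0.6 * cf$chrom_lengths[ch]))
      idx <- i_dmr[(b - 1) * cf$dmr_block_size + seq_len(cf$dmr_block_size)]
      probe_chrom[idx] <- ch
      probe_pos[idx] <- start + (seq_along(idx) - 1L) * cf$dmr_spacing_bp
      excl[[b]] <- c(ch, start - cf$dmr_spacing_bp,
                     max(probe_pos[idx]) + cf$dmr_spacing_bp)
    }
    bg <- setdiff(seq_len(n_auto), c(i_dmp, i_dmr, i_meqtl, i_clock, i_ref))
    in_any_zone <- function(ii) {
      hit <- rep(FALSE, length(ii))
      for (e in excl)
        hit <- hit | (probe_chrom[ii] == e[1] &
                        probe_pos[ii] >= as.numeric(e[2]) &
                        probe_pos[ii] <= as.numeric(e[3]))
      hit
    }
    for (tries in 1:100) {
      inside <- bg[in_any_zone(bg)]
      if (length(inside) == 0) break
      probe_pos[inside] <- floor(stats::runif(
        length(inside), 1, cf$chrom_lengths[probe_chrom[inside]]))
    }
  }
  # meQTL probes in the middle band, each with a partner SNP nearby
  if (cf$n_meqtl > 0) {
    probe_chrom[i_meqtl] <- sample(chroms, cf$n_meqtl, replace = TRUE)
    probe_pos[i_meqtl] <- floor(stats::runif(
      cf$n_meqtl, 0.45 * cf$chrom_lengths[probe_chrom[i_meqtl]],
      0.6 * cf$chrom_lengths[probe_chrom[i_meqtl]]))
  }
  probe_pos <- as.integer(pmax(probe_pos, 1L))
  manifest <- probe_manifest(ids, probe_chrom, probe_pos,
                             gene = "", feature = "IGR")

  ## ---- reference methylomes and planted effects (logit scale) ---------
  # baseline logit means per probe, shared across cell types, plus
  # cell-type-specific separation at the deconvolution panel
  base <- stats::qnorm(stats::runif(cf$n_probes, 0.02, 0.98))  # spread in logit
  ref <- matrix(rep(base, K), cf$n_probes, K,
                dimnames = list(ids, cf$cell_types))
  panel_cell <- rep(seq_len(K), length.out = n_ref)
  for (j in seq_len(n_ref)) {
    ref[i_ref[j], ] <- stats::qlogis(0.15)
    ref[i_ref[j], panel_cell[j]] <- stats::qlogis(0.85)
  }
  ref[i_meqtl, ] <- 0        # beta 0.5: keeps the slope linear on M scale
  ref[i_dmp, ] <- stats::qlogis(stats::runif(cf$n_dmp, 0.35, 0.65))
  ref[i_dmr, ] <- stats::qlogis(stats::runif(length(i_dmr), 0.35, 0.65))

  delta_dmp <- if (cf$n_dmp > 0)
    rep(cf$dmp_delta, length.out = cf$n_dmp) *
      rep(c(-1, 1), length.out = cf$n_dmp) else numeric(0)
  delta_dmr <- if (cf$n_dmr_blocks > 0)
    rep(cf$dmr_delta * rep(c(-1, 1), length.out = cf$n_dmr_blocks),
        each = cf$dmr_block_size) else numeric(0)

  ## ---- genotypes -------------------------------------------------------
  geno <- NULL
  meqtl_truth <- NULL
  ld_ids <- character(0)
  if (cf$n_snps > 0) {
    snp_ids <- sprintf("rs%06d", seq_len(cf$n_snps))
    snp_chrom <- sample(chroms, cf$n_snps, replace = TRUE)
    snp_pos <- floor(stats::runif(cf$n_snps, 1,
                                  cf$chrom_lengths[snp_chrom]))
    maf <- stats::runif(cf$n_snps, cf$maf_range[1], cf$maf_range[2])
    dos <- matrix(stats::rbinom(cf$n_snps * n, 2, rep(maf, n)),
                  cf$n_snps, n, dimnames = list(snp_ids, subj))
    if (cf$n_meqtl > 0) {
      # partner SNPs sit meqtl_distance_bp from their probes
      snp_chrom[seq_len(cf$n_meqtl)] <- probe_chrom[i_meqtl]
      snp_pos[seq_len(cf$n_meqtl)] <-
        probe_pos[i_meqtl] + cf$meqtl_distance_bp
      meqtl_truth <- data.frame(
        snp_id = snp_ids[seq_len(cf$n_meqtl)],
        probe_id = ids[i_meqtl], slope = cf$meqtl_slope,
        distance = cf$meqtl_distance_bp,
        case_delta = cf$meqtl_case_delta * rep(c(-1, 1),
                                               length.out = cf$n_meqtl),
        stringsAsFactors = FALSE)
    }
    if (sum(cf$ld_haplotype_freqs > 0) > 1 && cf$n_snps >= cf$n_meqtl + 2) {
      ld_idx <- cf$n_meqtl + 1:2
      ld <- simulate_ld_genotypes(cf$ld_haplotype_freqs, n)
      dos[ld_idx, ] <- ld$dosage
      snp_chrom[ld_idx] <- chroms[1]
      snp_pos[ld_idx] <- c(1e6, 1e6 + 13072)
      ld_ids <- snp_ids[ld_idx]
    }
    geno <- genotype_matrix(dos, snp_chrom, as.integer(snp_pos),
                            ref = "A", alt = "G")
  }

  ## ---- cell-type methylomes and whole-blood mixture --------------------
  W <- rdirichlet(n, cf$dirichlet_alpha)
  dimnames(W) <- list(subj, cf$cell_types)
  clock_b0 <- 0.2; clock_b1 <- 0.006
  cell_beta <- vector("list", K)
  names(cell_beta) <- cf$cell_types
  for (k in seq_len(K)) {
    L <- matrix(ref[, k], cf$n_probes, n)
    if (cf$n_dmp > 0)
      L[i_dmp, ] <- L[i_dmp, ] + outer(delta_dmp, case)
    if (length(i_dmr) > 0)
      L[i_dmr, ] <- L[i_dmr, ] + outer(delta_dmr, case)
    if (!is.null(meqtl_truth))
      L[i_meqtl, ] <- L[i_meqtl, ] +
        cf$meqtl_slope * geno$dosage[meqtl_truth$snp_id, , drop = FALSE]
    if (!is.null(meqtl_truth) && cf$meqtl_case_delta != 0)
      L[i_meqtl, ] <- L[i_meqtl, ] +
        outer(rep(cf$meqtl_case_delta * c(-1, 1),
                  length.out = cf$n_meqtl), case)
    if (cf$n_clock_probes > 0)
      L[i_clock, ] <- matrix(stats::qlogis(clip01(clock_b0 + clock_b1 * age)),
                             cf$n_clock_probes, n, byrow = TRUE)
    if (cf$n_x_probes > 0)
      L[xi, ] <- matrix(stats::qlogis(ifelse(sex == "F", 2 / 3, 1 / 3)),
                        cf$n_x_probes, n, byrow = TRUE)
    if (cf$batch_effect != 0)
      L <- L + matrix(ifelse(batch == "b2", cf$batch_effect, 0),
                      cf$n_probes, n, byrow = TRUE)
    if (cf$noise_sd > 0)
      L <- L + matrix(stats::rnorm(cf$n_probes * n, 0, cf$noise_sd),
                      cf$n_probes, n)
    B <- stats::plogis(L)
    dimnames(B) <- list(ids, subj)
    cell_beta[[k]] <- B
  }
  wb <- Reduce(`+`, lapply(seq_len(K), function(k)
    cell_beta[[k]] * matrix(W[, k], cf$n_probes, n, byrow = TRUE)))
  detp <- matrix(stats::runif(cf$n_probes * n, 0, 0.005), cf$n_probes, n,
                 dimnames = list(ids, subj))
  if (cf$detection_fail_rate > 0) {
    fail <- stats::runif(cf$n_probes * n) < cf$detection_fail_rate
    detp[fail] <- stats::runif(sum(fail), 0.01, 1)
  }
  meth <- c(list(whole_blood = methylation_matrix(wb, detp)),
            lapply(cell_beta, methylation_matrix))

  ## ---- deconvolution reference and clock --------------------------------
  ref_profile <- reference_profile(stats::plogis(ref[i_ref, , drop = FALSE]))
  clock <- NULL
  if (cf$n_clock_probes > 0) {
    wts <- stats::setNames(rep(1 / (cf$n_clock_probes * clock_b1),
                               cf$n_clock_probes), ids[i_clock])
    clock <- clock_model(intercept = -clock_b0 / clock_b1, weights = wts)
  }

  ## ---- expression -------------------------------------------------------
  expression <- NULL
  coupling_truth <- NULL
  expr_subj <- subj[seq_len(min(cf$n_expr_subjects, n))]
  if (cf$n_genes > 0) {
    gene_ids <- sprintf("ILMN_%06d", seq_len(cf$n_genes))
    baseline <- stats::rnorm(cf$n_genes, 8, 1)
    n_c <- min(cf$n_coupled_genes, cf$n_genes, cf$n_dmp)
    expression <- list()
    cell_names <- c("whole_blood", cf$cell_types)
    for (ct in cell_names) {
      E <- matrix(baseline, cf$n_genes, length(expr_subj),
                  dimnames = list(gene_ids, expr_subj)) +
        matrix(stats::rnorm(cf$n_genes * length(expr_subj), 0,
                            cf$expr_noise_sd),
               cf$n_genes, length(expr_subj))
      if (n_c > 0 && ct == cf$coupling_cell_type) {
        bsrc <- cell_beta[[ct]][ids[i_dmp[seq_len(n_c)]], expr_subj,
                                drop = FALSE]
        E[seq_len(n_c), ] <- E[seq_len(n_c), ] - cf$coupling_gamma * bsrc
      }
      expression[[ct]] <- E
    }
    if (n_c > 0)
      coupling_truth <- data.frame(
        gene_probe_id = gene_ids[seq_len(n_c)],
        probe_id = ids[i_dmp[seq_len(n_c)]],
        gamma = cf$coupling_gamma, cell_type = cf$coupling_cell_type,
        stringsAsFactors = FALSE)
  }
  cell_sheet <- do.call(rbind, lapply(c("whole_blood", cf$cell_types),
    function(ct) {
      s <- sheet[match(expr_subj, sheet$sample_id), , drop = FALSE]
      s$cell_type <- ct
      s$subject_id <- s$sample_id
      s$sample_id <- paste0(s$sample_id, ".", ct)
      s
    }))
  rownames(cell_sheet) <- NULL
  class(cell_sheet) <- class(sheet)

  ## ---- truth table ------------------------------------------------------
  truth <- list(
    dmps = if (cf$n_dmp > 0) data.frame(
      probe_id = ids[i_dmp], delta = delta_dmp,
      delta_beta = stats::plogis(ref[i_dmp, 1] + delta_dmp) -
        stats::plogis(ref[i_dmp, 1]),
      in_locus = seq_len(cf$n_dmp) <= round(cf$dmp_in_loci_frac * cf$n_dmp),
      stringsAsFactors = FALSE) else NULL,
    dmr_blocks = if (cf$n_dmr_blocks > 0) data.frame(
      block = rep(seq_len(cf$n_dmr_blocks), each = cf$dmr_block_size),
      probe_id = ids[i_dmr], delta = delta_dmr,
      stringsAsFactors = FALSE) else NULL,
    meqtls = meqtl_truth,
    ld_snp_ids = ld_ids,
    ld_expected = if (length(ld_ids) == 2)
      ld_stats(cf$ld_haplotype_freqs) else NULL,
    couplings = coupling_truth,
    clock_probes = if (cf$n_clock_probes > 0) ids[i_clock] else character(0),
    ref_probes = ids[i_ref])

  structure(list(meth = meth, sheet = sheet, manifest = manifest,
                 geno = geno, expression = expression,
                 cell_sheet = cell_sheet, loci = loci,
                 other_loci = other_loci, reference = ref_profile,
                 clock = clock, proportions = W, truth = truth,
                 config = cf),
            class = "ewas_cohort")
}

#' @exportS3Method base::print
print.ewas_cohort <- function(x, ...) {
  cat(sprintf("ewas_cohort: %d samples (%d cases), %d probes, %d SNPs\n",
              nrow(x$sheet), sum(x$sheet$phenotype != "control"),
              nrow(x$manifest),
              if (is.null(x$geno)) 0L else nrow(x$geno$dosage)))
  invisible(x)
}

#' Simulate two SNPs with a specified haplotype distribution
#'
#' Each sample receives two haplotypes drawn i.i.d. from the four-class
#' distribution `(pAB, pAb, paB, pab)` ("A"/"B" = alternate alleles);
#' unphased dosages are returned. The population D', r-squared of the
#' generating distribution are available in closed form via
#' [ld_stats()].
#'
#' @param haplotype_freqs Numeric vector of four frequencies summing
#'   to 1.
#' @param n_samples Number of diploid samples.
#' @param seed Optional integer seed.
#' @return List with `dosage` (2 x n matrix, rows snp1/snp2) and
#'   `expected` (the closed-form `ld_stats`).
#' @export
simulate_ld_genotypes <- function(haplotype_freqs, n_samples, seed = NULL) {
  if (any(haplotype_freqs < 0)) stop("negative haplotype frequency")
  if (abs(sum(haplotype_freqs) - 1) > 1e-8)
    stop("haplotype frequencies must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  h1 <- sample(4, n_samples, replace = TRUE, prob = haplotype_freqs)
  h2 <- sample(4, n_samples, replace = TRUE, prob = haplotype_freqs)
  dosage <- rbind(snp1 = hap[h1, 1] + hap[h2, 1],
                  snp2 = hap[h1, 2] + hap[h2, 2])
  colnames(dosage) <- sprintf("S%04d", seq_len(n_samples))
  list(dosage = dosage, expected = ld_stats(haplotype_freqs))
}

#' Simulate a genotype-methylation-phenotype mediation scenario
#'
#' Scenario `"full"`: the SNP shifts methylation and the phenotype is
#' sampled from a logistic model on methylation only (SNP affects
#' disease exclusively through methylation). Scenario `"direct"`: the
#' SNP acts on the phenotype directly and methylation is independent
#' noise. Scenario `"none"`: no associations. Coefficient defaults give
#' the marginal criteria of [mediation_chain()] high power at n = 400.
#'
#' @param n Samples (default 400).
#' @param scenario `"full"`, `"direct"` or `"none"`.
#' @param maf Minor allele frequency of the SNP.
#' @param b_snp_meth Methylation (M-value) shift per alternate allele.
#' @param b_meth_pheno Log-odds of disease per M-value unit.
#' @param b_snp_pheno Log-odds per allele (direct scenario).
#' @param noise_sd Methylation residual standard deviation.
#' @param seed Optional integer seed.
#' @return List with `dosage`, `m`, `phenotype`, `scenario`.
#' @export
simulate_mediation <- function(n = 400,
                               scenario = c("full", "direct", "none"),
                               maf = 0.3, b_snp_meth = 0.8,
                               b_meth_pheno = 1.5, b_snp_pheno = 0.8,
                               noise_sd = 0.5, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rbinom(n, 2, maf)
  if (scenario == "full") {
    m <- b_snp_meth * g + stats::rnorm(n, 0, noise_sd)
    eta <- b_meth_pheno * (m - b_snp_meth * 2 * maf)
  } else if (scenario == "direct") {
    m <- stats::rnorm(n, 0, noise_sd)
    eta <- b_snp_pheno * (g - 2 * maf)
  } else {
    m <- stats::rnorm(n, 0, noise_sd)
    eta <- rep(0, n)
  }
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(dosage = g, m = m, phenotype = y, scenario = scenario)
}

#' Write a cohort's data layers to a directory
#'
#' Emits the formats the readers consume: beta and detection-p TSVs per
#' methylation layer, a sample-sheet CSV, a manifest TSV, genotypes as
#' both minimal VCF and dosage TSV, expression TSVs, BED locus files,
#' truth tables as TSV, and a `MANIFEST.txt` listing every file with its
#' MD5 checksum.
#'
#' @param cohort An `ewas_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
write_cohort <- function(cohort, dir) {
  if (nrow(cohort$sheet) == 0) stop("refusing to write an empty cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  files <- character(0)
  emit <- function(fun, obj, name, ...) {
    path <- file.path(dir, name)
    fun(obj, path, ...)
    files <<- c(files, path)
  }
  for (layer in names(cohort$meth)) {
    path <- file.path(dir, paste0("beta_", layer, ".tsv"))
    dpath <- if (is.null(cohort$meth[[layer]]$detection_p)) NULL else
      file.path(dir, paste0("detp_", layer, ".tsv"))
    write_methylation(cohort$meth[[layer]], path, dpath)
    files <- c(files, path, dpath)
  }
  emit(write_sample_sheet, cohort$sheet, "samples.csv")
  emit(write_sample_sheet, cohort$cell_sheet, "cell_samples.csv")
  emit(write_manifest, cohort$manifest, "manifest.tsv")
  if (!is.null(cohort$geno)) {
    emit(write_genotypes, cohort$geno, "genotypes.vcf")
    emit(write_genotypes, cohort$geno, "genotypes.tsv")
  }
  if (!is.null(cohort$expression))
    for (ct in names(cohort$expression))
      emit(write_expression, cohort$expression[[ct]],
           paste0("expression_", ct, ".tsv"))
  emit(write_loci, cohort$loci, "ibd_loci.bed")
  emit(write_loci, cohort$other_loci, "other_disease_loci.bed")
  for (nm in c("dmps", "dmr_blocks", "meqtls", "couplings")) {
    tt <- cohort$truth[[nm]]
    if (is.null(tt)) next
    path <- file.path(dir, paste0("truth_", nm, ".tsv"))
    utils::write.table(tt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, path)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "MANIFEST.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Verify a written cohort against its checksum manifest
#'
#' @param dir Directory written by [write_cohort()].
#' @return `TRUE` if every listed file matches its MD5; otherwise errors.
#' @export
verify_cohort_checksums <- function(dir) {
  mf <- utils::read.delim(file.path(dir, "MANIFEST.txt"),
                          stringsAsFactors = FALSE)
  now <- unname(tools::md5sum(file.path(dir, mf$file)))
  bad <- mf$file[now != mf$md5 | is.na(now)]
  if (length(bad) > 0)
    stop("checksum mismatch for: ", paste(bad, collapse = ", "))
  TRUE
}
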