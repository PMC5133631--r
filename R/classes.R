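#' Construct a methylation matrix
#'
#' Container for a probe-by-sample matrix of beta values (ratio of
#' methylated to total probe intensity, in \[0, 1\]) with an optional
#' matched matrix of detection p-values. Probes are rows, samples are
#' columns (the 450K convention); a heuristic shape check rejects input
#' that looks transposed.
#'
#' @param beta Numeric matrix of beta values with probe rownames and
#'   sample colnames. Values must lie in \[0, 1\] or be `NA`.
#' @param detection_p Optional numeric matrix of detection p-values with
#'   the same dimensions and dimnames as `beta`.
#' @return An object of class `MethylationMatrix`: a list with elements
#'   `beta` and `detection_p`.
#' @export
methylation_matrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("`beta` must be a numeric matrix")
  if ((nrow(beta) > 0 && is.null(rownames(beta))) ||
      (ncol(beta) > 0 && is.null(colnames(beta))))
    stop("`beta` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (%.4g)",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, , drop = FALSE]]))
  }
  # transposition guard: sample headers should not look like CpG probe ids
  probe_like <- grepl("^(cg|ch\\.)", colnames(beta))
  if (ncol(beta) > 0 && mean(probe_like) > 0.5)
    stop("more than half of the column names look like probe ids; ",
         "the matrix appears transposed (expected probes as rows)")
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p dimensions do not match beta")
    if (!identical(dimnames(detection_p), dimnames(beta)))
      stop("detection_p dimnames do not match beta")
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1)))
      stop("detection p-values must lie in [0,1]")
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "MethylationMatrix")
}

#' @exportS3Method base::print
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "" else " (with detection p-values)"))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$beta)

probe_ids <- function(x) UseMethod("probe_ids")
#' @export
probe_ids.MethylationMatrix <- function(x) rownames(x$beta)

#' Subset a methylation matrix by probes and/or samples
#'
#' @param x A `MethylationMatrix`.
#' @param probes,samples Character or logical index vectors; `NULL` keeps all.
#' @return A `MethylationMatrix` restricted to the requested rows/columns.
#' @export
subset_methylation <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "MethylationMatrix"))
  if (is.null(probes)) probes <- seq_len(nrow(x$beta))
  if (is.null(samples)) samples <- seq_len(ncol(x$beta))
  dp <- if (is.null(x$detection_p)) NULL else
    x$detection_p[probes, samples, drop = FALSE]
  methylation_matrix(x$beta[probes, samples, drop = FALSE], dp)
}

#' Construct a probe manifest
#'
#' Per-probe genomic annotation: chromosome, 1-based position, gene
#' symbol (may be empty), feature class and CpG-island relation.
#' Chromosome names are normalized to the "chr"-prefixed form and rows
#' are sorted by (chrom, pos) with a stable order.
#'
#' @param probe_id,chrom,pos,gene,feature,island_relation Vectors of equal
#'   length; `gene` and `island_relation` default to empty strings.
#' @return A `data.frame` with class `ProbeManifest` prepended, sorted by
#'   (chrom, pos).
#' @export
probe_manifest <- function(probe_id, chrom, pos, gene = "", feature = "IGR",
                           island_relation = "") {
  if (anyDuplicated(probe_id)) stop("duplicate probe ids in manifest")
  if (any(pos < 1)) stop("manifest positions must be >= 1 (1-based)")
  feats <- c("TSS1500", "TSS200", "5'UTR", "Body", "3'UTR", "IGR")
  if (!all(feature %in% feats))
    stop("unknown feature class: ", paste(setdiff(feature, feats), collapse = ", "))
  mf <- data.frame(probe_id = as.character(probe_id),
                   chrom = normalize_chrom(chrom),
                   pos = as.integer(pos),
                   gene = as.character(gene),
                   feature = as.character(feature),
                   island_relation = as.character(island_relation),
                   stringsAsFactors = FALSE)
  mf <- mf[order(mf$chrom, mf$pos, mf$probe_id, method = "radix"), , drop = FALSE]
  rownames(mf) <- NULL
  class(mf) <- c("ProbeManifest", "data.frame")
  mf
}

normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Construct a sample sheet
#'
#' @param sample_id Unique sample identifiers.
#' @param phenotype One of `"IBD"`, `"CD"`, `"UC"`, `"control"`.
#' @param age Age in years (non-negative).
#' @param sex `"M"` or `"F"`.
#' @param batch Batch label.
#' @param cell_type One of `"whole_blood"`, `"CD4"`, `"CD8"`, `"CD14"`.
#' @param ... Further per-sample columns (e.g. smoking, CRP) recycled to
#'   length `length(sample_id)`.
#' @return A `data.frame` with class `SampleSheet` prepended.
#' @export
sample_sheet <- function(sample_id, phenotype, age, sex,
                         batch = "b1", cell_type = "whole_blood", ...) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in sample sheet")
  if (any(age < 0)) stop("age must be non-negative")
  if (!all(phenotype %in% c("IBD", "CD", "UC", "control")))
    stop("phenotype must be one of IBD, CD, UC, control")
  if (!all(sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(cell_type %in% c("whole_blood", "CD4", "CD8", "CD14")))
    stop("cell_type must be one of whole_blood, CD4, CD8, CD14")
  sh <- data.frame(sample_id = as.character(sample_id),
                   phenotype = as.character(phenotype),
                   age = as.numeric(age), sex = as.character(sex),
                   batch = as.character(batch),
                   cell_type = as.character(cell_type),
                   ..., stringsAsFactors = FALSE)
  class(sh) <- c("SampleSheet", "data.frame")
  sh
}

#' Construct a genotype matrix
#'
#' SNP-by-sample additive dosages (count of alternate alleles, 0/1/2 or
#' `NA`) with per-SNP coordinates and allele labels.
#'
#' @param dosage Integer matrix (SNP rows, sample columns) with values in
#'   \{0, 1, 2, NA\}; rownames are SNP ids, colnames sample ids.
#' @param chrom,pos,ref,alt Per-SNP chromosome, 1-based position and
#'   reference/alternate allele, parallel to `rownames(dosage)`.
#' @return An object of class `GenotypeMatrix`: list with `dosage` and an
#'   `info` data.frame (snp_id, chrom, pos, ref, alt).
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref, alt) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("`dosage` must have SNP rownames and sample colnames")
  if (anyDuplicated(rownames(dosage))) stop("duplicate SNP ids")
  if (any(!is.na(dosage) & !dosage %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (length(chrom) != nrow(dosage) || length(pos) != nrow(dosage))
    stop("chrom/pos length must match the number of SNPs")
  info <- data.frame(snp_id = rownames(dosage),
                     chrom = normalize_chrom(chrom), pos = as.integer(pos),
                     ref = as.character(ref), alt = as.character(alt),
                     stringsAsFactors = FALSE)
  structure(list(dosage = dosage, info = info), class = "GenotypeMatrix")
}

#' @exportS3Method base::print
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Per-SNP minor allele frequency
#'
#' `min(f, 1 - f)` where `f` is the alternate-allele frequency
#' `mean(dosage)/2` over non-missing genotypes.
#'
#' @param geno A `GenotypeMatrix`.
#' @return Named numeric vector of MAFs.
#' @export
snp_maf <- function(geno) {
  f <- rowMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Construct a locus set
#'
#' Genomic intervals in 0-based half-open (BED) coordinates, e.g. GWAS
#' susceptibility loci. Records are sorted by (chrom, start); overlapping
#' records are preserved, not merged.
#'
#' @param chrom,start,end,name Parallel vectors; `start < end` required.
#' @return A `data.frame` with class `LocusSet` prepended.
#' @export
locus_set <- function(chrom, start, end, name = NULL) {
  if (any(start >= end))
    stop("locus with start >= end (0-based half-open intervals required)")
  if (any(start < 0)) stop("locus start must be >= 0")
  if (is.null(name)) name <- paste0("locus", seq_along(chrom))
  ls <- data.frame(chrom = normalize_chrom(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name), stringsAsFactors = FALSE)
  ls <- ls[order(ls$chrom, ls$start, method = "radix"), , drop = FALSE]
  rownames(ls) <- NULL
  class(ls) <- c("LocusSet", "data.frame")
  ls
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' `bed_to_genomic()` maps BED records (0-based half-open) to 1-based
#' inclusive coordinates; `genomic_to_bed()` is its inverse. The two are
#' exact inverses on any record.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
bed_to_genomic <- function(start, end) list(start = start + 1L, end = end)

#' @rdname bed_to_genomic
#' @export
genomic_to_bed <- function(start, end) list(start = start - 1L, end = end)
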