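#' Read a probe-by-sample methylation matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe ids;
#' remaining cells are beta values in \[0, 1\] or `NA`. Non-numeric cells
#' and out-of-range values are rejected with the offending probe and
#' sample named.
#'
#' @param path TSV file of beta values.
#' @param detection_path Optional TSV of detection p-values with the same
#'   layout and dimnames.
#' @return A [methylation_matrix()].
#' @export
read_methylation <- function(path, detection_path = NULL) {
  beta <- read_numeric_tsv(path, what = "beta value", lo = 0, hi = 1)
  dp <- NULL
  if (!is.null(detection_path))
    dp <- read_numeric_tsv(detection_path, what = "detection p-value",
                           lo = 0, hi = 1)
  methylation_matrix(beta, dp)
}

read_numeric_tsv <- function(path, what, lo = -Inf, hi = Inf) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate row ids in %s", path))
  if (anyDuplicated(colnames(df)[-1]))
    stop(sprintf("duplicate column ids in %s", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  bad <- which(is.na(num) & !is.na(m) & !(m %in% c("NA", "", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric %s '%s' at probe '%s', sample '%s' in %s",
                 what, m[bad[1, , drop = FALSE]], ids[bad[1, 1]],
                 colnames(m)[bad[1, 2]], path))
  oob <- which(!is.na(num) & (num < lo | num > hi), arr.ind = TRUE)
  if (nrow(oob) > 0)
    stop(sprintf("%s %s out of [%g,%g] at probe '%s', sample '%s' in %s",
                 what, m[oob[1, , drop = FALSE]], lo, hi, ids[oob[1, 1]],
                 colnames(m)[oob[1, 2]], path))
  dimnames(num) <- list(ids, colnames(m))
  num
}

#' Write a methylation matrix (and optional detection p-values) to TSV
#'
#' @param meth A `MethylationMatrix`.
#' @param path Output TSV path for beta values.
#' @param detection_path Optional output path for detection p-values.
#' @return Invisibly, the paths written.
#' @export
write_methylation <- function(meth, path, detection_path = NULL) {
  write_numeric_tsv(meth$beta, path)
  if (!is.null(detection_path)) {
    if (is.null(meth$detection_p))
      stop("no detection p-values to write")
    write_numeric_tsv(meth$detection_p, detection_path)
  }
  invisible(c(path, detection_path))
}

write_numeric_tsv <- function(m, path, digits = 15) {
  df <- data.frame(id = rownames(m),
                   format(m, digits = digits, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- "probe_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read genotypes from a minimal VCF or a TSV dosage file
#'
#' VCF input (`*.vcf`) must be v4.x with a GT field and diploid calls;
#' `0/0`, `0/1` (or `1/0`), `1/1` and `./.` map to dosages 0, 1, 2 and
#' `NA`. Multi-allelic records are rejected. TSV input has columns
#' `snp_id, chrom, pos, ref, alt` followed by one column per sample with
#' values in \{0, 1, 2, NA\}.
#'
#' @param path Input file; format chosen by extension (`.vcf` vs other).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotypes_vcf(path)
  else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF record at ",
         paste(fix[grepl(",", alt), "ID"][1]), " (unsupported)")
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF record without GT in FORMAT")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    d <- rep(NA_integer_, length(g))
    d[g == "0/0"] <- 0L
    d[g %in% c("0/1", "1/0")] <- 1L
    d[g == "1/1"] <- 2L
    bad <- !is.na(g) & !g %in% c("0/0", "0/1", "1/0", "1/1", "./.")
    if (any(bad)) stop("unsupported genotype call: ", g[bad][1])
    d
  }
  dos <- apply(gt, 2, code)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt))
  dimnames(dos) <- list(fix[, "ID"], colnames(gt))
  genotype_matrix(dos, chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = alt)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(df)))
    stop("dosage TSV must have columns ", paste(need, collapse = ", "))
  samp <- setdiff(colnames(df), need)
  dos <- as.matrix(df[, samp, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- df$snp_id
  genotype_matrix(dos, df$chrom, df$pos, df$ref, df$alt)
}

#' Write genotypes as TSV dosages or minimal VCF
#'
#' @param geno A `GenotypeMatrix`.
#' @param path Output path; `.vcf` selects VCF v4.2 output (GT only).
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(geno, path) {
  if (grepl("\\.vcf$", path)) write_genotypes_vcf(geno, path)
  else write_genotypes_tsv(geno, path)
  invisible(path)
}

write_genotypes_tsv <- function(geno, path) {
  df <- cbind(geno$info, as.data.frame(geno$dosage, check.names = FALSE))
  colnames(df)[1] <- "snp_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_genotypes_vcf <- function(geno, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(geno$dosage), ncol(geno$dosage))
  ok <- !is.na(geno$dosage)
  gt[ok] <- gt_code[geno$dosage[ok] + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(geno$dosage)), collapse = "\t"))
  body <- paste(geno$info$chrom, geno$info$pos, geno$info$snp_id,
                geno$info$ref, geno$info$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Read GWAS loci from a BED file
#'
#' BED3/BED4, 0-based half-open. Records are returned sorted by
#' (chrom, start); overlaps are preserved. Records with start >= end are
#' rejected.
#'
#' @param path BED file.
#' @return A [locus_set()].
#' @export
read_loci <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  if (any(raw[[2]] >= raw[[3]]))
    stop("BED record with start >= end in ", path)
  gr <- rtracklayer::import(path, format = "BED")
  locus_set(chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,
            end = GenomicRanges::end(gr),
            name = if (!is.null(gr$name)) gr$name else NULL)
}

#' Write a locus set as BED
#'
#' @param loci A `LocusSet`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_loci <- function(loci, path) {
  utils::write.table(loci[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read/write a probe manifest TSV
#'
#' Columns: probe_id, chrom, pos, gene, feature, island_relation.
#'
#' @param path TSV file.
#' @return A [probe_manifest()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$gene[is.na(df$gene)] <- ""
  df$island_relation[is.na(df$island_relation)] <- ""
  probe_manifest(df$probe_id, df$chrom, df$pos, df$gene, df$feature,
                 df$island_relation)
}

#' @rdname read_manifest
#' @param manifest A `ProbeManifest` to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a sample sheet CSV
#'
#' @param path CSV file with at least sample_id, phenotype, age, sex,
#'   batch, cell_type columns.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(colnames(df),
                   c("sample_id", "phenotype", "age", "sex", "batch",
                     "cell_type"))
  args <- c(list(sample_id = df$sample_id, phenotype = df$phenotype,
                 age = df$age, sex = df$sex, batch = df$batch,
                 cell_type = df$cell_type),
            as.list(df[, extra, drop = FALSE]))
  do.call(sample_sheet, args)
}

#' @rdname read_sample_sheet
#' @param sheet A `SampleSheet` to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a gene-by-sample log2 expression matrix TSV
#'
#' @param path TSV with gene probe ids in the first column and one column
#'   per sample; values are log2 intensities (finite).
#' @return A numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  m <- read_numeric_tsv(path, what = "log2 intensity")
  if (any(!is.finite(m[!is.na(m)])))
    stop("non-finite expression values in ", path)
  m
}

#' @rdname read_expression
#' @param expr Matrix to write.
#' @export
write_expression <- function(expr, path) {
  write_numeric_tsv(expr, path)
  invisible(path)
}

#' Align data layers on their shared samples
#'
#' Restricts every layer to the intersection of sample ids, imposing the
#' first layer's ordering on all, and reports the ids dropped from each
#' layer. Layers may be `MethylationMatrix`, `GenotypeMatrix`,
#' `SampleSheet`, or any matrix/data.frame with sample columns or a
#' `sample_id` column.
#'
#' @param layers Named list of two or more data objects.
#' @return List with `layers` (aligned, same names) and `dropped` (list of
#'   character vectors of ids removed per layer).
#' @export
align_samples <- function(layers) {
  if (length(layers) < 2) stop("need at least two layers to align")
  ids <- lapply(layers, layer_sample_ids)
  common <- Reduce(intersect, ids)
  if (length(common) == 0) stop("no samples shared across layers")
  common <- ids[[1]][ids[[1]] %in% common]  # first layer's order
  aligned <- lapply(layers, restrict_layer, keep = common)
  dropped <- lapply(ids, function(x) setdiff(x, common))
  list(layers = aligned, dropped = dropped)
}

layer_sample_ids <- function(x) {
  if (inherits(x, "MethylationMatrix")) colnames(x$beta)
  else if (inherits(x, "GenotypeMatrix")) colnames(x$dosage)
  else if (is.data.frame(x) && "sample_id" %in% colnames(x)) x$sample_id
  else if (is.matrix(x)) colnames(x)
  else stop("cannot extract sample ids from layer of class ",
            paste(class(x), collapse = "/"))
}

restrict_layer <- function(x, keep) {
  if (inherits(x, "MethylationMatrix")) subset_methylation(x, samples = keep)
  else if (inherits(x, "GenotypeMatrix")) {
    x$dosage <- x$dosage[, keep, drop = FALSE]
    x
  } else if (is.data.frame(x) && "sample_id" %in% colnames(x)) {
    out <- x[match(keep, x$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else x[, keep, drop = FALSE]
}
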