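# Differential expression and cell-type-resolved methylation-expression
# correlation.

#' Per-gene differential expression
#'
#' Ordinary least squares of log2 intensity on case status plus
#' covariates (age and sex by default), with a two-sided t-test on the
#' group coefficient and Benjamini-Hochberg FDR across genes. The group
#' coefficient is the log2 fold change (case minus control).
#'
#' @param expr Gene-by-sample matrix of log2 intensities.
#' @param sheet `SampleSheet` aligned with the matrix columns.
#' @param design A [design_spec()].
#' @return data.frame with gene_probe_id, logFC, t, p, p_fdr, n.
#' @export
fit_de <- function(expr, sheet, design = design_spec()) {
  if (!identical(colnames(expr), sheet$sample_id))
    stop("expression samples and sheet are not aligned")
  X <- build_design(sheet, design)
  if (nrow(X) < ncol(X) + 2)
    stop("too few samples for the design (need rank+2)")
  res <- ols_group_tests(expr, X, min_n = ncol(X) + 2)
  data.frame(gene_probe_id = rownames(expr), logFC = res$coef, t = res$t,
             p = res$p, p_fdr = adjust_pvalues(res$p, "bh"), n = res$n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate methylation with gene expression, per cell type
#'
#' Pearson correlation between a methylation probe's beta values and a
#' gene's log2 expression on matched samples, computed separately within
#' each cell type present in the sheet.
#'
#' @param meth_values Named numeric vector of beta values (names =
#'   sample ids).
#' @param expr_values Named numeric vector of log2 expression.
#' @param sheet `SampleSheet` giving each sample's cell type.
#' @param probe_id,gene_probe_id Identifiers carried into the output.
#' @return data.frame with probe_id, gene_probe_id, cell_type, r, p, n;
#'   cell types with fewer than 3 matched pairs or a constant vector are
#'   reported with `NA` and a warning.
#' @export
correlate_meth_expr <- function(meth_values, expr_values, sheet,
                                probe_id = "probe", gene_probe_id = "gene") {
  common <- intersect(names(meth_values), names(expr_values))
  common <- intersect(common, sheet$sample_id)
  if (length(common) < 3) stop("need >= 3 matched samples")
  ct <- sheet$cell_type[match(common, sheet$sample_id)]
  out <- lapply(unique(ct), function(k) {
    ids <- common[ct == k]
    x <- meth_values[ids]; y <- expr_values[ids]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("cell type ", k, ": constant vector or <3 pairs; r = NA")
      return(data.frame(probe_id = probe_id,
                        gene_probe_id = gene_probe_id, cell_type = k,
                        r = NA_real_, p = NA_real_, n = length(x),
                        stringsAsFactors = FALSE))
    }
    ht <- stats::cor.test(x, y, method = "pearson")
    data.frame(probe_id = probe_id, gene_probe_id = gene_probe_id,
               cell_type = k, r = unname(ht$estimate), p = ht$p.value,
               n = length(x), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
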