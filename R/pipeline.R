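# End-to-end orchestration: simulate -> qc -> deconvolve -> dmp -> dmr ->
# enrich -> meqtl -> mediate -> integrate, from one config and one seed.

#' Configure a pipeline run
#'
#' @param outdir Output directory for result tables.
#' @param seed Single global seed; per-stage substreams are derived from
#'   it deterministically, so toggling one stage does not perturb
#'   another's randomness.
#' @param sim A [sim_config()] for the synthetic cohort (its `seed` is
#'   overridden by the derived substream).
#' @param stages Named logical toggles: qc, deconvolve, dmp, dmr, enrich,
#'   meqtl, mediate, integrate.
#' @param dmr_alpha,enrich_bins,meqtl_window,meqtl_maf Stage thresholds.
#' @param resume Reload existing stage outputs instead of recomputing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, sim = NULL,
                            stages = c(qc = TRUE, deconvolve = TRUE,
                                       dmp = TRUE, dmr = TRUE,
                                       enrich = TRUE, meqtl = TRUE,
                                       mediate = TRUE, integrate = TRUE),
                            dmr_alpha = 0.05,
                            enrich_bins = c(25e3, 50e3, 100e3, 250e3),
                            meqtl_window = 1e6, meqtl_maf = 0.1,
                            resume = FALSE) {
  defaults <- c(qc = TRUE, deconvolve = TRUE, dmp = TRUE, dmr = TRUE,
                enrich = TRUE, meqtl = TRUE, mediate = TRUE,
                integrate = TRUE)
  defaults[names(stages)] <- stages
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 stages = defaults, dmr_alpha = dmr_alpha,
                 enrich_bins = enrich_bins, meqtl_window = meqtl_window,
                 meqtl_maf = meqtl_maf, resume = resume),
            class = "pipeline_config")
}

stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

write_result_table <- function(df, path, seed, cfg_hash) {
  con <- file(path, "w")
  writeLines(sprintf("# ewaspipe %s config=%s seed=%d",
                     as.character(utils::packageVersion("ewaspipe")),
                     cfg_hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

read_result_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in order, writes one TSV per stage result
#' under `config$outdir` (each with a header comment recording version,
#' config hash and seed), and returns a run report. Identical config and
#' seed give byte-identical result tables. The cohort itself is always
#' materialized in memory from the simulate substream; with
#' `resume = TRUE`, analysis stages whose output tables already exist
#' are reloaded from disk instead of recomputed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report`: per-stage record counts, the
#'   thresholds and seeds used, wall time, and a file manifest with MD5
#'   checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- substr(tools::md5sum(
    textConnection_dump(config))[[1]], 1, 8)
  counts <- list(); files <- character(0)
  stage_log <- character(0)
  note <- function(stage, msg) {
    message("[", stage, "] ", msg)
    stage_log <<- c(stage_log, paste0(stage, ": ", msg))
  }
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    write_result_table(df, path, config$seed, cfg_hash)
    files <<- c(files, path)
    path
  }
  cached <- function(name) {
    config$resume && file.exists(file.path(config$outdir, name))
  }
  load_cached <- function(name) {
    read_result_table(file.path(config$outdir, name))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate (always in memory; drives every later stage)
  sim_cfg <- if (is.null(config$sim)) sim_config() else config$sim
  sim_cfg$seed <- stage_seed(config$seed, 1)
  cohort <- run_stage("simulate", simulate_cohort(sim_cfg))
  note("simulate", sprintf("%d samples, %d probes", nrow(cohort$sheet),
                           nrow(cohort$manifest)))
  counts$samples <- nrow(cohort$sheet)
  counts$probes <- nrow(cohort$manifest)

  ## qc
  meth <- cohort$meth$whole_blood
  if (config$stages[["qc"]]) {
    qc <- run_stage("qc", {
      fp <- filter_probes(meth)
      fs <- filter_samples(fp$meth)
      norm <- quantile_normalize(
        methylation_matrix(fs$meth$beta))  # complete synthetic matrix
      list(meth = norm, probes_removed = fp$report$probes_removed$detection,
           samples_removed = fs$report$samples_removed$failure_fraction)
    })
    meth <- qc$meth
    counts$probes_removed <- length(qc$probes_removed)
    counts$samples_removed <- length(qc$samples_removed)
    sexchk <- run_stage("qc", infer_sex(meth, cohort$manifest, cohort$sheet))
    counts$sex_mismatches <- sum(sexchk$mismatch)
    emit(data.frame(metric = c("probes_removed", "samples_removed",
                               "sex_mismatches"),
                    value = c(counts$probes_removed, counts$samples_removed,
                              counts$sex_mismatches)), "qc_report.tsv")
    note("qc", sprintf("%d probes, %d samples removed; %d sex mismatches",
                       counts$probes_removed, counts$samples_removed,
                       counts$sex_mismatches))
  } else note("qc", "skipped")
  sheet <- cohort$sheet[match(colnames(meth$beta), cohort$sheet$sample_id), ]
  rownames(sheet) <- NULL
  class(sheet) <- class(cohort$sheet)

  ## deconvolve
  props <- NULL
  if (config$stages[["deconvolve"]]) {
    props <- run_stage("deconvolve",
                       estimate_cell_proportions(meth, cohort$reference))
    emit(data.frame(sample_id = rownames(props$proportions),
                    props$proportions, check.names = FALSE),
         "cell_proportions.tsv")
    note("deconvolve", sprintf("%d samples deconvolved", nrow(props$proportions)))
  } else note("deconvolve", "skipped")

  ## dmp
  dmps <- NULL
  if (config$stages[["dmp"]]) {
    if (cached("dmp.tsv")) {
      dmps <- load_cached("dmp.tsv")
      note("dmp", "reloaded from disk")
    } else {
      design <- design_spec(cell_props = props)
      dmps <- run_stage("dmp", fit_dmp(meth, sheet, design))
      emit(dmps, "dmp.tsv")
      note("dmp", sprintf("%d probes tested, %d Holm-significant",
                          nrow(dmps), sum(dmps$p_holm < 0.05, na.rm = TRUE)))
    }
    counts$dmp_significant <- sum(dmps$p_holm < 0.05, na.rm = TRUE)
  } else note("dmp", "skipped")

  ## dmr
  if (config$stages[["dmr"]] && !is.null(dmps)) {
    dmrs <- if (cached("dmr.tsv")) load_cached("dmr.tsv") else {
      d <- run_stage("dmr", call_dmrs(dmps, cohort$manifest,
                                      alpha = config$dmr_alpha))
      emit(d, "dmr.tsv")
      d
    }
    counts$dmrs <- nrow(dmrs)
    note("dmr", sprintf("%d regions", nrow(dmrs)))
  } else note("dmr", "skipped")

  ## enrich
  if (config$stages[["enrich"]] && !is.null(dmps)) {
    sig <- dmps$probe_id[!is.na(dmps$p_holm) & dmps$p_holm < 0.05]
    sig <- intersect(sig, cohort$manifest$probe_id[
      cohort$manifest$chrom != "chrX"])
    if (length(sig) >= 3) {
      enr <- run_stage("enrich", gwas_proximity_enrichment(
        sig, cohort$manifest, cohort$loci, bin_sizes = config$enrich_bins,
        seed = stage_seed(config$seed, 5)))
      enr$locus_set <- "ibd"
      ctrl <- run_stage("enrich", gwas_proximity_enrichment(
        sig, cohort$manifest, cohort$other_loci,
        bin_sizes = config$enrich_bins,
        seed = stage_seed(config$seed, 6)))
      ctrl$locus_set <- "other_disease"
      emit(rbind(enr, ctrl), "enrichment.tsv")
      counts$enrichment_bins <- nrow(enr)
      note("enrich", sprintf("min empirical p %.3g (ibd loci)",
                             min(enr$empirical_p)))
    } else note("enrich", "skipped (fewer than 3 significant DMPs)")
  } else note("enrich", "skipped")

  ## meqtl
  meqtl <- NULL
  if (config$stages[["meqtl"]] && !is.null(cohort$geno) && !is.null(dmps)) {
    sig <- dmps$probe_id[!is.na(dmps$p_holm) & dmps$p_holm < 0.05]
    sig <- intersect(sig, rownames(meth$beta))
    if (length(sig) > 0) {
      al <- align_samples(list(meth = subset_methylation(meth, probes = sig),
                               geno = cohort$geno, sheet = sheet))
      meqtl <- run_stage("meqtl", scan_cis_meqtl(
        al$layers$meth, al$layers$geno, cohort$manifest, al$layers$sheet,
        window = config$meqtl_window, maf_thresh = config$meqtl_maf,
        design = design_spec(cell_props = props)))
      emit(meqtl, "meqtl.tsv")
      counts$meqtl_significant <- sum(meqtl$p_fdr < 0.05, na.rm = TRUE)
      note("meqtl", sprintf("%d tests, %d FDR-significant", nrow(meqtl),
                            counts$meqtl_significant))
    } else note("meqtl", "skipped (no significant DMPs)")
  } else note("meqtl", "skipped")

  ## mediate: chain on the strongest meQTL pair
  if (config$stages[["mediate"]] && !is.null(meqtl) && nrow(meqtl) > 0) {
    top <- meqtl[which.min(meqtl$p), ]
    med <- run_stage("mediate", mediation_chain(
      cohort$geno$dosage[top$snp_id, sheet$sample_id],
      beta_to_m(meth$beta[top$probe_id, ]),
      as.numeric(sheet$phenotype != "control"),
      covariates = data.frame(age = sheet$age,
                              sex = as.numeric(sheet$sex == "M"))))
    emit(data.frame(snp_id = top$snp_id, probe_id = top$probe_id,
                    p1 = med$p[1], p2 = med$p[2], p3 = med$p[3],
                    p4 = med$p[4], label = med$label), "mediation.tsv")
    note("mediate", sprintf("%s (top pair %s-%s)", med$label,
                            top$snp_id, top$probe_id))
  } else note("mediate", "skipped")

  ## integrate: per-cell-type DE and methylation-expression correlation
  if (config$stages[["integrate"]] && !is.null(cohort$expression)) {
    de_all <- list(); cors <- list()
    for (ct in names(cohort$expression)) {
      sub_sheet <- cohort$cell_sheet[cohort$cell_sheet$cell_type == ct, ]
      expr <- cohort$expression[[ct]]
      colnames(expr) <- paste0(colnames(expr), ".", ct)
      de <- run_stage("integrate",
                      fit_de(expr, {
                        s <- sub_sheet
                        class(s) <- class(cohort$sheet)
                        s
                      }))
      de$cell_type <- ct
      de_all[[ct]] <- de
      # correlate the strongest DE genes with the strongest DMPs
      top_genes <- de$gene_probe_id[order(de$p)][
        seq_len(min(3, nrow(de)))]
      top_probes <- if (!is.null(dmps))
        dmps$probe_id[order(dmps$p)][seq_len(min(3, nrow(dmps)))] else NULL
      mlayer <- if (ct == "whole_blood") meth else cohort$meth[[ct]]
      for (gp in top_genes) for (pp in intersect(top_probes,
                                                 rownames(mlayer$beta))) {
        mv <- mlayer$beta[pp, ]
        names(mv) <- paste0(names(mv), ".", ct)
        ev <- cohort$expression[[ct]][gp, ]
        names(ev) <- paste0(names(ev), ".", ct)
        cors[[length(cors) + 1]] <- run_stage("integrate",
          suppressWarnings(correlate_meth_expr(
            mv, ev, cohort$cell_sheet, probe_id = pp, gene_probe_id = gp)))
      }
    }
    de_tab <- do.call(rbind, de_all)
    rownames(de_tab) <- NULL
    emit(de_tab, "de.tsv")
    if (length(cors) > 0) {
      cor_tab <- do.call(rbind, cors)
      emit(cor_tab, "correlation.tsv")
    }
    counts$de_tests <- nrow(de_tab)
    note("integrate", sprintf("%d DE tests across %d cell types",
                              nrow(de_tab), length(de_all)))
  } else note("integrate", "skipped")

  report <- structure(list(
    counts = counts, stages = config$stages, seed = config$seed,
    stage_seeds = stats::setNames(vapply(1:6, function(k)
      stage_seed(config$seed, k), integer(1)),
      c("simulate", "qc", "deconvolve", "dmp", "enrich", "enrich_ctrl")),
    thresholds = list(dmr_alpha = config$dmr_alpha,
                      meqtl_window = config$meqtl_window,
                      meqtl_maf = config$meqtl_maf),
    log = stage_log,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    manifest = data.frame(file = basename(files),
                          md5 = unname(tools::md5sum(files)),
                          stringsAsFactors = FALSE)),
    class = "run_report")
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("wall_time_s: %.1f", report$wall_time_s),
               report$log,
               paste(report$manifest$file, report$manifest$md5)),
             file.path(config$outdir, "run_report.txt"))
  report
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", ", sprintf("%.1f", x$wall_time_s),
      " s)\n", sep = "")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

# stable text serialization of a config for hashing; paths and the
# resume flag do not alter the scientific content of a run
textConnection_dump <- function(config) {
  tmp <- tempfile()
  dput(config[setdiff(names(config), c("resume", "outdir"))], tmp)
  tmp
}
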