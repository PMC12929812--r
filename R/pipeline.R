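# End-to-end orchestration with file-based stage contracts: every stage
# reads its inputs from disk and writes TSV outputs, so each stage is
# testable in isolation and usable on external data. A manifest records the
# seed, config hash and checksums of every file touched.

#' Default pipeline configuration
#'
#' @param n_patients,n_genes Cohort size of the synthetic demo run.
#' @return Nested configuration list understood by
#'   \code{\link{run_pipeline}}.
#' @export
default_pipeline_config <- function(n_patients = 20, n_genes = 300) {
  list(
    seed = 1,
    cohort = list(n_patients = n_patients, n_genes = n_genes),
    stages = list(thresholds = TRUE, crosscor = TRUE, lmm = TRUE,
                  deg = TRUE, tcr = TRUE, spatial = TRUE, histo = TRUE),
    thresholds = list(min_cells = 10, nonzero_only = TRUE),
    crosscor = list(B = 2000, r_thresh = 0.25, p_thresh = 0.05,
                    min_cells = 10),
    lmm = list(target_gene = "CTLA4", target_cell_type = "T"),
    deg = list(cell_type = "T", rule = "human"),
    tcr = list(B = 2000),
    spatial = list(rows = 25, cols = 25, rho = 0.5, mean_counts = 5,
                   dropout = 0.1),
    histo = list(n_regions = 5, intensity_profile = c(0.4, 0.3, 0.2, 0.1),
                 n_til_regions = 5, til_profile = c(0.5, 0.3, 0.15, 0.05),
                 n_grids = 400, class_mix = c(0.4, 0.35, 0.25))
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_cfg(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_cfg(base, config)
}

pipeline_log <- function(fmt, ...) message(sprintf(paste0("[tmecrosstalk] ", fmt), ...))

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, then runs normalization and GMM
#' thresholding, the cross-cell-type correlation scan with the
#' random-intercept mixed model, differential expression between the
#' anchor-defined patient groups, TCR expansion analysis, spatial
#' pseudo-spot co-expression, and histology scoring — each stage exchanging
#' data through files under \code{out_dir}.
#'
#' @param config A configuration list (see
#'   \code{\link{default_pipeline_config}}) or the path to a YAML file with
#'   the same structure.
#' @param out_dir Output directory.
#' @param seed Optional root-seed override.
#' @return Invisibly, the manifest (also written as
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         seed = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_dir <- file.path(out_dir, "input")
  files <- character(0)
  note <- function(p) files <<- unique(c(files, unlist(p, use.names = FALSE)))

  # --- simulate ------------------------------------------------------------
  ccfg <- do.call(cohort_config, cfg$cohort)
  cohort <- generate_cohort(ccfg, seed = cfg$seed)
  pipeline_log("simulated cohort: %d patients, %d cells, %d genes",
               ccfg$n_patients, length(cohort$table$cell_ids), ccfg$n_genes)
  note(write_expression(cohort$table, in_dir))
  note(write_clonotypes(cohort$clonotypes, file.path(in_dir, "clonotypes.csv")))
  slide <- do.call(generate_slide,
                   c(cfg$spatial[c("rows", "cols", "rho", "mean_counts",
                                   "dropout")],
                     list(seed = cfg$seed,
                          gene_names = c(ccfg$anchor_gene,
                                         cfg$lmm$target_gene))))
  note(write_spots(slide, file.path(in_dir, "spots.tsv")))
  ihc <- rbind(
    generate_ihc(cfg$histo$n_regions, cfg$histo$intensity_profile,
                 region_kind = "epithelial", seed = cfg$seed),
    generate_ihc(cfg$histo$n_til_regions, cfg$histo$til_profile,
                 region_kind = "TIL", seed = cfg$seed + 1))
  ihc$region_id <- paste(ihc$region_kind, ihc$region_id, sep = "_")
  note(write_ihc(ihc_cell_table(ihc), file.path(in_dir, "ihc_cells.csv")))
  tgrid <- generate_til_grid(cfg$histo$n_grids, cfg$histo$class_mix,
                             seed = cfg$seed)
  note(write_til_grid(tgrid, file.path(in_dir, "til_grid.csv")))
  truth_path <- file.path(in_dir, "ground_truth.json")
  jsonlite::write_json(
    list(patients = cohort$truth$patients, coupling = cohort$truth$coupling,
         anchor_gene = cohort$truth$anchor_gene,
         anchor_cell_type = cohort$truth$anchor_cell_type, seed = cfg$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  note(truth_path)

  # --- reload inputs (stage isolation) -------------------------------------
  table <- read_expression(file.path(in_dir, "matrix.mtx"),
                           file.path(in_dir, "genes.tsv"),
                           file.path(in_dir, "barcodes.tsv"),
                           file.path(in_dir, "cell_meta.tsv"))
  norm <- normalize_expression(table)
  pb <- pseudobulk(norm, min_cells = cfg$crosscor$min_cells)
  anchor_pb <- pb[pb$gene == ccfg$anchor_gene &
                  pb$cell_type == ccfg$anchor_cell_type, ]
  anchor_means <- setNames(anchor_pb$mean_norm_expr, anchor_pb$patient_id)
  stage_ran <- list()

  # --- thresholds ----------------------------------------------------------
  if (isTRUE(cfg$stages$thresholds)) {
    sel <- table$cell_meta$cell_type == ccfg$anchor_cell_type
    vals <- as.vector(norm$values[ccfg$anchor_gene, sel])
    fit <- fit_gmm2(vals, seed = cfg$seed,
                    nonzero_only = isTRUE(cfg$thresholds$nonzero_only))
    cut_df <- data.frame(gene = ccfg$anchor_gene,
                         cell_type = ccfg$anchor_cell_type,
                         w1 = fit$w1, mu1 = fit$mu1, sd1 = fit$sd1,
                         w2 = fit$w2, mu2 = fit$mu2, sd2 = fit$sd2,
                         cutoff = fit$cutoff, n_values = fit$n,
                         stringsAsFactors = FALSE)
    p <- file.path(out_dir, "cutoffs.tsv")
    write_tsv_utf8(cut_df, p); note(p)
    groups <- patient_group(pb, ccfg$anchor_gene, ccfg$anchor_cell_type,
                            fit$cutoff)
    p <- file.path(out_dir, "patient_groups.tsv")
    write_tsv_utf8(groups, p); note(p)
    pipeline_log("thresholds: cutoff %.3f; %d high / %d low patients",
                 fit$cutoff, sum(groups$group == "high"),
                 sum(groups$group == "low"))
    stage_ran$thresholds <- TRUE
  }

  # --- crosscor + lmm ------------------------------------------------------
  if (isTRUE(cfg$stages$crosscor)) {
    scan <- cross_celltype_scan(pb, ccfg$anchor_gene, ccfg$anchor_cell_type,
                                B = cfg$crosscor$B,
                                r_thresh = cfg$crosscor$r_thresh,
                                p_thresh = cfg$crosscor$p_thresh,
                                seed = cfg$seed)
    p <- file.path(out_dir, "crosscor.tsv")
    write_tsv_utf8(as.data.frame(scan), p); note(p)
    pipeline_log("crosscor: %d pairs tested, %d selected", nrow(scan),
                 sum(scan$selected))
    stage_ran$crosscor <- TRUE
  }
  if (isTRUE(cfg$stages$lmm)) {
    tg <- cfg$lmm$target_gene; tct <- cfg$lmm$target_cell_type
    sel <- table$cell_meta$cell_type == tct &
      table$cell_meta$patient_id %in% names(anchor_means)
    y <- as.vector(norm$values[tg, sel])
    pats <- table$cell_meta$patient_id[sel]
    xz <- zscore_patients(anchor_means)
    lfit <- fit_random_intercept_lmm(y, pats, xz)
    p <- file.path(out_dir, "lmm.tsv")
    write_tsv_utf8(data.frame(target_gene = tg, target_cell_type = tct,
                              beta0 = lfit$beta0, beta1 = lfit$beta1,
                              se = lfit$se_beta1, sigma_u2 = lfit$sigma_u2,
                              sigma_e2 = lfit$sigma_e2, df = lfit$df_satt,
                              p = lfit$p_value, n_cells = lfit$n_cells,
                              n_patients = lfit$n_patients,
                              stringsAsFactors = FALSE), p)
    note(p)
    stage_ran$lmm <- TRUE
  }

  # --- deg -----------------------------------------------------------------
  if (isTRUE(cfg$stages$deg) && isTRUE(stage_ran$thresholds)) {
    groups <- read.delim(file.path(out_dir, "patient_groups.tsv"),
                         stringsAsFactors = FALSE)
    hi <- groups$patient_id[groups$group == "high"]
    lo <- groups$patient_id[groups$group == "low"]
    sel <- table$cell_meta$cell_type == cfg$deg$cell_type
    ca <- table$cell_meta$barcode[sel & table$cell_meta$patient_id %in% hi]
    cb <- table$cell_meta$barcode[sel & table$cell_meta$patient_id %in% lo]
    if (length(ca) && length(cb)) {
      recs <- wilcoxon_deg(norm, ca, cb)
      recs <- if (identical(cfg$deg$rule, "mouse")) filter_deg_mouse(recs)
              else filter_deg_human(recs)
      p <- file.path(out_dir, "deg.tsv")
      write_tsv_utf8(as.data.frame(recs), p); note(p)
      pipeline_log("deg (%s cells, %s rule): %d tested, %d selected",
                   cfg$deg$cell_type, cfg$deg$rule, nrow(recs),
                   sum(recs$selected))
      stage_ran$deg <- TRUE
    }
  }

  # --- tcr -----------------------------------------------------------------
  if (isTRUE(cfg$stages$tcr)) {
    clon <- read_clonotypes(file.path(in_dir, "clonotypes.csv"), table)
    summ <- clonotype_sizes(clon, table$cell_meta)
    p <- file.path(out_dir, "tcr_summary.tsv")
    write_tsv_utf8(as.data.frame(summ), p); note(p)
    props <- expanded_proportion(summ)
    p <- file.path(out_dir, "tcr_patient.tsv")
    write_tsv_utf8(props, p); note(p)
    if (nrow(props) >= 3) {
      ec <- correlate_expansion(props, anchor_means, B = cfg$tcr$B,
                                seed = cfg$seed)
      p <- file.path(out_dir, "tcr_expansion_cor.tsv")
      write_tsv_utf8(data.frame(r = ec$r, p_perm = ec$p,
                                n_patients = ec$n_patients), p)
      note(p)
      pipeline_log("tcr: expansion-anchor r = %.3f (p = %.3g, n = %d)",
                   ec$r, ec$p, ec$n_patients)
    }
    stage_ran$tcr <- TRUE
  }

  # --- spatial -------------------------------------------------------------
  if (isTRUE(cfg$stages$spatial)) {
    grid <- read_spots(file.path(in_dir, "spots.tsv"))
    res <- analyze_slide(grid, ccfg$anchor_gene, cfg$lmm$target_gene)
    p <- file.path(out_dir, "spatial.tsv")
    write_tsv_utf8(data.frame(
      n_spots = res$n_spots,
      n_pseudospots_retained = res$n_pseudospots_retained,
      expressing_frac = res$expressing_frac,
      pass_filter = res$pass_filter,
      r_spot = res$r_spot, r_pseudospot = res$r_pseudospot,
      stringsAsFactors = FALSE), p)
    note(p)
    pipeline_log("spatial: r_spot = %.3f, r_pseudospot = %.3f",
                 res$r_spot, res$r_pseudospot)
    stage_ran$spatial <- TRUE
  }

  # --- histo ---------------------------------------------------------------
  if (isTRUE(cfg$stages$histo)) {
    cells <- read_ihc(file.path(in_dir, "ihc_cells.csv"))
    hs <- h_score(cells, region_kind = "epithelial")
    cs <- counting_score(cells, region_kind = "TIL")
    tg2 <- read_til_grid(file.path(in_dir, "til_grid.csv"))
    isc <- inflamed_score(tg2)
    p <- file.path(out_dir, "histo.tsv")
    write_tsv_utf8(data.frame(
      h_score_case = hs$case_score, counting_score_case = cs$case_score,
      inflamed = isc$proportions["inflamed"],
      excluded = isc$proportions["excluded"],
      desert = isc$proportions["desert"], stringsAsFactors = FALSE), p)
    note(p)
    stage_ran$histo <- TRUE
  }

  # --- manifest ------------------------------------------------------------
  cfg_tmp <- tempfile(); on.exit(unlink(cfg_tmp), add = TRUE)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), cfg_tmp)
  manifest <- list(
    package_version = as.character(packageVersion("tmecrosstalk")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    stages = stage_ran,
    files = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
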