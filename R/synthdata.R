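# Synthetic cohorts with planted structure. Every downstream stage of the
# pipeline is validated against data from this module, whose ground truth
# (per-patient anchor activity, coupling slopes, expansion fractions,
# latent spatial correlation) is recorded explicitly.
#
# Generative model for a cohort:
#   * patient anchor activity a_i ~ two-component normal mixture (bimodal,
#     so GMM thresholding has a meaningful target);
#   * per-cell gene counts ~ negative binomial with
#     log mean = log(baseline_g) + b_(g,t) * a_i for coupled (gene, cell
#     type) pairs, and b = 0 otherwise (gene-level dispersion mimics
#     scRNA-seq overdispersion);
#   * T-cell clonotypes with per-patient expanded-cell fraction
#     logistic in a_i and expanded clone sizes 2 + a geometric tail;
#   * all randomness flows from one root seed through named substreams
#     (expression, tcr, spatial, ihc, til) so modules regenerate
#     independently.

#' Cohort generator configuration
#'
#' Defaults emulate a 30-patient colorectal-cancer single-cell cohort with a
#' bimodal epithelial anchor gene and one planted coupled target gene in T
#' cells.
#'
#' @param n_patients Number of patients.
#' @param cells_per_patient Length-2 integer range; per-patient cell counts
#'   are drawn uniformly from it.
#' @param cell_type_proportions Named probability vector over cell types.
#' @param n_genes Total genes (anchor and coupled genes included).
#' @param anchor_gene,anchor_cell_type The anchor marker and its compartment.
#' @param anchor_mixture Anchor-activity mixture: list(weights, means, sds),
#'   two components each.
#' @param anchor_slope Coupling of the anchor gene itself to the activity
#'   within the anchor cell type (makes the anchor's pseudobulk mean track
#'   a_i).
#' @param coupling data.frame(gene, cell_type, slope): planted couplings of
#'   target genes to a_i. NULL or 0-row for an all-null cohort.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline mean counts
#'   are lognormal(baseline_log_mean, baseline_log_sd), drawn once per
#'   cohort from the expression substream.
#' @param marker_baseline Fixed baseline mean count for the named genes
#'   (anchor and coupled targets); markers are well-detected genes, which a
#'   lognormal draw would not guarantee.
#' @param tcr_c0,tcr_c1 Expansion-fraction logistic coefficients:
#'   fraction_i = plogis(tcr_c0 + tcr_c1 * a_i).
#' @param tcr_recovery Fraction of T cells with a recovered clonotype.
#' @param tcr_geom_p Geometric parameter of the expanded clone-size tail
#'   (sizes are 2 + geometric(tcr_geom_p)).
#' @return A validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 30,
                          cells_per_patient = c(80, 150),
                          cell_type_proportions = c(epithelial = 0.40,
                                                    T = 0.30, B = 0.10,
                                                    myeloid = 0.10,
                                                    fibroblast = 0.10),
                          n_genes = 500,
                          anchor_gene = "CEBPB",
                          anchor_cell_type = "epithelial",
                          anchor_mixture = list(weights = c(0.5, 0.5),
                                                means = c(0, 2),
                                                sds = c(0.3, 0.3)),
                          anchor_slope = 1,
                          coupling = data.frame(gene = "CTLA4",
                                                cell_type = "T",
                                                slope = 1,
                                                stringsAsFactors = FALSE),
                          nb_dispersion = 0.5,
                          baseline_log_mean = log(0.5),
                          baseline_log_sd = 1,
                          marker_baseline = 5,
                          tcr_c0 = -1.5, tcr_c1 = 2,
                          tcr_recovery = 0.85,
                          tcr_geom_p = 0.35) {
  check_count(n_patients, "n_patients", lower = 0)
  check_count(n_genes, "n_genes", lower = 0)
  stopifnot(length(cells_per_patient) == 2, all(cells_per_patient >= 1),
            cells_per_patient[1] <= cells_per_patient[2])
  p <- cell_type_proportions
  if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0))
    abort_tme("cell_type_proportions must be a named probability vector")
  w <- anchor_mixture$weights
  if (length(w) != 2 || any(w <= 0) || any(w >= 1) || abs(sum(w) - 1) > 1e-8)
    abort_tme("anchor mixture weights must be two values in (0,1) summing to 1")
  if (any(anchor_mixture$sds <= 0)) abort_tme("anchor mixture sds must be > 0")
  if (!anchor_cell_type %in% names(p))
    abort_tme("anchor_cell_type must be one of the cell types")
  if (is.null(coupling))
    coupling <- data.frame(gene = character(), cell_type = character(),
                           slope = numeric(), stringsAsFactors = FALSE)
  coupling <- as.data.frame(coupling, stringsAsFactors = FALSE)
  if (nrow(coupling) && !all(coupling$cell_type %in% names(p)))
    abort_tme("coupling cell types must be in cell_type_proportions")
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(tcr_recovery, "tcr_recovery", lower = 0, upper = 1)
  check_number(tcr_geom_p, "tcr_geom_p", lower = 1e-6, upper = 1 - 1e-6)
  structure(list(
    n_patients = n_patients, cells_per_patient = cells_per_patient,
    cell_type_proportions = p, n_genes = n_genes,
    anchor_gene = anchor_gene, anchor_cell_type = anchor_cell_type,
    anchor_mixture = anchor_mixture, anchor_slope = anchor_slope,
    coupling = coupling, nb_dispersion = nb_dispersion,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    marker_baseline = marker_baseline,
    tcr_c0 = tcr_c0, tcr_c1 = tcr_c1, tcr_recovery = tcr_recovery,
    tcr_geom_p = tcr_geom_p), class = "cohort_config")
}

cohort_gene_ids <- function(config) {
  named <- unique(c(config$anchor_gene, config$coupling$gene))
  if (length(named) > config$n_genes)
    abort_tme("n_genes smaller than the number of named genes")
  n_fill <- config$n_genes - length(named)
  c(named, if (n_fill > 0) sprintf("G%04d", seq_len(n_fill)))
}

#' Generate a synthetic cohort
#'
#' Draws a full single-cell cohort (expression + clonotypes) from a
#' \code{\link{cohort_config}} and records the ground truth. Identical
#' (config, seed) give byte-identical output.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Integer root seed.
#' @return List: \code{table} (\code{cell_expression_table}),
#'   \code{clonotypes} (\code{clonotype_table}), \code{truth} (list with
#'   per-patient activity/expansion data.frame \code{patients}, the
#'   \code{coupling} table, per-gene \code{baseline_means}, and the seed).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- cohort_gene_ids(config)
  types <- names(config$cell_type_proportions)
  size_nb <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf

  expr_seed <- substream_seed(seed, "expression")
  tcr_seed <- substream_seed(seed, "tcr")

  # slope matrix gene x cell type
  slopes <- matrix(0, length(genes), length(types),
                   dimnames = list(genes, types))
  if (config$n_genes > 0) {
    slopes[config$anchor_gene, config$anchor_cell_type] <- config$anchor_slope
    if (nrow(config$coupling))
      slopes[cbind(match(config$coupling$gene, genes),
                   match(config$coupling$cell_type, types))] <-
        config$coupling$slope
  }

  empty <- config$n_patients == 0
  patients <- sprintf("P%03d", seq_len(config$n_patients))

  gen <- with_seed(expr_seed, {
    baseline <- exp(rnorm(length(genes), config$baseline_log_mean,
                          config$baseline_log_sd))
    named <- unique(c(config$anchor_gene, config$coupling$gene))
    baseline[match(named, genes)] <- config$marker_baseline
    comp <- if (empty) integer(0) else
      1L + (runif(config$n_patients) > config$anchor_mixture$weights[1])
    a <- if (empty) numeric(0) else
      rnorm(config$n_patients,
            config$anchor_mixture$means[comp],
            config$anchor_mixture$sds[comp])
    n_cells <- if (empty) integer(0) else
      sample(seq(config$cells_per_patient[1], config$cells_per_patient[2]),
             config$n_patients, replace = TRUE)
    blocks <- vector("list", config$n_patients)
    meta <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      ct <- sample(types, n_cells[i], replace = TRUE,
                   prob = config$cell_type_proportions)
      counts_i <- matrix(0L, length(genes), n_cells[i])
      for (t in types) {
        sel <- which(ct == t)
        if (!length(sel)) next
        mu <- baseline * exp(slopes[, t] * a[i])
        counts_i[, sel] <- if (is.finite(size_nb))
          rnbinom(length(genes) * length(sel), size = size_nb, mu = mu)
        else rpois(length(genes) * length(sel), mu)
      }
      blocks[[i]] <- counts_i
      meta[[i]] <- data.frame(
        barcode = sprintf("%s_cell%04d", patients[i], seq_len(n_cells[i])),
        patient_id = patients[i], cell_type = ct,
        subtype = NA_character_, stringsAsFactors = FALSE)
    }
    list(baseline = baseline, comp = comp, a = a, n_cells = n_cells,
         blocks = blocks, meta = meta)
  })

  meta <- if (empty)
    data.frame(barcode = character(), patient_id = character(),
               cell_type = character(), subtype = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, gen$meta)
  counts <- if (empty || config$n_genes == 0)
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(genes), nrow(meta)),
                         dimnames = list(genes, meta$barcode))
  else {
    dense <- do.call(cbind, gen$blocks)
    dimnames(dense) <- list(genes, meta$barcode)
    as(as(as(Matrix::Matrix(dense, sparse = TRUE), "dMatrix"),
          "generalMatrix"), "CsparseMatrix")
  }
  table <- cell_expression_table(counts, meta)

  # clonotypes for T cells: expanded-cell fraction logistic in a_i, expanded
  # clone sizes 2 + geometric tail
  expansion <- plogis(config$tcr_c0 + config$tcr_c1 * gen$a)
  clon <- with_seed(tcr_seed, {
    rows <- list()
    for (i in seq_len(config$n_patients)) {
      tcells <- meta$barcode[meta$patient_id == patients[i] &
                             meta$cell_type == "T"]
      if (!length(tcells)) next
      rec <- tcells[runif(length(tcells)) < config$tcr_recovery]
      if (!length(rec)) next
      rec <- sample(rec)
      m <- rbinom(1, length(rec), expansion[i])
      if (m == 1) m <- 0                     # a lone cell cannot be expanded
      sizes <- integer(0)
      left <- m
      while (left > 0) {
        s <- 2 + rgeom(1, config$tcr_geom_p)
        if (s > left) s <- left
        if (s == 1) {                        # fold remainder into last clone
          sizes[length(sizes)] <- sizes[length(sizes)] + 1L
          left <- 0
        } else {
          sizes <- c(sizes, s)
          left <- left - s
        }
      }
      sizes <- c(sizes, rep(1L, length(rec) - m))
      ids <- sprintf("%s_K%04d", patients[i], seq_along(sizes))
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = rec, clonotype_id = rep(ids, sizes),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(barcode = character(), clonotype_id = character(),
                    stringsAsFactors = FALSE)
  })
  clonotypes <- clonotype_table(clon, table)

  truth <- list(
    patients = data.frame(patient_id = patients,
                          anchor_activity = gen$a,
                          mixture_component = gen$comp,
                          expansion_fraction = expansion,
                          n_cells = gen$n_cells,
                          stringsAsFactors = FALSE),
    coupling = config$coupling,
    anchor_gene = config$anchor_gene,
    anchor_cell_type = config$anchor_cell_type,
    baseline_means = setNames(gen$baseline, genes),
    seed = seed)
  list(table = table, clonotypes = clonotypes, truth = truth)
}

#' Monte-Carlo estimate of the true planted patient-level correlation
#'
#' Estimates the patient-level Pearson correlation between the anchor
#' pseudobulk mean and a coupled target's pseudobulk mean implied by a
#' config, by generating one large cohort. Used to express coupling slopes
#' on the correlation scale.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param target_gene,target_cell_type The coupled pair to evaluate.
#' @param n_patients Number of patients for the Monte-Carlo cohort.
#' @param seed Integer seed.
#' @param min_cells Pseudobulk cell filter.
#' @return The estimated correlation.
#' @export
planted_patient_r <- function(config, target_gene, target_cell_type,
                              n_patients = 400, seed = 1, min_cells = 5) {
  big <- config
  big$n_patients <- n_patients
  cohort <- generate_cohort(big, seed = seed)
  norm <- normalize_expression(cohort$table)
  pb <- pseudobulk(norm, min_cells = min_cells,
                   genes = unique(c(config$anchor_gene, target_gene)))
  xa <- pb[pb$gene == config$anchor_gene &
           pb$cell_type == config$anchor_cell_type, ]
  yt <- pb[pb$gene == target_gene & pb$cell_type == target_cell_type, ]
  pats <- intersect(xa$patient_id, yt$patient_id)
  pearson_r(xa$mean_norm_expr[match(pats, xa$patient_id)],
            yt$mean_norm_expr[match(pats, yt$patient_id)])
}

#' Calibrate a coupling slope to a target patient-level correlation
#'
#' Evaluates \code{\link{planted_patient_r}} on a grid of slopes and
#' interpolates the slope whose implied patient-level correlation matches
#' \code{target_r}.
#'
#' @param config A \code{\link{cohort_config}} with exactly one coupling row.
#' @param target_r Desired true patient-level correlation.
#' @param slopes Candidate slope grid.
#' @param n_patients,seed Monte-Carlo settings per grid point.
#' @return The interpolated slope, with the grid as an attribute.
#' @export
calibrate_coupling_slope <- function(config, target_r,
                                     slopes = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5),
                                     n_patients = 400, seed = 1) {
  stopifnot(nrow(config$coupling) == 1)
  rs <- vapply(seq_along(slopes), function(k) {
    cfg <- config
    cfg$coupling$slope <- slopes[k]
    planted_patient_r(cfg, config$coupling$gene, config$coupling$cell_type,
                      n_patients = n_patients, seed = seed + k)
  }, numeric(1))
  if (target_r < min(rs) || target_r > max(rs))
    abort_tme("target_r %.2f outside the achievable range [%.2f, %.2f]",
              target_r, min(rs), max(rs))
  o <- order(rs)
  slope <- stats::approx(rs[o], slopes[o], xout = target_r, ties = mean)$y
  structure(slope, grid = data.frame(slope = slopes, r = rs))
}

#' Generate a synthetic Visium-style slide
#'
#' Full hexagonal lattice in array coordinates (row + col even) minus
#' random dropout, with two gene-count channels driven by shared smooth
#' latent Gaussian fields with correlation \code{rho} and Poisson
#' observation noise.
#'
#' @param rows,cols Lattice dimensions (rows x spots-per-row).
#' @param rho Latent-field correlation between the two channels, in [-1,1].
#' @param mean_counts Marginal mean count per spot and gene.
#' @param dropout Probability a spot is missing.
#' @param seed Integer seed.
#' @param gene_names Names of the two gene channels.
#' @param latent_sd Log-scale sd of the latent field.
#' @param smoothing Number of neighbor-averaging passes (spatial range of
#'   the field).
#' @return A \code{\link{spot_grid}}; the latent fields are recorded in
#'   \code{attr(, "truth")}.
#' @export
generate_slide <- function(rows, cols, rho, mean_counts = 5, dropout = 0.1,
                           seed = 1, gene_names = c("CEBPB", "CTLA4"),
                           latent_sd = 0.6, smoothing = 2) {
  check_count(rows, "rows", lower = 1)
  check_count(cols, "cols", lower = 1)
  check_number(rho, "rho", lower = -1, upper = 1)
  check_number(dropout, "dropout", lower = 0, upper = 1)
  array_row <- rep(seq_len(rows) - 1L, each = cols)
  array_col <- as.vector(vapply(seq_len(rows) - 1L, function(r)
    seq(r %% 2L, by = 2L, length.out = cols), integer(cols)))
  n <- length(array_row)
  key <- paste(array_row, array_col)
  nb_idx <- lapply(seq_len(n), function(i) {
    hits <- match(paste(array_row[i] + HEX_OFFSETS[, "dr"],
                        array_col[i] + HEX_OFFSETS[, "dc"]), key)
    hits[!is.na(hits)]
  })
  smooth_field <- function(z) {
    for (pass in seq_len(smoothing)) {
      z <- vapply(seq_len(n), function(i) mean(z[c(i, nb_idx[[i]])]),
                  numeric(1))
    }
    if (sd(z) > 0) z <- (z - mean(z)) / sd(z)
    z
  }
  with_seed(substream_seed(seed, "spatial"), {
    f <- smooth_field(rnorm(n))
    h1 <- smooth_field(rnorm(n))
    h2 <- smooth_field(rnorm(n))
    ar <- sqrt(abs(rho))
    g1 <- ar * f + sqrt(1 - abs(rho)) * h1
    g2 <- sign(rho) * ar * f + sqrt(1 - abs(rho)) * h2
    lam1 <- mean_counts * exp(latent_sd * g1 - latent_sd^2 / 2)
    lam2 <- mean_counts * exp(latent_sd * g2 - latent_sd^2 / 2)
    c1 <- rpois(n, lam1)
    c2 <- rpois(n, lam2)
    keep <- runif(n) >= dropout
    df <- data.frame(barcode = sprintf("spot_%05d", seq_len(n)),
                     array_row = array_row, array_col = array_col,
                     stringsAsFactors = FALSE)
    df[[gene_names[1]]] <- c1
    df[[gene_names[2]]] <- c2
    grid <- spot_grid(df[keep, , drop = FALSE])
    attr(grid, "truth") <- list(rho = rho, latent = cbind(g1, g2)[keep, ],
                                dropout = dropout, seed = seed)
    grid
  })
}

#' Generate a synthetic IHC cell table
#'
#' Multinomial staining intensities per region with a common intensity
#' profile.
#'
#' @param n_regions Number of regions.
#' @param intensity_profile Probability vector over intensities 0..3.
#' @param cells_per_region Length-2 range of cells per region.
#' @param area_mm2 Region area.
#' @param region_kind "epithelial" or "TIL".
#' @param seed Integer seed.
#' @return An \code{\link{ihc_cell_table}}.
#' @export
generate_ihc <- function(n_regions, intensity_profile,
                         cells_per_region = c(100, 300), area_mm2 = 1,
                         region_kind = "epithelial", seed = 1) {
  check_count(n_regions, "n_regions", lower = 1)
  if (length(intensity_profile) != 4 || any(intensity_profile < 0) ||
      abs(sum(intensity_profile) - 1) > 1e-8)
    abort_tme("intensity_profile must be a probability vector over {0,1,2,3}")
  with_seed(substream_seed(seed, "ihc"), {
    rows <- lapply(seq_len(n_regions), function(r) {
      ncell <- sample(seq(cells_per_region[1], cells_per_region[2]), 1)
      data.frame(region_id = sprintf("R%03d", r), region_kind = region_kind,
                 region_area_mm2 = area_mm2,
                 intensity = sample(0:3, ncell, replace = TRUE,
                                    prob = intensity_profile),
                 stringsAsFactors = FALSE)
    })
    ihc_cell_table(do.call(rbind, rows))
  })
}

#' Generate a synthetic TIL density grid
#'
#' Samples each grid's immune-phenotype class from \code{class_mix} and
#' draws (intratumoral, stromal) densities from within-class regions of the
#' density plane, so downstream classification reproduces \code{class_mix}
#' in expectation.
#'
#' @param n_grids Number of grids.
#' @param class_mix Probability vector over (inflamed, excluded, desert).
#' @param seed Integer seed.
#' @return A \code{\link{til_grid}}; the drawn classes are recorded in
#'   \code{attr(, "truth")}.
#' @export
generate_til_grid <- function(n_grids, class_mix, seed = 1) {
  check_count(n_grids, "n_grids", lower = 1)
  if (length(class_mix) != 3 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8)
    abort_tme("class_mix must be a probability vector over (inflamed, excluded, desert)")
  with_seed(substream_seed(seed, "til"), {
    cls <- sample(c("inflamed", "excluded", "desert"), n_grids,
                  replace = TRUE, prob = class_mix)
    intra <- numeric(n_grids); strom <- numeric(n_grids)
    inf <- cls == "inflamed"; exc <- cls == "excluded"; des <- cls == "desert"
    intra[inf] <- runif(sum(inf), 130, 500)
    strom[inf] <- runif(sum(inf), 0, 600)
    intra[exc] <- runif(sum(exc), 0, 129.99)
    strom[exc] <- runif(sum(exc), 260, 800)
    intra[des] <- runif(sum(des), 0, 129.99)
    strom[des] <- runif(sum(des), 0, 259.99)
    grid <- til_grid(data.frame(grid_id = sprintf("G%05d", seq_len(n_grids)),
                                intratumoral_density = intra,
                                stromal_density = strom,
                                stringsAsFactors = FALSE))
    attr(grid, "truth") <- list(classes = cls, class_mix = class_mix,
                                seed = seed)
    grid
  })
}
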