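# TCR clonal-expansion summaries: per-patient clone sizes, the
# Single/Low/High/Hyper size classes, expanded-cell proportions, and their
# patient-level correlation with the anchor gene.

#' Clone sizes per patient
#'
#' Clonal size is the number of cells sharing an identical TCR within a
#' patient (clonotypes are never pooled across patients).
#'
#' @param clonotypes A \code{\link{clonotype_table}}.
#' @param meta Per-cell metadata with columns \code{barcode},
#'   \code{patient_id} (e.g. \code{table$cell_meta}).
#' @param percentile_classes If TRUE, additionally report classes from the
#'   within-dataset size percentiles (top 5% Hyper, top 25% High) instead of
#'   the absolute size bounds.
#' @return data.frame of class \code{clonotype_summary}: patient_id,
#'   clonotype_id, size, size_class.
#' @export
clonotype_sizes <- function(clonotypes, meta, percentile_classes = FALSE) {
  stopifnot(inherits(clonotypes, "clonotype_table"))
  idx <- match(clonotypes$barcode, meta$barcode)
  if (anyNA(idx)) abort_tme("clonotyped cell without patient metadata")
  df <- data.frame(patient_id = meta$patient_id[idx],
                   clonotype_id = clonotypes$clonotype_id,
                   stringsAsFactors = FALSE)
  if (!nrow(df)) {
    out <- data.frame(patient_id = character(), clonotype_id = character(),
                      size = integer(), size_class = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("clonotype_summary", "data.frame")))
  }
  agg <- as.data.frame(table(patient_id = df$patient_id,
                             clonotype_id = df$clonotype_id),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0, , drop = FALSE]
  out <- data.frame(patient_id = agg$patient_id,
                    clonotype_id = agg$clonotype_id,
                    size = as.integer(agg$Freq),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$clonotype_id), , drop = FALSE]
  if (percentile_classes) {
    qs <- quantile(out$size, c(0.75, 0.95), names = FALSE, type = 1)
    out$size_class <- ifelse(out$size == 1, "Single",
                      ifelse(out$size > qs[2], "Hyper",
                      ifelse(out$size > qs[1], "High", "Low")))
  } else {
    out$size_class <- classify_clone_size(out$size)
  }
  rownames(out) <- NULL
  structure(out, class = c("clonotype_summary", "data.frame"))
}

#' Clone-size class
#'
#' Absolute-size rule: 1 = Single, 2-5 = Low, 6-50 = High, >50 = Hyper.
#'
#' @param size Integer vector of clone sizes (>= 1).
#' @return Character vector of classes.
#' @export
classify_clone_size <- function(size) {
  if (any(size < 1) || any(size != round(size)))
    abort_tme("clone sizes must be integers >= 1")
  ifelse(size == 1, "Single",
  ifelse(size <= 5, "Low",
  ifelse(size <= 50, "High", "Hyper")))
}

#' Per-patient expanded-cell proportion
#'
#' Fraction of clonotyped cells that belong to an expanded clone (size >=
#' 2); the denominator is cells with a recovered clonotype, since cells
#' without a TCR cannot be classed. With \code{clone_level = TRUE} the
#' fraction of expanded clones among clones is returned instead.
#'
#' @param summaries A \code{\link{clonotype_sizes}} result.
#' @param clone_level Clone-level instead of cell-level fraction.
#' @return data.frame: patient_id, n_clonotyped_cells, n_clones,
#'   expanded_proportion.
#' @export
expanded_proportion <- function(summaries, clone_level = FALSE) {
  stopifnot(inherits(summaries, "clonotype_summary"))
  pats <- unique(summaries$patient_id)
  out <- do.call(rbind, lapply(pats, function(p) {
    s <- summaries$size[summaries$patient_id == p]
    prop <- if (clone_level) mean(s >= 2) else sum(s[s >= 2]) / sum(s)
    data.frame(patient_id = p, n_clonotyped_cells = sum(s),
               n_clones = length(s), expanded_proportion = prop,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(patient_id = character(), n_clonotyped_cells = integer(),
                      n_clones = integer(), expanded_proportion = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Correlate clonal expansion with the anchor gene
#'
#' Pearson correlation (with permutation p-value) between each patient's
#' expanded-cell proportion and their mean anchor-gene expression.
#'
#' @param proportions \code{\link{expanded_proportion}} output.
#' @param anchor_means Named numeric vector: per-patient anchor pseudobulk
#'   mean (names = patient ids).
#' @param B,seed Permutation settings (see \code{\link{permutation_pvalue}}).
#' @return List: r, p, n_patients.
#' @export
correlate_expansion <- function(proportions, anchor_means, B = 100000,
                                seed = 1) {
  pats <- intersect(proportions$patient_id, names(anchor_means))
  if (length(pats) < 3) abort_tme("need >= 3 patients with both values")
  x <- unname(anchor_means[pats])
  y <- proportions$expanded_proportion[match(pats, proportions$patient_id)]
  pv <- permutation_pvalue(x, y, B = B, seed = seed)
  list(r = pv$r, p = pv$p, n_patients = length(pats))
}
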