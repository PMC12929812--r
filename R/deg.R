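# Wilcoxon rank-sum differential expression between two cell groups, with
# the human (two-sided |log2FC| > 0.5) and mouse (one-sided log2FC > 1.5
# plus 25%-detection) selection rules and gene-set intersection.

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided rank-sum test between two disjoint cell groups on
#' log2-normalized expression. The log2 fold change is the difference of
#' group mean normalized expression (group a minus group b) — exact on the
#' log2(1 + CP10K) scale. Detection percentages come from raw nonzero
#' values. P-values are Bonferroni-adjusted over the genes actually tested.
#'
#' The p-value is exact (full null enumeration of the rank-sum statistic)
#' when both groups have at most \code{exact_limit} cells and the gene has
#' no tied values; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param norm A \code{\link{normalize_expression}} result.
#' @param cells_a,cells_b Disjoint, nonempty barcode vectors.
#' @param min_cells_detected Genes detected (nonzero) in fewer cells than
#'   this across both groups are not tested (default 3).
#' @param exact_limit Largest group size for the exact rank-sum p (default 25).
#' @return data.frame of class \code{deg_records}: gene, log2fc, p_value,
#'   p_adj, pct_a, pct_b. \code{attr(, "m")} is the Bonferroni multiplier.
#' @export
wilcoxon_deg <- function(norm, cells_a, cells_b, min_cells_detected = 3,
                         exact_limit = 25) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!length(cells_a) || !length(cells_b)) abort_tme("empty cell group")
  if (length(intersect(cells_a, cells_b))) abort_tme("cell groups overlap")
  unknown <- setdiff(c(cells_a, cells_b), colnames(norm$values))
  if (length(unknown)) abort_tme("unknown barcodes in cell groups")
  a <- as.matrix(norm$values[, cells_a, drop = FALSE])
  b <- as.matrix(norm$values[, cells_b, drop = FALSE])
  detected <- rowSums(a > 0) + rowSums(b > 0)
  test_idx <- which(detected >= min_cells_detected)
  m <- length(test_idx)
  if (!m) abort_tme("no genes pass the detection filter")
  res <- lapply(test_idx, function(i) {
    va <- a[i, ]; vb <- b[i, ]
    p <- rank_sum_p(va, vb, exact_limit = exact_limit)
    c(log2fc = mean(va) - mean(vb), p_value = p,
      pct_a = mean(va > 0), pct_b = mean(vb > 0))
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = rownames(norm$values)[test_idx],
                    log2fc = res[, "log2fc"],
                    p_value = res[, "p_value"],
                    p_adj = pmin(1, m * res[, "p_value"]),
                    pct_a = res[, "pct_a"], pct_b = res[, "pct_b"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("deg_records", "data.frame"), m = m)
}

# Two-sided rank-sum p for one gene; delegates to stats::wilcox.test.
rank_sum_p <- function(va, vb, exact_limit = 25) {
  if (all(va == va[1]) && all(vb == va[1])) return(1)   # no signal at all
  ties <- anyDuplicated(c(va, vb)) > 0
  use_exact <- !ties && length(va) <= exact_limit && length(vb) <= exact_limit
  suppressWarnings(
    wilcox.test(va, vb, exact = use_exact, correct = TRUE,
                alternative = "two.sided")$p.value)
}

#' Human-cohort DEG filter
#'
#' Two-sided rule: selected iff \code{|log2fc| > fc} and \code{p_adj <
#' alpha} (both strict).
#'
#' @param records \code{\link{wilcoxon_deg}} output.
#' @param fc Log2 fold-change cutoff (default 0.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param two_sided Use \code{|log2fc|} (default TRUE); FALSE restricts to
#'   up-regulation in group a.
#' @return The records with a logical \code{selected} column added.
#' @export
filter_deg_human <- function(records, fc = 0.5, alpha = 0.05, two_sided = TRUE) {
  eff <- if (two_sided) abs(records$log2fc) else records$log2fc
  records$selected <- eff > fc & records$p_adj < alpha
  records
}

#' Mouse-cohort DEG filter
#'
#' One-sided (up-regulated in group a): selected iff \code{log2fc > fc},
#' \code{p_adj < alpha}, and the gene is detected in more than
#' \code{min_pct} of cells in each group.
#'
#' @param records \code{\link{wilcoxon_deg}} output.
#' @param fc Log2 fold-change cutoff (default 1.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_pct Minimum detected fraction per group (default 0.25, strict).
#' @return The records with a logical \code{selected} column added.
#' @export
filter_deg_mouse <- function(records, fc = 1.5, alpha = 0.05, min_pct = 0.25) {
  records$selected <- records$log2fc > fc & records$p_adj < alpha &
    records$pct_a > min_pct & records$pct_b > min_pct
  records
}

#' Intersect selected gene sets
#'
#' @param ... Two or more \code{deg_records} with a \code{selected} column
#'   (or plain character vectors of gene names).
#' @return Sorted character vector: genes selected in every set.
#' @export
intersect_selected <- function(...) {
  sets <- lapply(list(...), function(s) {
    if (is.character(s)) return(s)
    if (!"selected" %in% names(s)) abort_tme("records lack a 'selected' column")
    s$gene[s$selected]
  })
  if (length(sets) < 2) abort_tme("need >= 2 sets to intersect")
  sort(Reduce(intersect, sets))
}
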