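# Patient-level cross-cell-type correlation against an anchor gene:
# pseudobulk profiles, Pearson r with a permutation null, and the
# |r| / p selection rule.

#' Patient x cell-type x gene pseudobulk profile
#'
#' Collapses normalized single-cell expression into per-(patient, cell type)
#' mean profiles. (patient, cell type) pairs with fewer than \code{min_cells}
#' cells are dropped (their means would be unstable).
#'
#' @param norm A \code{\link{normalize_expression}} result.
#' @param min_cells Minimum cells per (patient, cell_type) group.
#' @param genes Optional subset of genes to profile (default: all).
#' @param by Metadata column defining the cell grouping within patient;
#'   \code{"cell_type"} (default) or \code{"subtype"}.
#' @return data.frame of class \code{pseudobulk_profile} with columns
#'   patient_id, cell_type, gene, mean_norm_expr, n_cells. The dropped
#'   groups are recorded in \code{attr(, "dropped")}.
#' @export
pseudobulk <- function(norm, min_cells = 10, genes = NULL, by = "cell_type") {
  stopifnot(inherits(norm, "normalized_matrix"))
  check_count(min_cells, "min_cells", lower = 1)
  meta <- norm$cell_meta
  if (!by %in% names(meta)) abort_tme("unknown grouping column '%s'", by)
  values <- norm$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(values))
    if (length(missing))
      abort_tme("genes absent from matrix: %s",
                paste(utils::head(missing, 5), collapse = ", "))
    values <- values[genes, , drop = FALSE]
  }
  grp <- paste(meta$patient_id, meta[[by]], sep = "\r")
  grp_f <- factor(grp, levels = unique(grp))
  n_cells <- as.vector(table(grp_f)[levels(grp_f)])
  keep <- n_cells >= min_cells
  # group-mean via sparse matrix multiply with a cell x group indicator
  ind <- Matrix::sparseMatrix(
    i = seq_len(ncol(values)), j = as.integer(grp_f),
    x = 1, dims = c(ncol(values), nlevels(grp_f)))
  sums <- values %*% ind
  means <- as.matrix(sums) / rep(n_cells, each = nrow(values))
  parts <- do.call(rbind, strsplit(levels(grp_f), "\r", fixed = TRUE))
  out <- data.frame(
    patient_id = rep(parts[, 1], each = nrow(values)),
    cell_type = rep(parts[, 2], each = nrow(values)),
    gene = rep(rownames(values), nlevels(grp_f)),
    mean_norm_expr = as.vector(means),
    n_cells = rep(n_cells, each = nrow(values)),
    stringsAsFactors = FALSE)
  dropped <- unique(out[!keep[match(paste(out$patient_id, out$cell_type, sep = "\r"),
                                    levels(grp_f))],
                        c("patient_id", "cell_type", "n_cells")])
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  rownames(out) <- NULL
  rownames(dropped) <- NULL
  structure(out, class = c("pseudobulk_profile", "data.frame"),
            dropped = dropped, min_cells = min_cells, by = by)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient, or NA with a warning when either
#'   vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort_tme("x and y must have equal length")
  if (length(x) < 3) abort_tme("need >= 3 observations")
  if (anyNA(x) || anyNA(y)) abort_tme("missing values in correlation input")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided empirical p-value for \code{pearson_r(x, y)} under the
#' exchangeable null: y is permuted relative to x. With \code{exhaustive =
#' TRUE} (or n small enough that \code{factorial(n) <= B}) all n!
#' permutations are enumerated and the p-value is the exact fraction of
#' permutations with \code{|r|} at least the observed; otherwise B uniform
#' random permutations are drawn and p = (1 + #{|r_b| >= |r_obs|}) / (B + 1).
#'
#' @param x,y Numeric vectors (as \code{\link{pearson_r}}).
#' @param B Number of random permutations (default 100,000).
#' @param seed Integer seed (ignored in exhaustive mode).
#' @param exhaustive Force full enumeration (error if n > 8).
#' @return Named list: \code{r}, \code{p}, \code{B_effective},
#'   \code{exhaustive}.
#' @export
permutation_pvalue <- function(x, y, B = 100000, seed = 1, exhaustive = FALSE) {
  r_obs <- pearson_r(x, y)
  if (is.na(r_obs)) return(list(r = NA_real_, p = NA_real_,
                                B_effective = 0L, exhaustive = FALSE))
  n <- length(x)
  check_count(B, "B", lower = 1)
  do_exhaustive <- exhaustive || (n <= 8 && factorial(n) <= B)
  tol <- 1e-12
  if (do_exhaustive) {
    if (n > 8) abort_tme("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(p) cor(x, y[p]))
    p <- mean(abs(r_perm) >= abs(r_obs) - tol)
    return(list(r = r_obs, p = p, B_effective = nrow(perms), exhaustive = TRUE))
  }
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  count <- with_seed(seed, {
    hits <- 0L
    block <- 10000L
    done <- 0L
    while (done < B) {
      nb <- min(block, B - done)
      rb <- vapply(seq_len(nb), function(i) {
        sum(xs * ys[sample.int(n)]) / (n - 1)
      }, numeric(1))
      hits <- hits + sum(abs(rb) >= abs(r_obs) - tol)
      done <- done + nb
    }
    hits
  })
  list(r = r_obs, p = (1 + count) / (B + 1), B_effective = B,
       exhaustive = FALSE)
}

# All permutations of 1..n as a matrix (n! rows); recursion fine for n <= 8.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Z-score a vector of patient-level values
#'
#' @param values Numeric vector (n >= 2, nonzero variance).
#' @return \code{(values - mean) / sd} with the n-1 denominator sd.
#' @export
zscore_patients <- function(values) {
  if (length(values) < 2) abort_tme("need >= 2 patients to z-score")
  s <- sd(values)
  if (s == 0) abort_tme("zero variance: z-score undefined")
  (values - mean(values)) / s
}

#' Cross-cell-type correlation scan against an anchor gene
#'
#' For every (gene, cell type) with at least \code{min_patients} patients
#' shared with the anchor, correlates the patient-level mean expression of
#' the gene in that cell type with the patient-level mean expression of the
#' anchor gene in the anchor cell type. P-values come from a permutation
#' null; a pair is selected when \code{|r| > r_thresh} and
#' \code{p < p_thresh} (both strict). Patients lacking either entry are
#' dropped pairwise.
#'
#' @param profile A \code{\link{pseudobulk}} profile.
#' @param anchor_gene,anchor_cell_type The anchor (e.g. CEBPB in epithelial
#'   cells).
#' @param B Number of permutations (default 100,000).
#' @param r_thresh,p_thresh Selection thresholds (defaults 0.25, 0.05).
#' @param seed Integer seed for the permutation draws.
#' @param min_patients Minimum shared patients per pair (default 3).
#' @return data.frame of class \code{crosscor_records}: gene, cell_type,
#'   n_patients, r, p_perm, selected.
#' @export
cross_celltype_scan <- function(profile, anchor_gene, anchor_cell_type,
                                B = 100000, r_thresh = 0.25, p_thresh = 0.05,
                                seed = 1, min_patients = 3) {
  stopifnot(inherits(profile, "pseudobulk_profile"))
  anchor <- profile[profile$gene == anchor_gene &
                    profile$cell_type == anchor_cell_type, , drop = FALSE]
  if (!nrow(anchor))
    abort_tme("anchor %s / %s absent from profile", anchor_gene, anchor_cell_type)
  x_all <- setNames(anchor$mean_norm_expr, anchor$patient_id)

  records <- list()
  tol <- 1e-12
  for (ct in sort(unique(profile$cell_type))) {
    sub <- profile[profile$cell_type == ct, , drop = FALSE]
    pats <- sort(intersect(unique(sub$patient_id), names(x_all)))
    if (length(pats) < min_patients) next
    gene_names <- sort(unique(sub$gene))
    ymat <- matrix(NA_real_, length(pats), length(gene_names),
                   dimnames = list(pats, gene_names))
    ymat[cbind(match(sub$patient_id, pats), match(sub$gene, gene_names))] <-
      sub$mean_norm_expr
    x <- x_all[pats]
    # genes grouped by identical patient-availability pattern; within a
    # group one shared set of permutations serves every gene
    avail <- !is.na(ymat)
    pattern <- apply(avail, 2, function(z) paste(which(z), collapse = ","))
    for (pat_key in unique(pattern)) {
      idx <- which(avail[, match(pat_key, pattern)])
      if (length(idx) < min_patients) next
      gsel <- gene_names[pattern == pat_key]
      yg <- ymat[idx, gsel, drop = FALSE]
      xg <- x[idx]
      n <- length(idx)
      sdx <- sd(xg)
      sdy <- apply(yg, 2, sd)
      ok <- sdx > 0 & sdy > 0
      r <- rep(NA_real_, length(gsel))
      pp <- rep(NA_real_, length(gsel))
      if (sdx > 0 && any(ok)) {
        xs <- (xg - mean(xg)) / sdx
        ys <- scale(yg[, ok, drop = FALSE])
        r_obs <- as.vector(crossprod(xs, ys)) / (n - 1)
        sub_seed <- substream_seed(seed, paste0("scan:", ct, ":", pat_key))
        hits <- with_seed(sub_seed, {
          h <- integer(length(r_obs))
          block <- 2000L
          done <- 0L
          while (done < B) {
            nb <- min(block, B - done)
            pm <- matrix(0, nb, n)
            for (b in seq_len(nb)) pm[b, ] <- xs[sample.int(n)]
            rb <- abs(pm %*% ys) / (n - 1)
            h <- h + colSums(rb >= rep(abs(r_obs) - tol, each = nb))
            done <- done + nb
          }
          h
        })
        r[ok] <- r_obs
        pp[ok] <- (1 + hits) / (B + 1)
      }
      records[[length(records) + 1L]] <- data.frame(
        gene = gsel, cell_type = ct, n_patients = n,
        r = r, p_perm = pp,
        selected = !is.na(r) & abs(r) > r_thresh & pp < p_thresh,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(gene = character(), cell_type = character(),
               n_patients = integer(), r = numeric(), p_perm = numeric(),
               selected = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$cell_type, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("crosscor_records", "data.frame"),
            anchor_gene = anchor_gene, anchor_cell_type = anchor_cell_type,
            B = B, r_thresh = r_thresh, p_thresh = p_thresh)
}
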