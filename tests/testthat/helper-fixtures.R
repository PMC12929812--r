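# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (dense loops, full enumeration) and never share code
# with the implementation paths they check.

# A tiny hand-built expression table: 3 genes x 4 cells, 2 patients.
tiny_table <- function() {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3, 3), j = c(1, 2, 2, 3, 4), x = c(5, 1, 2, 7, 3),
    dims = c(3, 4),
    dimnames = list(c("CEBPB", "CTLA4", "ACTB"),
                    c("c1", "c2", "c3", "c4")))
  meta <- data.frame(barcode = c("c1", "c2", "c3", "c4"),
                     patient_id = c("P1", "P1", "P2", "P2"),
                     cell_type = c("epithelial", "T", "epithelial", "T"),
                     stringsAsFactors = FALSE)
  cell_expression_table(m, meta)
}

# Random sparse integer expression table for round-trip / oracle tests.
random_table <- function(n_genes = 8, n_cells = 12, seed = 1,
                         genes = sprintf("g%02d", seq_len(n_genes))) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 0.8), n_genes, n_cells,
              dimnames = list(genes, sprintf("cell%03d", seq_len(n_cells))))
  meta <- data.frame(
    barcode = colnames(m),
    patient_id = sample(c("PA", "PB", "PC"), n_cells, replace = TRUE),
    cell_type = sample(c("epithelial", "T"), n_cells, replace = TRUE),
    stringsAsFactors = FALSE)
  cell_expression_table(Matrix::Matrix(m, sparse = TRUE), meta)
}

# Independent exhaustive two-sided permutation p for a Pearson correlation,
# enumerating permutations by lexicographic successor (distinct algorithm
# from the implementation's recursive enumeration).
oracle_perm_p <- function(x, y) {
  n <- length(x)
  perm <- seq_len(n)
  r_obs <- abs(cor(x, y))
  hits <- 0L
  total <- 0L
  repeat {
    total <- total + 1L
    if (abs(cor(x, y[perm])) >= r_obs - 1e-12) hits <- hits + 1L
    # next lexicographic permutation
    i <- n - 1L
    while (i >= 1L && perm[i] >= perm[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (perm[j] <= perm[i]) j <- j - 1L
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    perm[(i + 1L):n] <- rev(perm[(i + 1L):n])
  }
  hits / total
}

# Exhaustive two-sided rank-sum p via enumeration of all group-a index sets.
oracle_wilcoxon_p <- function(va, vb) {
  pooled <- c(va, vb)
  r <- rank(pooled)
  na <- length(va)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Dense group-by mean oracle for pseudobulk.
oracle_pseudobulk <- function(norm, min_cells) {
  dense <- as.matrix(norm$values)
  meta <- norm$cell_meta
  out <- list()
  for (p in unique(meta$patient_id)) for (ct in unique(meta$cell_type)) {
    cells <- meta$barcode[meta$patient_id == p & meta$cell_type == ct]
    if (length(cells) < min_cells) next
    for (g in rownames(dense)) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p, cell_type = ct, gene = g,
        mean_norm_expr = mean(dense[g, cells, drop = TRUE]),
        n_cells = length(cells), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

mk_ihc_acc <- function(intensities) {
  ihc_cell_table(data.frame(region_id = "R1", region_kind = "epithelial",
                            region_area_mm2 = 1, intensity = intensities,
                            stringsAsFactors = FALSE))
}

# Full hexagonal test lattice with one count column per gene.
full_lattice <- function(rows, cols, seed = 1) {
  set.seed(seed)
  ar <- rep(seq_len(rows) - 1L, each = cols)
  ac <- as.vector(vapply(seq_len(rows) - 1L, function(r)
    seq(r %% 2L, by = 2L, length.out = cols), integer(cols)))
  spot_grid(data.frame(barcode = sprintf("s%04d", seq_along(ar)),
                       array_row = ar, array_col = ac,
                       GA = rpois(length(ar), 4), GB = rpois(length(ar), 4),
                       stringsAsFactors = FALSE))
}
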