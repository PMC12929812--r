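test_that("expression tables validate their invariants", {
  tab <- tiny_table()
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(length(tab$counts@x), 5L)

  m <- as.matrix(tab$counts)
  m[1, 1] <- -1
  expect_error(cell_expression_table(Matrix::Matrix(m, sparse = TRUE),
                                     tab$cell_meta),
               "negative count")
  m[1, 1] <- 1.5
  expect_error(cell_expression_table(Matrix::Matrix(m, sparse = TRUE),
                                     tab$cell_meta),
               "non-integer")

  m2 <- tab$counts
  rownames(m2) <- c("A", "A", "B")
  expect_error(cell_expression_table(m2, tab$cell_meta), "duplicate gene")

  meta_bad <- tab$cell_meta
  meta_bad$barcode[2] <- "c1"
  expect_error(cell_expression_table(tab$counts, meta_bad), "duplicate barcode")

  expect_error(cell_expression_table(tab$counts, tab$cell_meta,
                                     cell_types = c("epithelial")),
               "unknown cell_type")
})

test_that("write/read round-trips expression tables exactly", {
  for (seed in 1:3) {
    tab <- random_table(seed = seed)
    d <- withr::local_tempdir()
    write_expression(tab, d)
    back <- read_expression(file.path(d, "matrix.mtx"),
                            file.path(d, "genes.tsv"),
                            file.path(d, "barcodes.tsv"),
                            file.path(d, "cell_meta.tsv"))
    expect_identical(as.matrix(back$counts), as.matrix(tab$counts))
    expect_identical(back$gene_ids, tab$gene_ids)
    expect_identical(back$cell_ids, tab$cell_ids)
    expect_identical(back$cell_meta$patient_id, tab$cell_meta$patient_id)
  }
})

test_that("empty tables and unicode gene names survive the round trip", {
  empty <- cell_expression_table(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(2, 0),
                         dimnames = list(c("g1", "g2"), character(0))),
    data.frame(barcode = character(), patient_id = character(),
               cell_type = character(), stringsAsFactors = FALSE))
  d <- withr::local_tempdir()
  write_expression(empty, d)
  back <- read_expression(file.path(d, "matrix.mtx"),
                          file.path(d, "genes.tsv"),
                          file.path(d, "barcodes.tsv"),
                          file.path(d, "cell_meta.tsv"))
  expect_equal(dim(back), c(2L, 0L))

  uni <- random_table(n_genes = 3, n_cells = 4, seed = 5,
                      genes = c("MT-βactin", "Géne2", "g3"))
  d2 <- withr::local_tempdir()
  write_expression(uni, d2)
  back2 <- read_expression(file.path(d2, "matrix.mtx"),
                           file.path(d2, "genes.tsv"),
                           file.path(d2, "barcodes.tsv"),
                           file.path(d2, "cell_meta.tsv"))
  expect_identical(back2$gene_ids, uni$gene_ids)
})

test_that("mismatched metadata and dimensions are rejected on read", {
  tab <- random_table(seed = 2)
  d <- withr::local_tempdir()
  write_expression(tab, d)
  meta <- read.delim(file.path(d, "cell_meta.tsv"), stringsAsFactors = FALSE)
  meta <- rbind(meta, data.frame(barcode = "ghost", patient_id = "PX",
                                 cell_type = "T", subtype = NA))
  write.table(meta, file.path(d, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(file.path(d, "matrix.mtx"),
                               file.path(d, "genes.tsv"),
                               file.path(d, "barcodes.tsv"),
                               file.path(d, "cell_meta.tsv")),
               "absent from matrix")
  genes <- read.delim(file.path(d, "genes.tsv"))
  write.table(genes[-1, , drop = FALSE], file.path(d, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(file.path(d, "matrix.mtx"),
                               file.path(d, "genes.tsv"),
                               file.path(d, "barcodes.tsv"),
                               file.path(d, "cell_meta.tsv")),
               "dimension mismatch")
})

test_that("clonotype tables validate and round-trip", {
  tab <- tiny_table()
  rec <- data.frame(barcode = c("c2", "c4", "c1"),
                    clonotype_id = c("K1", "K1", "K2"),
                    stringsAsFactors = FALSE)
  ct <- clonotype_table(rec, tab)
  expect_equal(length(unique(ct$clonotype_id)), 2L)

  expect_error(clonotype_table(rbind(rec, rec[1, ]), tab), "duplicate barcode")
  bad <- rbind(rec, data.frame(barcode = "nope", clonotype_id = "K9"))
  expect_error(clonotype_table(bad, tab), "absent from expression")
  expect_warning(ct2 <- clonotype_table(bad, tab, strict = FALSE), "dropping")
  expect_equal(nrow(ct2), 3L)

  p <- withr::local_tempfile(fileext = ".csv")
  write_clonotypes(ct, p)
  back <- read_clonotypes(p, tab)
  expect_identical(as.data.frame(back), as.data.frame(ct))
})

test_that("spot grids enforce the hexagonal parity convention", {
  ok <- data.frame(barcode = c("a", "b"), array_row = c(0, 1),
                   array_col = c(0, 1), CEBPB = c(1, 2), CTLA4 = c(0, 1))
  g <- spot_grid(ok)
  expect_setequal(attr(g, "genes"), c("CEBPB", "CTLA4"))

  bad <- ok; bad$array_col <- c(1, 1)
  expect_error(spot_grid(bad), "even")
  dup <- ok; dup$array_row <- c(0, 0); dup$array_col <- c(2, 2)
  expect_error(spot_grid(dup), "duplicate")

  p <- withr::local_tempfile(fileext = ".tsv")
  write_spots(g, p)
  expect_equal(as.data.frame(read_spots(p)), as.data.frame(g), ignore_attr = TRUE)
})

test_that("IHC and TIL tables validate and round-trip", {
  cells <- data.frame(region_id = "R1", region_kind = "epithelial",
                      region_area_mm2 = 0.5, intensity = c(0, 1, 2, 3))
  tab <- ihc_cell_table(cells)
  expect_s3_class(tab, "ihc_cell_table")
  expect_error(ihc_cell_table(transform(cells, intensity = c(0, 1, 2, 4))),
               "intensity")
  expect_error(ihc_cell_table(transform(cells, region_area_mm2 = 0)),
               "positive")
  p <- withr::local_tempfile(fileext = ".csv")
  write_ihc(tab, p)
  expect_equal(as.data.frame(read_ihc(p)), as.data.frame(tab), ignore_attr = TRUE)

  tg <- til_grid(data.frame(grid_id = c("g1", "g2"),
                            intratumoral_density = c(10, 300),
                            stromal_density = c(5, 100)))
  expect_equal(tg$grid_area_mm2, c(0.25, 0.25))
  expect_error(til_grid(data.frame(grid_id = "g", intratumoral_density = -1,
                                   stromal_density = 0)), "nonnegative")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_til_grid(tg, p2)
  expect_equal(as.data.frame(read_til_grid(p2)), as.data.frame(tg), ignore_attr = TRUE)
})
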