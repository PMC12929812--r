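test_that("cohort generation is deterministic and validates its config", {
  cfg <- cohort_config(n_patients = 6, n_genes = 40,
                       cells_per_patient = c(30, 50))
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(as.matrix(a$table$counts), as.matrix(b$table$counts))
  expect_identical(a$table$cell_meta, b$table$cell_meta)
  expect_identical(as.data.frame(a$clonotypes), as.data.frame(b$clonotypes))
  expect_identical(a$truth$patients, b$truth$patients)

  c2 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(as.matrix(a$table$counts), as.matrix(c2$table$counts)))

  expect_error(cohort_config(cell_type_proportions = c(epithelial = 0.6, T = 0.5)),
               "probability vector")
  expect_error(cohort_config(anchor_mixture = list(weights = c(0.7, 0.7),
                                                   means = c(0, 1),
                                                   sds = c(0.3, 0.3))),
               "summing to 1")
})

test_that("degenerate cohorts are empty but valid", {
  cfg <- cohort_config(n_patients = 0, n_genes = 10)
  out <- generate_cohort(cfg, seed = 1)
  expect_equal(dim(out$table), c(10L, 0L))
  expect_equal(nrow(out$clonotypes), 0L)
  expect_equal(nrow(out$truth$patients), 0L)
})

test_that("planted coupling induces the expected patient-level correlation", {
  cfg <- cohort_config(n_patients = 30, n_genes = 60,
                       coupling = data.frame(gene = "CTLA4", cell_type = "T",
                                             slope = 1.2))
  r_true <- planted_patient_r(cfg, "CTLA4", "T", n_patients = 300, seed = 42)
  expect_gt(r_true, 0.3)

  co <- generate_cohort(cfg, seed = 5)
  norm <- normalize_expression(co$table)
  pb <- pseudobulk(norm, min_cells = 5)
  xa <- pb[pb$gene == "CEBPB" & pb$cell_type == "epithelial", ]
  yt <- pb[pb$gene == "CTLA4" & pb$cell_type == "T", ]
  pats <- intersect(xa$patient_id, yt$patient_id)
  r_hat <- pearson_r(xa$mean_norm_expr[match(pats, xa$patient_id)],
                     yt$mean_norm_expr[match(pats, yt$patient_id)])
  expect_lt(abs(r_hat - r_true), 0.3)  # single 30-patient cohort is noisy
})

test_that("anchor pseudobulk separates the two activity components", {
  cfg <- cohort_config(n_patients = 20, n_genes = 40)
  co <- generate_cohort(cfg, seed = 9)
  norm <- normalize_expression(co$table)
  pb <- pseudobulk(norm, min_cells = 5)
  ap <- pb[pb$gene == "CEBPB" & pb$cell_type == "epithelial", ]
  truth <- co$truth$patients
  comp <- truth$mixture_component[match(ap$patient_id, truth$patient_id)]
  expect_gt(mean(ap$mean_norm_expr[comp == 2]),
            mean(ap$mean_norm_expr[comp == 1]))
})

test_that("slide generator produces a valid lattice with planted correlation", {
  g0 <- generate_slide(8, 8, rho = 0.5, dropout = 0, seed = 3)
  expect_equal(nrow(g0), 64L)
  nb_counts <- vapply(g0$barcode, function(b) length(hex_neighbors(b, g0)),
                      integer(1))
  interior <- g0$array_row >= 1 & g0$array_row <= 6 &
    g0$array_col >= 2 & g0$array_col <= 12
  expect_true(all(nb_counts[interior] == 6L))

  # rho = 1, high counts: near-deterministic co-expression
  g1 <- generate_slide(12, 12, rho = 1, mean_counts = 200, dropout = 0,
                       seed = 4)
  expect_gt(spot_correlation(g1$CEBPB, g1$CTLA4), 0.95)

  # determinism + dropout bounds
  g2 <- generate_slide(8, 8, rho = 0.5, dropout = 0.2, seed = 3)
  g3 <- generate_slide(8, 8, rho = 0.5, dropout = 0.2, seed = 3)
  expect_identical(as.data.frame(g2), as.data.frame(g3))
  expect_lt(nrow(g2), 64L)
})

test_that("IHC generator reproduces forced H-scores and the expectation", {
  all3 <- generate_ihc(3, c(0, 0, 0, 1), seed = 1)
  expect_equal(h_score(all3)$case_score, 300)
  none <- generate_ihc(3, c(1, 0, 0, 0), seed = 1)
  expect_equal(h_score(none)$case_score, 0)
  flat <- generate_ihc(4, c(0.25, 0.25, 0.25, 0.25),
                       cells_per_region = c(20000, 20000), seed = 2)
  expect_lt(abs(h_score(flat)$case_score - 150), 3)
  expect_error(generate_ihc(2, c(0.5, 0.5, 0.5, 0.5)), "probability vector")
})

test_that("TIL grid generator reproduces the class mix downstream", {
  mix <- c(0.5, 0.3, 0.2)
  g <- generate_til_grid(10000, mix, seed = 6)
  sc <- inflamed_score(g)
  expect_true(all(abs(sc$proportions - mix) <= 0.02))
  expect_identical(unname(sc$proportions[c("inflamed", "excluded", "desert")]),
                   unname(sc$proportions))

  all_inf <- generate_til_grid(50, c(1, 0, 0), seed = 1)
  expect_true(all(inflamed_score(all_inf)$classes$ip_class == "inflamed"))
  all_des <- generate_til_grid(50, c(0, 0, 1), seed = 1)
  expect_equal(inflamed_score(all_des)$inflamed_score, 0)
})
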