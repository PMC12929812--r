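test_that("normalization follows the CP10K log2 formula", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(10, 4),
                            dims = c(2, 2),
                            dimnames = list(c("g1", "g2"), c("c1", "c2")))
  meta <- data.frame(barcode = c("c1", "c2"), patient_id = "P1",
                     cell_type = "T", stringsAsFactors = FALSE)
  tab <- cell_expression_table(m, meta)
  norm <- normalize_expression(tab)
  # cell c1: counts (10, 0), total 10 -> gene1 = log2(1 + 10000)
  expect_equal(norm$values["g1", "c1"], log2(10001), tolerance = 1e-12)
  expect_equal(norm$values["g2", "c1"], 0)

  # scale invariance: doubling all counts of a cell changes nothing
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  norm2 <- normalize_expression(cell_expression_table(m2, meta))
  expect_equal(norm2$values[, "c1"], norm$values[, "c1"])

  # all-zero cell: flagged, left all-zero
  m3 <- m; m3[2, 2] <- 0
  expect_warning(norm3 <- normalize_expression(cell_expression_table(m3, meta)),
                 "zero total")
  expect_equal(norm3$zero_cells, "c2")
  expect_true(all(norm3$values[, "c2"] == 0))
})

test_that("EM recovers well-separated mixture components deterministically", {
  set.seed(101)
  x <- c(rnorm(2500, 0, 0.3), rnorm(2500, 2, 0.3))
  fit <- fit_gmm2(x, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu1 - 0), 0.1)
  expect_lt(abs(fit$mu2 - 2), 0.1)
  expect_true(fit$mu1 <= fit$mu2)
  expect_equal(fit$w1 + fit$w2, 1)
  # EM monotonicity of the winning trace
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # determinism
  fit2 <- fit_gmm2(x, seed = 1)
  expect_identical(fit[c("w1", "mu1", "sd1", "mu2", "sd2", "cutoff")],
                   fit2[c("w1", "mu1", "sd1", "mu2", "sd2", "cutoff")])

  # two near-point masses: symmetric weights
  set.seed(7)
  y <- c(rnorm(100, 0, 1e-3), rnorm(100, 2, 1e-3))
  fity <- fit_gmm2(y, seed = 2)
  expect_lt(abs(fity$w1 - 0.5), 0.02)

  expect_error(fit_gmm2(c(1, 2, 3)), "degenerate")
  expect_error(fit_gmm2(rep(1, 10)), "degenerate")
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(55)
  x <- c(rnorm(1500, 0.2, 0.4), rnorm(1000, 2.5, 0.6))
  fit <- fit_gmm2(x, seed = 3)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(fit$loglik - mc$loglik), 1)
  expect_lt(abs(fit$mu1 - min(mc$parameters$mean)), 0.05)
  expect_lt(abs(fit$mu2 - max(mc$parameters$mean)), 0.05)
})

test_that("the cutoff solves the weighted-density equation", {
  mk_fit <- function(w1, mu1, sd1, mu2, sd2) {
    structure(list(w1 = w1, w2 = 1 - w1, mu1 = mu1, sd1 = sd1, mu2 = mu2,
                   sd2 = sd2, converged = TRUE), class = "gmm_fit")
  }
  # equal weights and sds: the midpoint
  expect_equal(gmm_cutoff(mk_fit(0.5, 0, 0.5, 2, 0.5)), 1.0, tolerance = 1e-12)
  # unequal weights, equal sds: closed form 1 + (sd^2/delta) * log(w1/w2)
  expect_equal(gmm_cutoff(mk_fit(0.8, 0, 0.5, 2, 0.5)),
               1 + (0.25 / 2) * log(4), tolerance = 1e-12)
  # identical components: no crossing
  expect_true(is.na(gmm_cutoff(mk_fit(0.5, 1, 0.5, 1, 0.5))))
  # unequal sds: quadratic case, checked against a grid-search root finder
  fit <- mk_fit(0.6, 0.3, 0.4, 2.2, 0.8)
  cut <- gmm_cutoff(fit)
  dens_diff <- function(x) fit$w1 * dnorm(x, fit$mu1, fit$sd1) -
    fit$w2 * dnorm(x, fit$mu2, fit$sd2)
  grid <- seq(1e-4, 6, by = 1e-4)
  sign_flip <- which(diff(sign(dens_diff(grid))) != 0)[1]
  expect_lt(abs(cut - grid[sign_flip]), 2e-4)
  # residual: weighted densities equal at the cutoff
  expect_lt(abs(dens_diff(cut)), 1e-8)
  # smallest positive root is returned
  expect_true(cut > 0)
  expect_true(all(dens_diff(grid[grid < cut - 1e-3]) > 0))

  nc <- mk_fit(0.5, 0, 0.5, 2, 0.5); nc$converged <- FALSE
  expect_error(gmm_cutoff(nc), "converged")
})

test_that("cutoff estimated from data converges to the analytic intersection", {
  set.seed(202)
  x <- c(rnorm(2500, 0, 0.3), rnorm(2500, 2, 0.3))
  fit <- fit_gmm2(x, seed = 1)
  expect_lt(abs(fit$cutoff - 1.0), 0.05)
})

test_that("high/low assignment uses the strict-greater convention", {
  expect_equal(assign_high_low(1.30, 1.23), "high")
  expect_equal(assign_high_low(1.23, 1.23), "low")
  expect_equal(assign_high_low(1.80, 1.73), "high")
  expect_equal(assign_high_low(c(0.5, NA, 2), 1), c("low", NA, "high"))
})

test_that("patient grouping recovers the planted bimodal classes", {
  cfg <- cohort_config(n_patients = 24)
  co <- generate_cohort(cfg, seed = 13)
  norm <- normalize_expression(co$table)
  pb <- pseudobulk(norm, min_cells = 5)
  sel <- co$table$cell_meta$cell_type == "epithelial"
  vals <- as.vector(norm$values["CEBPB", sel])
  # the zero spike would absorb a component; fit the expressing cells
  fit <- fit_gmm2(vals, seed = 1, nonzero_only = TRUE)
  groups <- patient_group(pb, "CEBPB", "epithelial", fit$cutoff)
  truth <- co$truth$patients
  comp <- truth$mixture_component[match(groups$patient_id, truth$patient_id)]
  agreement <- mean((groups$group == "high") == (comp == 2))
  expect_gte(agreement, 0.9)

  expect_error(patient_group(pb, "NOPE", "epithelial", 1), "absent")
})
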