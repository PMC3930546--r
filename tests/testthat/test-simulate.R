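test_that("cohort simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_snps = 60, n_probesets = 6, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$expression, b$expression)
  expect_identical(a$dose_response, b$dose_response)
  expect_identical(a$truth$eqtl_map, b$truth$eqtl_map)

  c2 <- simulate_cohort(sim_config(n_snps = 60, n_probesets = 6, seed = 6))
  expect_false(identical(a$genotypes$calls, c2$genotypes$calls))
  expect_identical(dim(a$genotypes$calls), dim(c2$genotypes$calls))
})

test_that("default cohort shape matches the three-population panel", {
  cfg <- sim_config(n_snps = 40, n_probesets = 4)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$genotypes$calls), 174)
  expect_equal(as.vector(table(cohort$covariates$population)[c("CA", "AA",
                                                               "HCA")]),
               c(60, 54, 60))
  expect_true(all(cohort$covariates$sex %in% c("F", "M")))
  si <- cohort$genotypes$snp_info
  for (cc in unique(si$chr))
    expect_false(is.unsorted(si$pos[si$chr == cc], strictly = TRUE))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_snps = 0), class = "pgx_config_error")
  expect_error(sim_config(fst = 0), class = "pgx_config_error")
  expect_error(sim_config(n_snps = 5, n_cis_eqtl = 4, n_trans_eqtl = 4),
               class = "pgx_config_error")
  expect_error(sim_config(dose_grid = c(1, 1, 2)),
               class = "pgx_config_error")
})

test_that("with fst near 0 sample allele frequencies match the ancestral draw", {
  cfg <- sim_config(n_per_population = c(POP = 5000), n_snps = 50,
                    fst = 1e-10, ld_copy_prob = 0, missing_rate = 0,
                    n_cis_eqtl = 0, n_trans_eqtl = 0, n_pgx_snps = 0,
                    seed = 21)
  g <- simulate_genotypes(cfg)
  f_hat <- colMeans(g$calls) / 2
  p <- g$snp_info$p_anc
  se <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(f_hat - p) < 4.5 * se))
})

test_that("missing_rate controls missingness exactly at the degenerate rate", {
  cfg0 <- sim_config(n_snps = 80, missing_rate = 0, seed = 2)
  expect_false(anyNA(simulate_genotypes(cfg0)$calls))
  cfg1 <- sim_config(n_snps = 80, missing_rate = 0.1, seed = 2)
  rate <- mean(is.na(simulate_genotypes(cfg1)$calls))
  expect_gt(rate, 0.07)
  expect_lt(rate, 0.13)
})

test_that("planted eQTL shifts expression by beta per alternate allele", {
  cfg <- sim_config(n_snps = 100, n_probesets = 8, n_cis_eqtl = 1,
                    n_trans_eqtl = 0, n_pgx_snps = 0, beta_eqtl = 2,
                    sigma_expr = 0.1, missing_rate = 0, seed = 31)
  geno <- simulate_genotypes(cfg)
  truth <- plant_effects(geno, cfg)
  expr <- simulate_expression(geno, truth, cfg)
  g <- geno$calls[, truth$eqtl_map$snp[1]]
  e <- expr[truth$eqtl_map$probeset[1], ]
  slope <- coef(lm(e ~ g))[["g"]]
  expect_equal(slope, 2, tolerance = 0.05)
})

test_that("noiseless expression is exactly baseline plus beta times genotype", {
  cfg <- sim_config(n_snps = 50, n_probesets = 4, n_cis_eqtl = 1,
                    n_trans_eqtl = 0, n_pgx_snps = 0, beta_eqtl = 1.5,
                    sigma_expr = 0, sigma_pop_expr = 0, sigma_sex_expr = 0,
                    missing_rate = 0, seed = 32)
  geno <- simulate_genotypes(cfg)
  truth <- plant_effects(geno, cfg)
  expr <- simulate_expression(geno, truth, cfg)
  g <- geno$calls[, truth$eqtl_map$snp[1]]
  e <- expr[truth$eqtl_map$probeset[1], ]
  fit <- lm(e ~ g)
  expect_equal(unname(coef(fit)["g"]), 1.5, tolerance = 1e-10)
  expect_lt(max(abs(resid(fit))), 1e-10)
  # a probeset with no planted effect is exactly constant
  null_probe <- setdiff(seq_len(4), truth$eqtl_map$probeset)[1]
  expect_lt(diff(range(expr[null_probe, ])), 1e-12)
})

test_that("expression variance decomposes into residual plus offset components", {
  cfg <- sim_config(n_snps = 30, n_probesets = 400, n_cis_eqtl = 0,
                    n_trans_eqtl = 0, n_pgx_snps = 0, sigma_expr = 1,
                    missing_rate = 0, seed = 33)
  geno <- simulate_genotypes(cfg)
  truth <- plant_effects(geno, cfg)
  expr <- simulate_expression(geno, truth, cfg)
  v <- mean(apply(expr, 1, var))
  w <- c(60, 54, 60) / 174
  expected <- 1 + cfg$sigma_pop_expr^2 * (1 - sum(w^2)) +
    0.25 * cfg$sigma_sex_expr^2
  expect_equal(v, expected, tolerance = 0.05)
})

test_that("viability readouts follow the four-parameter logistic", {
  cfg <- sim_config(n_snps = 40, n_probesets = 4, viability_noise_sd = 0,
                    seed = 41)
  cohort <- simulate_cohort(cfg)
  dr <- cohort$dose_response
  one <- dr[dr$sample_id == dr$sample_id[1] & dr$drug == "gemcitabine", ]
  e <- 10^cohort$truth$true_log_ic50[one$sample_id[1], "gemcitabine"]
  expect_equal(one$viability,
               pmax(0, logistic4(one$dose, cfg$hill_slope,
                                 cfg$lower_asymptote, cfg$upper_asymptote,
                                 e)),
               tolerance = 1e-12)
  # midpoint and low-dose asymptote of the generating curve
  expect_equal(logistic4(e, 1, 0.05, 1, e), (0.05 + 1) / 2)
  expect_equal(logistic4(1e-12, 1, 0.05, 1, e), 1, tolerance = 1e-6)
  # slope sign flip reflects the curve about the midpoint response
  x <- 10^seq(-3, 3, length.out = 25)
  expect_equal(logistic4(x, -1, 0.05, 1, e),
               0.05 + 1 - logistic4(x, 1, 0.05, 1, e))
})

test_that("single-population fst->0 genotypes are consistent with HWE", {
  cfg <- sim_config(n_per_population = c(POP = 174), n_snps = 1000,
                    fst = 1e-10, ld_copy_prob = 0, missing_rate = 0,
                    n_cis_eqtl = 0, n_trans_eqtl = 0, n_pgx_snps = 0,
                    seed = 51)
  g <- simulate_genotypes(cfg)$calls
  p <- apply(g, 2, function(col)
    hwe_exact_test(sum(col == 0), sum(col == 1), sum(col == 2)))
  # exact-test P-values are discrete and conservative: the empirical CDF
  # must not exceed the uniform CDF (beyond Monte Carlo error) and must
  # not be more than 2x conservative at moderate thresholds
  for (x in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    frac <- mean(p <= x)
    expect_lt(frac, x + 3 * sqrt(x * (1 - x) / 1000))
    expect_gt(frac, 0.5 * x - 3 * sqrt(x * (1 - x) / 1000))
  }
})

test_that("block copying induces the predicted LD decay", {
  cfg <- sim_config(n_per_population = c(POP = 5000), n_snps = 10,
                    ld_block_size = 5, ld_copy_prob = 0.9, fst = 1e-10,
                    missing_rate = 0, n_cis_eqtl = 0, n_trans_eqtl = 0,
                    n_pgx_snps = 0, seed = 61)
  g <- simulate_genotypes(cfg)$calls
  r2_adj <- ld_r2(g[, 1], g[, 2])
  expect_equal(r2_adj, ld_expected_r2(0.9, 1), tolerance = 0.04)
  r2_lag2 <- ld_r2(g[, 1], g[, 3])
  expect_equal(r2_lag2, ld_expected_r2(0.9, 2), tolerance = 0.05)
  # across a block boundary LD resets
  expect_lt(ld_r2(g[, 5], g[, 6]), 0.05)
})
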