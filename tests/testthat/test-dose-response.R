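test_that("noiseless 4PL parameters are recovered to high precision", {
  doses <- 10^seq(-3, 2, length.out = 8)
  truth <- list(b = 1, c = 0.1, d = 1.0, e = 0.5)
  v <- logistic4(doses, truth$b, truth$c, truth$d, truth$e)
  fit <- fit_logistic(doses, v, model = "4PL")
  expect_true(fit$converged)
  for (p in names(truth))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("degenerate curves are flagged, not silently fitted", {
  doses <- 10^seq(-2, 2)
  fit <- fit_logistic(doses, rep(1, length(doses)))
  expect_false(fit$converged)
  expect_warning(ic <- estimate_ic50(fit), "did not converge")
  expect_true(is.na(ic))
  expect_error(fit_logistic(c(1, 10, 100), c(1, 0.5, 0.1), model = "4PL"),
               class = "pgx_insufficient_data")
  expect_error(fit_logistic(c(-1, 1, 10, 100), c(1, 0.9, 0.5, 0.1)),
               class = "pgx_domain_error")
})

test_that("multi-start least squares matches a dense grid-search oracle", {
  set.seed(71)
  doses <- rep(10^seq(-3, 2, length.out = 8), 2)
  v <- logistic4(doses, 1.3, 0.08, 1.02, 0.7) + rnorm(length(doses), 0, 0.05)
  fit <- fit_logistic(doses, v, model = "4PL")
  grid <- expand.grid(b = seq(0.4, 2.5, length.out = 12),
                      c = seq(0, 0.3, length.out = 7),
                      d = seq(0.8, 1.2, length.out = 9),
                      e = 10^seq(-3, 2, length.out = 25))
  rss <- mapply(function(b, c, d, e) sum((v - logistic4(doses, b, c, d, e))^2),
                grid$b, grid$c, grid$d, grid$e)
  expect_lte(fit$rss, min(rss) * 1.01)
})

test_that("IC50 extraction returns the midpoint and respects dose units", {
  doses <- 10^seq(-3, 2, length.out = 8)
  v <- logistic4(doses, 1, 0.1, 1, 0.5)
  fit <- fit_logistic(doses, v, model = "4PL")
  expect_equal(estimate_ic50(fit), 0.5, tolerance = 1e-6)
  # fitted response at the midpoint dose is halfway between the asymptotes
  expect_equal(logistic4(fit$e, fit$b, fit$c, fit$d, fit$e),
               (fit$c + fit$d) / 2, tolerance = 1e-10)
  # rescaling all doses by 10 rescales the IC50 by 10
  fit10 <- fit_logistic(doses * 10, v, model = "4PL")
  expect_equal(estimate_ic50(fit10), 5, tolerance = 1e-5)
  # absolute mode: dose at which the curve crosses 50% of control
  abs50 <- estimate_ic50(fit, type = "absolute")
  expect_equal(logistic4(abs50, fit$b, fit$c, fit$d, fit$e), 0.5,
               tolerance = 1e-8)
})

test_that("AIC model selection prefers 3PL when the true lower asymptote is 0", {
  set.seed(72)
  doses <- 10^seq(-3, 2, length.out = 8)
  picks <- replicate(60, {
    v <- logistic4(doses, 1, 0, 1, 0.5) + rnorm(8, 0, 0.05)
    fit_logistic(doses, v, model = "auto")$model
  })
  expect_gte(mean(picks == "3PL"), 0.5)
})

test_that("log10 phenotype transform and its domain checks work", {
  expect_equal(transform_phenotype(c(1, 10, 100), "log10"), c(0, 1, 2))
  expect_error(transform_phenotype(c(1, -2), "log10"),
               class = "pgx_domain_error")
  expect_equal(transform_phenotype(c(5, NA, 50), "log10"),
               c(log10(5), NA, log10(50)))
})

test_that("van der Waerden transform maps ranks to normal quantiles", {
  expect_equal(transform_phenotype(c(3, 1, 2), "vdw"),
               qnorm(c(3, 1, 2) / 4))
  expect_equal(qnorm(0.75), 0.6744898, tolerance = 1e-6)
  # odd-length tie-free vector: the median maps to 0
  x <- c(10, 2, 7, 30, 4)
  expect_equal(transform_phenotype(x, "vdw")[x == 7], 0)
  # empirical mean is 0 for tie-free input
  set.seed(73)
  y <- rnorm(51)
  expect_equal(mean(transform_phenotype(y, "vdw")), 0, tolerance = 1e-10)
  # ties get average ranks
  expect_equal(transform_phenotype(c(1, 1, 2), "vdw"),
               qnorm(c(1.5, 1.5, 3) / 4))
  # missing values propagate without disturbing the rest
  z <- c(5, NA, 1, 9)
  expect_equal(transform_phenotype(z, "vdw"),
               c(qnorm(2 / 4), NA, qnorm(1 / 4), qnorm(3 / 4)))
  expect_error(transform_phenotype(c(1, NA), "vdw"),
               class = "pgx_insufficient_data")
})

test_that("vdw output is invariant under strictly monotone input transforms", {
  set.seed(74)
  for (i in 1:5) {
    x <- rnorm(40)
    base <- transform_phenotype(x, "vdw")
    expect_equal(transform_phenotype(exp(x), "vdw"), base)
    expect_equal(transform_phenotype(x^3, "vdw"), base)
    expect_equal(transform_phenotype(rank(x), "vdw"), base)
  }
})

test_that("fit_ic50_table handles a mixed table and flags failures", {
  cohort <- simulate_cohort(sim_config(n_snps = 40, n_probesets = 4,
                                       n_per_population = c(CA = 8),
                                       seed = 75))
  tab <- fit_ic50_table(cohort$dose_response)
  expect_equal(nrow(tab), 8 * 2)
  expect_true(all(tab$converged))
  expect_equal(tab$ic50, tab$e)
  # a flat curve in the table yields a non-converged row, not an error
  flat <- data.frame(sample_id = "Sflat", drug = "gemcitabine",
                     dose = 10^seq(-2, 2), viability = 1)
  tab2 <- fit_ic50_table(rbind(cohort$dose_response, flat))
  expect_false(tab2$converged[tab2$sample_id == "Sflat"])
  expect_true(is.na(tab2$ic50[tab2$sample_id == "Sflat"]))
})
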