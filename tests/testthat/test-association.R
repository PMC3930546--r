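test_that("partial correlation with intercept-only design is plain Pearson", {
  set.seed(101)
  x <- rnorm(40)
  expect_equal(partial_pearson(x, 2 * x + 1)$r, 1)
  for (i in 1:5) {
    a <- rnorm(40); b <- rnorm(40)
    expect_equal(partial_pearson(a, b)$r, cor(a, b), tolerance = 1e-12)
  }
})

test_that("collinearity with the design yields an undefined-correlation signal", {
  cohort <- fixture_cohort()
  d <- build_design(cohort$covariates, include_eigenvectors = FALSE)
  y <- d$X[, 2]  # a design column
  x <- rnorm(nrow(d$X))
  expect_true(is.na(partial_pearson(x, y, d)$r))
})

test_that("partial correlation matches the explicit least-squares oracle", {
  set.seed(102)
  for (i in 1:10) {
    Z <- matrix(rnorm(30 * 3), ncol = 3)
    x <- rnorm(30) + Z %*% c(1, -1, 0.5)
    y <- rnorm(30) + Z %*% c(0.3, 0.2, -0.7) + 0.4 * x
    got <- partial_pearson(as.numeric(x), as.numeric(y), cbind(1, Z))
    expect_equal(got$r, oracle_partial_r(as.numeric(x), as.numeric(y), Z),
                 tolerance = 1e-10)
    expect_equal(got$n, 30L)
  }
})

test_that("missing values restrict to complete cases per pair", {
  set.seed(103)
  x <- rnorm(50); y <- rnorm(50)
  x[c(3, 7)] <- NA; y[c(7, 11)] <- NA
  got <- partial_pearson(x, y)
  expect_equal(got$n, 47L)
  cc <- complete.cases(x, y)
  expect_equal(got$r, cor(x[cc], y[cc]), tolerance = 1e-12)
})

test_that("Wald test has the right null center, monotonicity and df", {
  w0 <- wald_pvalue(0, 100, 3)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  rs <- seq(0.05, 0.9, by = 0.05)
  ps <- vapply(rs, function(r) wald_pvalue(r, 60, 5)$p, numeric(1))
  expect_false(is.unsorted(rev(ps), strictly = TRUE))
  # k = 0 reproduces the classical correlation t-test
  set.seed(104)
  x <- rnorm(25); y <- rnorm(25) + 0.5 * x
  ct <- cor.test(x, y)
  w <- wald_pvalue(cor(x, y), 25, 0)
  expect_equal(w$t, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(w$p, ct$p.value, tolerance = 1e-10)
  expect_warning(w1 <- wald_pvalue(1, 20, 0), "smallest representable")
  expect_lt(w1$p, 1e-300)
  expect_error(wald_pvalue(0.5, 5, 5), class = "pgx_insufficient_data")
})

test_that("Wald P for a top-hit-sized correlation matches the t-CDF oracle", {
  # r = 0.391, n = 174, k = 8 (race + sex + 5 eigenvectors)
  w <- wald_pvalue(0.391, 174, 8)
  tt <- 0.391 * sqrt((174 - 2 - 8) / (1 - 0.391^2))
  oracle <- 2 * pt(-tt, 164)
  expect_equal(w$p, oracle, tolerance = 1e-12)
  expect_equal(signif(w$p, 3), signif(oracle, 3))
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is forced to 1", {
  set.seed(105)
  p <- runif(500)^1.5
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(q$q, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(storey_qvalues(rep(1, 200))$q, rep(1, 200))
})

test_that("pi0 smoother is near 1 on uniform nulls and q-values stay large", {
  set.seed(106)
  p <- runif(1e4)
  res <- storey_qvalues(p)
  expect_gt(res$pi0, 0.9)
  expect_lte(res$pi0, 1.1)
  expect_gt(min(res$q), 0.2)
})

test_that("q-values are monotone in p and invariant to input order", {
  set.seed(107)
  p <- c(runif(300)^3, runif(300))
  q <- storey_qvalues(p)$q
  o <- order(p)
  expect_false(is.unsorted(q[o]))
  perm <- sample(length(p))
  q2 <- storey_qvalues(p[perm])$q
  expect_equal(q2, q[perm], tolerance = 1e-12)
  expect_message(storey_qvalues(runif(10)), "conservative")
  expect_error(storey_qvalues(c(0.5, 0)), class = "pgx_domain_error")
})

test_that("the scan fast path agrees with per-predictor partial correlations", {
  cohort <- fixture_cohort()
  calls <- cohort$genotypes$calls[, 1:40]
  ev <- compute_eigenvectors(cohort$genotypes$calls, 5)
  d <- build_design(cohort$covariates, eigenvectors = ev)
  y <- cohort$truth$true_log_ic50[, "gemcitabine"]
  scan <- suppressMessages(association_scan(calls, y, d))
  for (j in c(1, 7, 23, 40)) {
    pp <- partial_pearson(calls[, j], y, d)
    expect_equal(scan$r[j], pp$r, tolerance = 1e-10)
    expect_equal(scan$n[j], pp$n)
  }
  expect_equal(scan$k[1], 8)
})

test_that("scans tolerate empty input and per-predictor failure", {
  y <- rnorm(30)
  empty <- association_scan(matrix(numeric(0), nrow = 30, ncol = 0), y)
  expect_equal(nrow(empty), 0)
  X <- cbind(good = rnorm(30), allna = NA_real_)
  scan <- suppressMessages(association_scan(X, y))
  expect_false(is.na(scan$r[1]))
  expect_true(is.na(scan$r[2]))
  expect_true(is.na(scan$q[2]))
})

test_that("a planted pharmacogenomic SNP tops the scan", {
  cohort <- fixture_cohort()
  ev <- compute_eigenvectors(cohort$genotypes$calls, 5)
  d <- build_design(cohort$covariates, eigenvectors = ev)
  y <- cohort$truth$true_log_ic50[, "gemcitabine"]
  scan <- suppressMessages(association_scan(cohort$genotypes$calls, y, d,
                                            sort_by_p = TRUE))
  planted <- cohort$truth$pgx_snps$snp_id
  expect_true(scan$predictor_id[1] %in% c(planted,
    # LD partners of a planted SNP share its block
    cohort$genotypes$snp_info$snp_id[
      cohort$genotypes$snp_info$block %in%
        cohort$genotypes$snp_info$block[
          match(planted, cohort$genotypes$snp_info$snp_id)]]))
  expect_lt(scan$p[1], 1e-4)
})
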