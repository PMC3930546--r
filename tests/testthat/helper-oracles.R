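# Independent oracles used by the unit and acceptance tests.  These
# deliberately re-derive each quantity by a different route than the
# package implementation.

# partial correlation via explicit least-squares residualization with
# solve(), not lm.fit/QR
oracle_partial_r <- function(x, y, Z) {
  cc <- complete.cases(x, y, Z)
  x <- x[cc]; y <- y[cc]; Z <- cbind(1, Z[cc, , drop = FALSE])
  beta_x <- solve(t(Z) %*% Z, t(Z) %*% x)
  beta_y <- solve(t(Z) %*% Z, t(Z) %*% y)
  rx <- x - Z %*% beta_x
  ry <- y - Z %*% beta_y
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# exact HWE p-value by direct log-gamma enumeration of the conditional
# distribution of heterozygote counts
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n0 + n1
  nb <- 2 * n2 + n1
  if (na == 0 || nb == 0) return(1)
  het <- seq(na %% 2, min(na, nb), by = 2)
  lp <- lgamma(n + 1) - lgamma((na - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((nb - het) / 2 + 1) + het * log(2) +
    lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pobs <- pr[match(n1, het)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

# brute-force locus construction: explicit iteration, re-filtering the
# candidate table from scratch at every step
oracle_define_loci <- function(assoc, snp_info, p_strong = 1e-4,
                               p_weak = 1e-3, half_window = 1e5) {
  d <- merge(assoc, snp_info, by.x = "predictor_id", by.y = "snp_id")
  d <- d[order(d$p, d$chr, d$pos), ]
  d$taken <- FALSE
  d$dead_seed <- FALSE
  out <- list()
  repeat {
    seeds <- d[!d$taken & !d$dead_seed & d$p < p_strong, , drop = FALSE]
    if (nrow(seeds) == 0) break
    s <- seeds[1, ]
    win <- d[!d$taken & d$chr == s$chr &
               d$pos >= s$pos - half_window &
               d$pos <= s$pos + half_window & d$p < p_weak, ,
             drop = FALSE]
    strong <- sum(win$p < p_strong)
    if (strong >= 2 || (strong >= 1 && nrow(win) - strong >= 3)) {
      out[[length(out) + 1]] <- list(seed = s$predictor_id,
                                     members = sort(win$predictor_id))
      d$taken[d$predictor_id %in% win$predictor_id] <- TRUE
    } else {
      d$dead_seed[d$predictor_id == s$predictor_id] <- TRUE
    }
  }
  out
}

# random association table on a small genome for locus-rule fuzzing
random_locus_instance <- function(n_snps, seed) {
  set.seed(seed)
  snp_info <- data.frame(
    snp_id = sprintf("s%04d", seq_len(n_snps)),
    chr = as.character(sample.int(4, n_snps, replace = TRUE)),
    pos = sample.int(2e6, n_snps, replace = TRUE),
    stringsAsFactors = FALSE)
  # heavy lower tail so that loci actually form
  p <- 10^runif(n_snps, -7, 0)
  assoc <- data.frame(predictor_id = snp_info$snp_id, p = p,
                      r = runif(n_snps, -0.5, 0.5),
                      stringsAsFactors = FALSE)
  list(assoc = assoc, snp_info = snp_info)
}

# small complete fixture cohort shared across tests (cheap to build)
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_snps = 300, n_probesets = 15,
                                           seed = 11))
    cache
  }
})

# analytic size of the exact HWE test at level alpha for sample size n and
# ancestral frequency f ~ Uniform(flo, fhi): conditional on the minor allele
# count the test is exact, so the size is the expectation over allele counts
# of the conditional rejection probability
oracle_hwe_size <- function(n, alpha, flo = 0.05, fhi = 0.95,
                            n_f_grid = 200) {
  cond_reject <- vapply(0:n, function(na) {   # na = minor allele count
    if (na == 0) return(0)
    het <- seq(na %% 2, na, by = 2)
    lp <- lgamma(n + 1) - lgamma((na - het) / 2 + 1) - lgamma(het + 1) -
      lgamma(n - (na + het) / 2 + 1) + het * log(2) +
      lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    pv <- vapply(pr, function(p0) sum(pr[pr <= p0 * (1 + 1e-12)]),
                 numeric(1))
    sum(pr[pv < alpha])
  }, numeric(1))
  fs <- seq(flo, fhi, length.out = n_f_grid)
  size_f <- vapply(fs, function(f) {
    cnt <- rbind(dbinom(0:n, 2 * n, f), dbinom(2 * n - (0:n), 2 * n, f))
    # fold allele counts to the minor side; count n (=2n-n) only once
    w <- colSums(cnt)
    w[length(w)] <- w[length(w)] / 2
    sum(w * cond_reject)
  }, numeric(1))
  mean(size_f)
}
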