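#' Simulation configuration for a synthetic LCL pharmacogenomic cohort
#'
#' Builds and validates the configuration used by [simulate_cohort()] and the
#' individual generators.  The defaults emulate a three-population
#' lymphoblastoid cell line panel (60 Caucasian-American, 54 African-American,
#' 60 Han Chinese-American; 174 samples) with population-differentiated allele
#' frequencies, optional block LD, planted cis-/trans-eQTLs, and drug IC50
#' variation driven by genotype and expression.
#'
#' Planted effect sizes default to values that give an expected partial
#' correlation of about 0.4 at n = 174 for each association leg (the magnitude
#' typical of top hits in LCL pharmacogenomic scans), computed at a reference
#' minor allele frequency of 0.4; see [effect_for_r()].
#'
#' @param n_per_population named integer vector of samples per population
#'   label.
#' @param n_snps,n_probesets panel dimensions.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param missing_rate per-call missingness probability in \[0, 1).
#' @param ld_block_size number of consecutive SNPs per LD block.
#' @param ld_copy_prob within-block allele-copy probability in \[0, 1\];
#'   adjacent SNPs in a block have expected genotype r^2 = `ld_copy_prob^2`
#'   (see [ld_expected_r2()]).
#' @param n_cis_eqtl,n_trans_eqtl number of planted cis-/trans-eQTL pairs.
#'   Each planted eQTL pair is a full "triad" plant: its probeset also drives
#'   IC50 (`gamma_expr`) and its SNP carries a direct effect (`gamma_snp`).
#' @param n_pgx_snps number of additional planted SNPs with a direct IC50
#'   effect only (no eQTL), used for scan power studies.
#' @param beta_eqtl expression shift per alternate allele (expression units).
#' @param gamma_snp log10-IC50 shift per alternate allele.
#' @param gamma_expr log10-IC50 shift per expression standard deviation.
#' @param sigma_expr,sigma_ic50 residual SDs of expression and log10 IC50.
#' @param sigma_pop_expr,sigma_sex_expr SDs of per-probeset population and sex
#'   offsets on expression.
#' @param sigma_pop_ic50 SD of per-population offsets on log10 IC50 (the
#'   stratification signal the eigenvector adjustment exists to remove).
#' @param drugs character vector of drug names.
#' @param mu_log_ic50 named numeric, baseline log10 IC50 per drug (dose units
#'   are those of `dose_grid`).
#' @param dose_grid ordered positive concentrations assayed per curve.
#' @param n_replicates viability readouts per dose (triplicate wells by
#'   default, the usual MTS assay layout).
#' @param viability_noise_sd SD of viability replicate noise.
#' @param hill_slope,lower_asymptote,upper_asymptote logistic curve parameters
#'   used to generate viability readouts.
#' @param n_chromosomes chromosomes over which SNPs are laid out.
#' @param seed integer seed; identical configurations give identical cohorts.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_population = c(CA = 60, AA = 54, HCA = 60),
                       n_snps = 1000,
                       n_probesets = 50,
                       fst = 0.02,
                       missing_rate = 0.01,
                       ld_block_size = 5,
                       ld_copy_prob = 0.8,
                       n_cis_eqtl = 1,
                       n_trans_eqtl = 1,
                       n_pgx_snps = 1,
                       beta_eqtl = effect_for_r(0.4, sigma = sigma_expr),
                       gamma_snp = effect_for_r(0.4, sigma = sigma_ic50),
                       gamma_expr = effect_for_r(0.4, sigma = sigma_ic50,
                                                 per_allele = FALSE),
                       sigma_expr = 1,
                       sigma_ic50 = 0.25,
                       sigma_pop_expr = 0.3,
                       sigma_sex_expr = 0.1,
                       sigma_pop_ic50 = 0.15,
                       drugs = c("gemcitabine", "araC"),
                       mu_log_ic50 = c(gemcitabine = -1.5, araC = -0.5),
                       dose_grid = 10^seq(-4, 3),
                       n_replicates = 3,
                       viability_noise_sd = 0.05,
                       hill_slope = 1,
                       lower_asymptote = 0.05,
                       upper_asymptote = 1,
                       n_chromosomes = 22,
                       seed = 1L) {
  cfg <- list(n_per_population = n_per_population, n_snps = as.integer(n_snps),
              n_probesets = as.integer(n_probesets), fst = fst,
              missing_rate = missing_rate,
              ld_block_size = as.integer(ld_block_size),
              ld_copy_prob = ld_copy_prob,
              n_cis_eqtl = as.integer(n_cis_eqtl),
              n_trans_eqtl = as.integer(n_trans_eqtl),
              n_pgx_snps = as.integer(n_pgx_snps),
              beta_eqtl = beta_eqtl, gamma_snp = gamma_snp,
              gamma_expr = gamma_expr, sigma_expr = sigma_expr,
              sigma_ic50 = sigma_ic50, sigma_pop_expr = sigma_pop_expr,
              sigma_sex_expr = sigma_sex_expr, sigma_pop_ic50 = sigma_pop_ic50,
              drugs = drugs, mu_log_ic50 = mu_log_ic50,
              dose_grid = dose_grid,
              n_replicates = as.integer(n_replicates),
              viability_noise_sd = viability_noise_sd,
              hill_slope = hill_slope, lower_asymptote = lower_asymptote,
              upper_asymptote = upper_asymptote,
              n_chromosomes = as.integer(n_chromosomes),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) pgx_stop(msg, "pgx_config_error")
  if (length(cfg$n_per_population) < 1 || any(cfg$n_per_population < 1))
    bad("n_per_population must contain positive counts")
  if (is.null(names(cfg$n_per_population)))
    bad("n_per_population must be a named vector of population labels")
  if (cfg$n_snps < 1) bad("n_snps must be >= 1")
  if (cfg$n_probesets < 1) bad("n_probesets must be >= 1")
  if (!(cfg$fst > 0 && cfg$fst < 1)) bad("fst must lie in (0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    bad("missing_rate must lie in [0, 1)")
  if (cfg$ld_block_size < 1) bad("ld_block_size must be >= 1")
  if (cfg$ld_copy_prob < 0 || cfg$ld_copy_prob > 1)
    bad("ld_copy_prob must lie in [0, 1]")
  n_planted <- cfg$n_cis_eqtl + cfg$n_trans_eqtl + cfg$n_pgx_snps
  if (n_planted > cfg$n_snps)
    bad("planted effects exceed n_snps")
  if (cfg$n_cis_eqtl + cfg$n_trans_eqtl > cfg$n_probesets)
    bad("planted eQTLs exceed n_probesets")
  sds <- c(cfg$sigma_expr, cfg$sigma_ic50, cfg$viability_noise_sd,
           cfg$sigma_pop_expr, cfg$sigma_sex_expr, cfg$sigma_pop_ic50)
  if (any(sds < 0))
    bad("SDs must be non-negative")
  if (any(cfg$dose_grid <= 0) || is.unsorted(cfg$dose_grid, strictly = TRUE))
    bad("dose_grid must be strictly increasing and positive")
  if (cfg$n_replicates < 1) bad("n_replicates must be >= 1")
  if (!all(cfg$drugs %in% names(cfg$mu_log_ic50)))
    bad("mu_log_ic50 must name every drug")
  if (cfg$upper_asymptote <= cfg$lower_asymptote)
    bad("upper_asymptote must exceed lower_asymptote")
  invisible(cfg)
}

#' Effect size giving a target correlation
#'
#' Converts a target (partial) Pearson correlation into the additive effect
#' size that attains it in the generator's linear model, at a reference minor
#' allele frequency.  For a per-allele effect `b` on an outcome with residual
#' SD `sigma`, the induced correlation is
#' `b * sd_g / sqrt(b^2 * sd_g^2 + sigma^2)` with
#' `sd_g = sqrt(2 * maf * (1 - maf))`; for an effect per outcome SD
#' (`per_allele = FALSE`) the genotype SD drops out.
#'
#' @param r target correlation in (-1, 1).
#' @param sigma residual SD of the outcome.
#' @param maf reference minor allele frequency (default 0.4).
#' @param per_allele if `TRUE` (default) the effect is per alternate allele.
#' @return the effect size (numeric scalar).
#' @export
effect_for_r <- function(r, sigma = 1, maf = 0.4, per_allele = TRUE) {
  stopifnot(abs(r) < 1, sigma > 0, maf > 0, maf < 1)
  slope <- r / sqrt(1 - r^2) * sigma
  if (per_allele) slope / sqrt(2 * maf * (1 - maf)) else slope
}

#' Expected genotype r-squared between block-copied SNPs
#'
#' Under the generator's LD model (within a block each haplotype allele copies
#' the previous SNP's allele with probability `copy_prob`, else draws fresh
#' from the block frequency), the genotype correlation at lag `lag` is
#' `copy_prob^lag`, hence r^2 = `copy_prob^(2 * lag)`.
#'
#' @param copy_prob within-block allele-copy probability.
#' @param lag number of SNP steps separating the pair (same block).
#' @return expected squared genotype correlation.
#' @export
ld_expected_r2 <- function(copy_prob, lag = 1) copy_prob^(2 * lag)

# RNG offsets: every generator op seeds its own stream from config$seed so
# that ops are reproducible standalone and simulate_cohort is deterministic.
.seed_genotypes <- 0L
.seed_truth <- 1L
.seed_expression <- 2L
.seed_ic50 <- 3L
.seed_viability <- 4L

#' Simulate multi-population genotypes under the Balding-Nichols model
#'
#' Each LD block draws an ancestral allele frequency from Uniform(0.05, 0.95);
#' each population draws a block frequency from a Beta distribution with mean
#' `p` and variance `p * (1 - p) * fst`.  Haplotype alleles within a block
#' copy the previous SNP's allele with probability `ld_copy_prob` (inducing
#' geometric LD decay), and genotypes are the sum of two haplotype chains.
#' Missing calls are masked at rate `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return a list with components
#'   \describe{
#'     \item{calls}{integer sample x SNP matrix in \{0, 1, 2, NA\}.}
#'     \item{snp_info}{data.frame with `snp_id`, `chr`, `pos`, `ref`, `alt`,
#'       `p_anc` (ancestral frequency), `block`.}
#'     \item{samples}{data.frame with `sample_id`, `population`, `sex`.}
#'   }
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_genotypes)
  n_pop <- config$n_per_population
  n <- sum(n_pop)
  m <- config$n_snps
  pops <- rep(names(n_pop), n_pop)

  block <- ceiling(seq_len(m) / config$ld_block_size)
  n_block <- max(block)
  chr_of_block <- ((seq_len(n_block) - 1L) %% config$n_chromosomes) + 1L
  chr <- chr_of_block[block]
  # strictly increasing positions within chromosome: cumulative random gaps
  pos <- integer(m)
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    pos[idx] <- cumsum(round(runif(length(idx), 2e3, 2e4)))
  }

  p_anc_block <- runif(n_block, 0.05, 0.95)
  p_anc <- p_anc_block[block]

  calls <- matrix(0L, nrow = n, ncol = m)
  row0 <- 0L
  for (k in seq_along(n_pop)) {
    nk <- n_pop[k]
    if (config$fst < 1e-9) {
      p_blk <- p_anc_block
    } else {
      shape <- (1 - config$fst) / config$fst
      p_blk <- rbeta(n_block, p_anc_block * shape,
                     (1 - p_anc_block) * shape)
      # keep blocks polymorphic enough to be usable downstream
      p_blk <- pmin(pmax(p_blk, 1e-4), 1 - 1e-4)
    }
    p_snp <- p_blk[block]
    if (config$ld_copy_prob == 0) {
      g <- matrix(rbinom(nk * m, 2L, rep(p_snp, each = nk)),
                  nrow = nk, ncol = m)
    } else {
      g <- matrix(0L, nrow = nk, ncol = m)
      h1 <- h2 <- matrix(0L, nrow = nk, ncol = m)
      for (j in seq_len(m)) {
        fresh1 <- rbinom(nk, 1L, p_snp[j])
        fresh2 <- rbinom(nk, 1L, p_snp[j])
        if (j > 1L && block[j] == block[j - 1L]) {
          cp1 <- rbinom(nk, 1L, config$ld_copy_prob)
          cp2 <- rbinom(nk, 1L, config$ld_copy_prob)
          h1[, j] <- ifelse(cp1 == 1L, h1[, j - 1L], fresh1)
          h2[, j] <- ifelse(cp2 == 1L, h2[, j - 1L], fresh2)
        } else {
          h1[, j] <- fresh1
          h2[, j] <- fresh2
        }
      }
      g <- h1 + h2
    }
    calls[row0 + seq_len(nk), ] <- g
    row0 <- row0 + nk
  }

  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * m) < config$missing_rate, nrow = n)
    calls[miss] <- NA_integer_
  }

  alleles <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                    ncol = 2, byrow = TRUE)
  al <- alleles[sample.int(4L, m, replace = TRUE), , drop = FALSE]
  snp_info <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chr = as.character(chr), pos = pos,
    ref = al[, 1], alt = al[, 2],
    p_anc = p_anc, block = block,
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    population = pops,
    sex = c("F", "M")[rbinom(n, 1L, 0.5) + 1L],
    stringsAsFactors = FALSE)
  dimnames(calls) <- list(samples$sample_id, snp_info$snp_id)
  list(calls = calls, snp_info = snp_info, samples = samples)
}

#' Plant ground-truth effects and place probesets
#'
#' Chooses planted SNPs (one per LD block, ancestral frequency in
#' \[0.3, 0.7\] so realized effect correlations are near their design
#' targets), lays probeset gene annotations along the simulated genome, and
#' records the truth ledger.  cis pairs place the gene within 50 kb of the
#' SNP on the same chromosome; trans pairs place it on a different
#' chromosome.  Every planted eQTL pair is a triad plant: its probeset drives
#' IC50 (`gamma_expr`) and its SNP carries a direct effect (`gamma_snp`).
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return an object of class `cohort_truth`: list with `eqtl_map`,
#'   `pgx_snps`, `pgx_probesets`, `probe_info`, and (after
#'   [simulate_cohort()]) `true_log_ic50`.
#' @export
plant_effects <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_truth)
  si <- genotypes$snp_info
  n_eqtl <- config$n_cis_eqtl + config$n_trans_eqtl
  n_plant <- n_eqtl + config$n_pgx_snps

  # one planted SNP per block so plants are not in LD with each other;
  # prefer blocks with moderate ancestral frequency (effect sizes are
  # calibrated at MAF ~0.4), fall back to the closest-to-0.5 blocks
  first_of_block <- which(!duplicated(si$block))
  eligible <- first_of_block[si$p_anc[first_of_block] >= 0.3 &
                               si$p_anc[first_of_block] <= 0.7]
  if (length(eligible) < n_plant) {
    extra <- setdiff(first_of_block, eligible)
    extra <- extra[order(abs(si$p_anc[extra] - 0.5))]
    eligible <- c(eligible, utils::head(extra, n_plant - length(eligible)))
  }
  if (length(eligible) < n_plant)
    pgx_stop("too few LD blocks for the requested planted effects",
             "pgx_config_error")
  planted <- if (length(eligible) == 1) eligible else
    sample(eligible, n_plant)
  cis_snps <- planted[seq_len(config$n_cis_eqtl)]
  trans_snps <- planted[config$n_cis_eqtl + seq_len(config$n_trans_eqtl)]
  direct_snps <- planted[n_eqtl + seq_len(config$n_pgx_snps)]

  # probeset / gene placement
  np <- config$n_probesets
  probe_chr <- as.character(sample.int(config$n_chromosomes, np,
                                       replace = TRUE))
  span <- tapply(si$pos, si$chr, max)
  start <- vapply(probe_chr, function(cc) {
    hi <- if (cc %in% names(span)) span[[cc]] else 1e6
    round(runif(1, 1, hi))
  }, numeric(1))
  len <- round(runif(np, 5e3, 5e4))
  probe_info <- data.frame(
    probeset_id = sprintf("ps%04d_at", seq_len(np)),
    gene_symbol = sprintf("GENE%04d", seq_len(np)),
    chr = probe_chr, start = start, end = start + len,
    strand = "+", stringsAsFactors = FALSE)

  eqtl_probes <- seq_len(n_eqtl)
  type <- rep(c("cis", "trans"),
              c(config$n_cis_eqtl, config$n_trans_eqtl))
  for (i in seq_along(cis_snps)) {
    s <- cis_snps[i]
    probe_info$chr[i] <- si$chr[s]
    st <- max(1, si$pos[s] + round(runif(1, -3e4, 1e4)))
    probe_info$start[i] <- st
    probe_info$end[i] <- st + 2e4
  }
  for (i in seq_along(trans_snps)) {
    j <- config$n_cis_eqtl + i
    s <- trans_snps[i]
    other <- setdiff(as.character(seq_len(config$n_chromosomes)), si$chr[s])
    probe_info$chr[j] <- sample(other, 1)
  }

  eqtl_snps <- c(cis_snps, trans_snps)
  eqtl_map <- data.frame(
    snp = eqtl_snps,
    snp_id = si$snp_id[eqtl_snps],
    probeset = eqtl_probes[seq_along(eqtl_snps)],
    probeset_id = probe_info$probeset_id[eqtl_probes[seq_along(eqtl_snps)]],
    beta = rep(config$beta_eqtl, length(eqtl_snps)),
    type = type[seq_along(eqtl_snps)],
    stringsAsFactors = FALSE)

  pgx_idx <- c(eqtl_snps, direct_snps)
  pgx_snps <- data.frame(
    snp = pgx_idx, snp_id = si$snp_id[pgx_idx],
    gamma = rep(config$gamma_snp, length(pgx_idx)),
    role = rep(c("triad", "direct"),
               c(length(eqtl_snps), length(direct_snps))),
    stringsAsFactors = FALSE)
  pgx_probesets <- data.frame(
    probeset = eqtl_map$probeset, probeset_id = eqtl_map$probeset_id,
    gamma = rep(config$gamma_expr, nrow(eqtl_map)),
    stringsAsFactors = FALSE)

  structure(list(eqtl_map = eqtl_map, pgx_snps = pgx_snps,
                 pgx_probesets = pgx_probesets, probe_info = probe_info,
                 true_log_ic50 = NULL),
            class = "cohort_truth")
}

# mean-imputed dosage vector for one SNP (used when planting effects so a
# missing call does not knock a whole sample out of the linear model)
.dosage_imputed <- function(g) {
  f <- mean(g, na.rm = TRUE)
  g[is.na(g)] <- f
  g
}

#' Simulate probeset expression with planted eQTLs
#'
#' Expression is `mu_p + population offset + sex offset + beta * genotype +
#' N(0, sigma_expr)` per probeset, with per-probeset baselines drawn from
#' N(8, 1) (log2-microarray scale) and offsets drawn from the configured
#' offset distributions.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param truth output of [plant_effects()].
#' @param config the same [sim_config()].
#' @return a probeset x sample numeric matrix.
#' @export
simulate_expression <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cohort_truth"))
  set.seed(config$seed + .seed_expression)
  np <- config$n_probesets
  n <- nrow(genotypes$calls)
  if (nrow(truth$probe_info) != np)
    pgx_stop("truth/probeset dimensions inconsistent with config",
             "pgx_config_error")
  if (any(truth$eqtl_map$snp > ncol(genotypes$calls)) ||
      any(truth$eqtl_map$probeset > np))
    pgx_stop("eQTL index out of range", "pgx_config_error")

  pops <- factor(genotypes$samples$population)
  mu <- rnorm(np, 8, 1)
  pop_off <- matrix(rnorm(np * nlevels(pops), 0, config$sigma_pop_expr),
                    nrow = np)
  sex_off <- rnorm(np, 0, config$sigma_sex_expr)
  is_m <- as.numeric(genotypes$samples$sex == "M")

  expr <- matrix(rnorm(np * n, 0, config$sigma_expr), nrow = np, ncol = n)
  expr <- expr + mu + pop_off[, as.integer(pops), drop = FALSE]
  expr <- expr + outer(sex_off, is_m)
  for (i in seq_len(nrow(truth$eqtl_map))) {
    g <- .dosage_imputed(genotypes$calls[, truth$eqtl_map$snp[i]])
    p <- truth$eqtl_map$probeset[i]
    expr[p, ] <- expr[p, ] + truth$eqtl_map$beta[i] * g
  }
  dimnames(expr) <- list(truth$probe_info$probeset_id,
                         genotypes$samples$sample_id)
  expr
}

# true log10 IC50 per sample per drug; gamma_expr acts on the observed
# (standardized) expression so that its units are "per expression SD"
.simulate_true_ic50 <- function(genotypes, expression, truth, config) {
  set.seed(config$seed + .seed_ic50)
  n <- nrow(genotypes$calls)
  pops <- factor(genotypes$samples$population)
  out <- matrix(NA_real_, nrow = n, ncol = length(config$drugs),
                dimnames = list(genotypes$samples$sample_id, config$drugs))
  for (d in config$drugs) {
    y <- rep(config$mu_log_ic50[[d]], n)
    y <- y + rnorm(nlevels(pops), 0, config$sigma_pop_ic50)[as.integer(pops)]
    for (i in seq_len(nrow(truth$pgx_snps)))
      y <- y + truth$pgx_snps$gamma[i] *
        .dosage_imputed(genotypes$calls[, truth$pgx_snps$snp[i]])
    for (i in seq_len(nrow(truth$pgx_probesets))) {
      e <- expression[truth$pgx_probesets$probeset[i], ]
      y <- y + truth$pgx_probesets$gamma[i] * as.numeric(scale(e))
    }
    out[, d] <- y + rnorm(n, 0, config$sigma_ic50)
  }
  out
}

#' Simulate dose-response viability readouts
#'
#' For each sample and drug, viabilities at `dose_grid` are generated from a
#' four-parameter logistic with midpoint `10^true_log_ic50`, plus Gaussian
#' replicate noise, clipped at 0 (readouts can exceed control but not be
#' negative).
#'
#' @param truth a `cohort_truth` whose `true_log_ic50` is populated (as done
#'   by [simulate_cohort()]).
#' @param config the same [sim_config()].
#' @return a long-format data.frame with columns `sample_id`, `drug`, `dose`,
#'   `viability`.
#' @export
simulate_dose_response <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "cohort_truth"))
  if (is.null(truth$true_log_ic50))
    pgx_stop("truth$true_log_ic50 is not populated; run simulate_cohort()",
             "pgx_config_error")
  set.seed(config$seed + .seed_viability)
  ic <- truth$true_log_ic50
  grid <- rep(config$dose_grid, each = config$n_replicates)
  n <- nrow(ic)
  out <- vector("list", ncol(ic))
  for (j in seq_len(ncol(ic))) {
    e <- 10^ic[, j]
    v <- logistic4(rep(grid, times = n),
                   b = config$hill_slope,
                   c = config$lower_asymptote,
                   d = config$upper_asymptote,
                   e = rep(e, each = length(grid)))
    if (config$viability_noise_sd > 0)
      v <- v + rnorm(length(v), 0, config$viability_noise_sd)
    out[[j]] <- data.frame(
      sample_id = rep(rownames(ic), each = length(grid)),
      drug = colnames(ic)[j],
      dose = rep(grid, times = n),
      viability = pmax(0, v),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a complete synthetic cohort
#'
#' Composes [simulate_genotypes()], [plant_effects()],
#' [simulate_expression()], the true-IC50 model, and
#' [simulate_dose_response()] into one deterministic cohort with a
#' ground-truth ledger.
#'
#' @param config a [sim_config()].
#' @return an object of class `pgx_cohort`: list with `genotypes` (calls +
#'   snp_info + samples), `expression`, `probe_info`, `covariates`,
#'   `dose_response`, `truth`, and the `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_snps = 50, n_probesets = 5))
#' dim(cohort$genotypes$calls)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  truth <- plant_effects(geno, config)
  expr <- simulate_expression(geno, truth, config)
  truth$true_log_ic50 <- .simulate_true_ic50(geno, expr, truth, config)
  dr <- simulate_dose_response(truth, config)
  structure(list(genotypes = geno, expression = expr,
                 probe_info = truth$probe_info,
                 covariates = geno$samples,
                 dose_response = dr, truth = truth, config = config),
            class = "pgx_cohort")
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat("Synthetic LCL pharmacogenomic cohort\n")
  cat(sprintf("  samples:   %d (%s)\n", nrow(x$genotypes$calls),
              paste(sprintf("%s=%d", names(x$config$n_per_population),
                            x$config$n_per_population), collapse = ", ")))
  cat(sprintf("  SNPs:      %d   probesets: %d\n",
              ncol(x$genotypes$calls), nrow(x$expression)))
  cat(sprintf("  drugs:     %s\n", paste(x$config$drugs, collapse = ", ")))
  cat(sprintf("  planted:   %d cis-eQTL, %d trans-eQTL, %d direct pgx SNP(s)\n",
              x$config$n_cis_eqtl, x$config$n_trans_eqtl,
              x$config$n_pgx_snps))
  invisible(x)
}
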