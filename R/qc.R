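#' Minor allele frequency of one SNP
#'
#' `MAF = min(f, 1 - f)` with `f = sum(calls) / (2 * n_nonmissing)`; missing
#' calls are excluded from numerator and denominator.  Invariant to ref/alt
#' relabeling (`g -> 2 - g`).
#'
#' @param calls integer vector in \{0, 1, 2, NA\}.
#' @return MAF in \[0, 0.5\], or `NA` if all calls are missing.
#' @export
compute_maf <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) return(NA_real_)
  f <- sum(calls[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: P is the sum of probabilities, over all heterozygote
#' counts compatible with the observed allele counts, of outcomes no more
#' probable than the observed one under the hypergeometric null of random
#' allele pairing.  Probabilities are computed by the stable ratio recurrence
#' over heterozygote counts.  Monomorphic SNPs return P = 1 (no test
#' possible; conventionally passes the filter).
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return exact P-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfectly balanced, P = 1
#' hwe_exact_test(50, 0, 50)    # gross heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    pgx_stop("genotype counts must be non-negative integers",
             "pgx_domain_error")
  n <- sum(counts)
  if (n < 1) pgx_stop("total genotype count must be >= 1", "pgx_domain_error")
  n_a <- 2 * n_hom_ref + n_het           # ref allele count
  if (n_a > n) n_a <- 2 * n - n_a        # fold to rarer allele
  if (n_a == 0) return(1.0)              # monomorphic

  # possible heterozygote counts share the parity of the rare allele count
  het <- seq.int(n_a %% 2, n_a, by = 2L)
  pr <- numeric(length(het))
  pr[1] <- 1
  if (length(het) > 1) {
    for (i in seq_len(length(het) - 1L)) {
      h <- het[i]
      # P(h + 2) / P(h) under the hypergeometric HWE null
      num <- 4 * ((n_a - h) / 2) * ((2 * n - n_a - h) / 2)
      den <- (h + 2) * (h + 1)
      pr[i + 1] <- pr[i] * num / den
    }
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, het)]
  if (is.na(p_obs))
    pgx_stop("heterozygote count incompatible with allele counts",
             "pgx_domain_error")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# vectorized per-SNP QC statistics for a call matrix
snp_qc_stats <- function(calls) {
  n <- nrow(calls)
  n_ok <- colSums(!is.na(calls))
  call_rate <- n_ok / n
  maf <- apply(calls, 2, compute_maf)
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  hwe_p <- rep(NA_real_, ncol(calls))
  has <- n_ok > 0
  hwe_p[has] <- mapply(hwe_exact_test, n0[has], n1[has], n2[has])
  data.frame(snp_id = colnames(calls), call_rate = call_rate, maf = maf,
             hwe_p = hwe_p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply SNP and sample quality-control filters
#'
#' Order of operations is fixed: (1) samples with call rate below
#' `sample_call_rate` are dropped; (2) on the remaining samples, SNPs are
#' dropped for low call rate, then Hardy-Weinberg failure (exact test on the
#' pooled cohort), then low MAF.  Each exclusion is recorded with its reason
#' (the first failing filter in that order).  The HWE test pools populations
#' by default; `hwe_by` can name a per-sample population vector to test
#' within strata and combine by minimum P (pooling multi-ethnic panels
#' inflates HWE failures via the Wahlund effect).
#'
#' @param calls sample x SNP integer matrix in \{0, 1, 2, NA\} with dimnames.
#' @param snp_info optional SNP annotation data.frame with `snp_id`; filtered
#'   alongside.
#' @param call_rate,hwe_p,maf,sample_call_rate thresholds; SNPs are kept when
#'   call rate >= `call_rate`, HWE P >= `hwe_p` and MAF >= `maf`.
#' @param hwe_by optional factor/character of per-sample strata for the HWE
#'   test.
#' @return a list of class `qc_result`: `calls` and `snp_info` (filtered),
#'   `report` (list with `samples`, `snps` data.frames and a `summary`
#'   count table), and `empty` flag set when nothing survives.
#' @export
apply_qc <- function(calls, snp_info = NULL, call_rate = 0.95,
                     hwe_p = 0.001, maf = 0.05, sample_call_rate = 0.95,
                     hwe_by = NULL) {
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("snp%05d", seq_len(ncol(calls)))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%04d", seq_len(nrow(calls)))

  s_rate <- rowMeans(!is.na(calls))
  samples <- data.frame(sample_id = rownames(calls), call_rate = s_rate,
                        pass = s_rate >= sample_call_rate,
                        stringsAsFactors = FALSE, row.names = NULL)
  kept <- calls[samples$pass, , drop = FALSE]

  stats <- snp_qc_stats(kept)
  if (!is.null(hwe_by)) {
    strata <- factor(hwe_by[samples$pass])
    per <- sapply(levels(strata), function(l) {
      snp_qc_stats(kept[strata == l, , drop = FALSE])$hwe_p
    })
    stats$hwe_p <- apply(cbind(per), 1, min, na.rm = TRUE)
  }
  fail_cr <- stats$call_rate < call_rate
  fail_hwe <- !fail_cr & !is.na(stats$hwe_p) & stats$hwe_p < hwe_p
  fail_maf <- !fail_cr & !fail_hwe & !is.na(stats$maf) & stats$maf < maf
  all_missing <- is.na(stats$maf)
  fail_cr <- fail_cr | all_missing
  stats$pass <- !(fail_cr | fail_hwe | fail_maf)
  stats$reason <- NA_character_
  stats$reason[fail_cr] <- "call_rate"
  stats$reason[fail_hwe] <- "hwe"
  stats$reason[fail_maf] <- "maf"

  keep_snps <- stats$pass
  out_calls <- kept[, keep_snps, drop = FALSE]
  out_info <- snp_info
  if (!is.null(out_info))
    out_info <- out_info[match(colnames(out_calls), out_info$snp_id), ,
                         drop = FALSE]
  summary <- c(samples_in = nrow(calls),
               samples_removed = sum(!samples$pass),
               snps_in = ncol(calls),
               snps_fail_call_rate = sum(fail_cr),
               snps_fail_hwe = sum(fail_hwe),
               snps_fail_maf = sum(fail_maf),
               snps_out = ncol(out_calls))
  empty <- nrow(out_calls) == 0 || ncol(out_calls) == 0
  if (empty)
    message("QC produced an empty genotype matrix")
  structure(list(calls = out_calls, snp_info = out_info,
                 report = list(samples = samples, snps = stats,
                               summary = summary),
                 empty = empty),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  s <- x$report$summary
  cat("Genotype QC\n")
  cat(sprintf("  samples: %d in, %d removed\n",
              s["samples_in"], s["samples_removed"]))
  cat(sprintf("  SNPs:    %d in -> %d out (call rate %d, HWE %d, MAF %d)\n",
              s["snps_in"], s["snps_out"], s["snps_fail_call_rate"],
              s["snps_fail_hwe"], s["snps_fail_maf"]))
  invisible(x)
}
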