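#' Classify SNP-gene pairs as cis or trans
#'
#' A pair is cis iff SNP and gene share a chromosome and the distance from
#' the SNP to the gene interval (0 if inside) is at most `cis_half_window`
#' (inclusive boundary); otherwise trans.  The window is measured from the
#' gene boundary, not the transcription start site.
#'
#' @param snp_chr,snp_pos SNP coordinates (vectors recycle).
#' @param gene_chr,gene_start,gene_end gene interval coordinates.
#' @param cis_half_window window half-width in base pairs (default 200 kb).
#' @return character vector `"cis"`/`"trans"`, `NA` when a coordinate is
#'   missing (unclassifiable; excluded from cis counts downstream).
#' @export
classify_cis_trans <- function(snp_chr, snp_pos, gene_chr, gene_start,
                               gene_end, cis_half_window = 2e5) {
  n <- max(length(snp_chr), length(gene_chr))
  snp_chr <- rep_len(as.character(snp_chr), n)
  gene_chr <- rep_len(as.character(gene_chr), n)
  snp_pos <- rep_len(snp_pos, n)
  gene_start <- rep_len(gene_start, n)
  gene_end <- rep_len(gene_end, n)
  dist <- ifelse(snp_pos < gene_start, gene_start - snp_pos,
                 ifelse(snp_pos > gene_end, snp_pos - gene_end, 0))
  out <- ifelse(snp_chr == gene_chr & dist <= cis_half_window,
                "cis", "trans")
  out[is.na(snp_chr) | is.na(gene_chr) | is.na(snp_pos) |
        is.na(gene_start) | is.na(gene_end)] <- NA_character_
  out
}

#' Three-way SNP-expression-IC50 integrated ("triad") analysis
#'
#' Starting from SNPs whose SNP-IC50 association passes
#' `thresholds$snp_ic50` (optionally restricted to members of a qualifying
#' locus set), joins every probeset whose SNP-expression association passes
#' `thresholds$snp_expr`, and retains pairs whose probeset also passes the
#' expression-IC50 threshold `thresholds$expr_pheno`.  One record is emitted
#' per surviving (SNP, probeset) pair, with all three association legs and a
#' cis/trans flag when coordinates are available.
#'
#' @param snp_assoc SNP-phenotype association table: `snp_id`, `r`, `p` (a
#'   renamed [association_scan()] output works).
#' @param snp_expr_assoc SNP-expression table: `snp_id`, `probeset_id`, `r`,
#'   `p`.
#' @param expr_pheno_assoc expression-phenotype table: `probeset_id`, `r`,
#'   `p`.
#' @param snp_info optional `snp_id`, `chr`, `pos` (+ `maf`) annotation.
#' @param probe_info optional `probeset_id`, `gene_symbol`, `chr`, `start`,
#'   `end` annotation.
#' @param loci optional [define_loci()] result restricting candidate SNPs to
#'   locus members.
#' @param thresholds list with `snp_ic50`, `snp_expr`, `expr_pheno`.
#' @param cis_half_window passed to [classify_cis_trans()].
#' @param restrict_gene optional gene symbol: keep only triads whose
#'   probeset maps to this gene (e.g. a SNP's own gene for cis follow-up).
#' @return data.frame of class `triad_table`, one row per (SNP, probeset)
#'   pair: identifiers, annotations, `r_snp_ic50`, `p_snp_ic50`,
#'   `r_snp_expr`, `p_snp_expr`, `r_expr_ic50`, `p_expr_ic50`, `cis_flag`;
#'   attribute `"summary"` carries distinct SNP / probeset / gene / locus
#'   counts.
#' @export
triad_analysis <- function(snp_assoc, snp_expr_assoc, expr_pheno_assoc,
                           snp_info = NULL, probe_info = NULL, loci = NULL,
                           thresholds = list(snp_ic50 = 1e-3,
                                             snp_expr = 1e-4,
                                             expr_pheno = 1e-4),
                           cis_half_window = 2e5,
                           restrict_gene = NULL) {
  th <- utils::modifyList(list(snp_ic50 = 1e-3, snp_expr = 1e-4,
                               expr_pheno = 1e-4), as.list(thresholds))
  snps <- snp_assoc[!is.na(snp_assoc$p) & snp_assoc$p < th$snp_ic50, ,
                    drop = FALSE]
  if (!is.null(loci)) {
    mem <- if (inherits(loci, "locus_set")) loci$members$snp_id else loci
    snps <- snps[snps$snp_id %in% mem, , drop = FALSE]
  }
  se <- snp_expr_assoc[!is.na(snp_expr_assoc$p) &
                         snp_expr_assoc$p < th$snp_expr &
                         snp_expr_assoc$snp_id %in% snps$snp_id, ,
                       drop = FALSE]
  orphans <- setdiff(se$probeset_id, expr_pheno_assoc$probeset_id)
  if (length(orphans) > 0)
    pgx_stop(sprintf("probeset id(s) missing from expr_pheno_assoc: %s",
                     paste(unique(orphans), collapse = ", ")),
             "pgx_join_error")
  ep <- expr_pheno_assoc[!is.na(expr_pheno_assoc$p) &
                           expr_pheno_assoc$p < th$expr_pheno, ,
                         drop = FALSE]
  out <- merge(
    data.frame(snp_id = snps$snp_id, r_snp_ic50 = snps$r,
               p_snp_ic50 = snps$p, stringsAsFactors = FALSE),
    data.frame(snp_id = se$snp_id, probeset_id = se$probeset_id,
               r_snp_expr = se$r, p_snp_expr = se$p,
               stringsAsFactors = FALSE),
    by = "snp_id")
  out <- merge(out, data.frame(probeset_id = ep$probeset_id,
                               r_expr_ic50 = ep$r, p_expr_ic50 = ep$p,
                               stringsAsFactors = FALSE),
               by = "probeset_id")

  out$gene_symbol <- rep(NA_character_, nrow(out))
  out$cis_flag <- rep(NA_character_, nrow(out))
  if (!is.null(probe_info)) {
    pi_ <- probe_info[match(out$probeset_id, probe_info$probeset_id), ,
                      drop = FALSE]
    if ("gene_symbol" %in% names(pi_)) out$gene_symbol <- pi_$gene_symbol
    if (!is.null(snp_info) &&
        all(c("chr", "start", "end") %in% names(pi_))) {
      si <- snp_info[match(out$snp_id, snp_info$snp_id), , drop = FALSE]
      out$snp_chr <- si$chr
      out$snp_pos <- si$pos
      if ("maf" %in% names(si)) out$snp_maf <- si$maf
      out$cis_flag <- classify_cis_trans(si$chr, si$pos, pi_$chr,
                                         pi_$start, pi_$end,
                                         cis_half_window)
    }
  }
  if (!is.null(restrict_gene))
    out <- out[!is.na(out$gene_symbol) & out$gene_symbol %in% restrict_gene,
               , drop = FALSE]
  ord <- order(out$p_snp_ic50, out$snp_id, out$probeset_id)
  out <- out[ord, c("snp_id", "probeset_id", "gene_symbol",
                    intersect(c("snp_chr", "snp_pos", "snp_maf"),
                              names(out)),
                    "r_snp_ic50", "p_snp_ic50", "r_snp_expr", "p_snp_expr",
                    "r_expr_ic50", "p_expr_ic50", "cis_flag"),
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    n_pairs = nrow(out),
    n_snps = length(unique(out$snp_id)),
    n_probesets = length(unique(out$probeset_id)),
    n_genes = length(unique(na.omit(out$gene_symbol))),
    n_cis = sum(out$cis_flag == "cis", na.rm = TRUE),
    n_trans = sum(out$cis_flag == "trans", na.rm = TRUE))
  attr(out, "thresholds") <- th
  class(out) <- c("triad_table", class(out))
  out
}

#' Re-validate a triad table against its thresholds
#'
#' Independent post-hoc checker that every record's three legs pass the
#' thresholds the table was built with.
#'
#' @param triads a [triad_analysis()] result.
#' @param thresholds optionally override the recorded thresholds.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_triads <- function(triads, thresholds = attr(triads, "thresholds")) {
  ok <- triads$p_snp_ic50 < thresholds$snp_ic50 &
    triads$p_snp_expr < thresholds$snp_expr &
    triads$p_expr_ic50 < thresholds$expr_pheno
  if (!all(ok))
    pgx_stop("triad record(s) violate the thresholds",
             "pgx_validation_error")
  invisible(TRUE)
}

#' Filter an imputed-dosage panel on quality and frequency
#'
#' Retains SNPs with imputation quality (dosage R^2) of at least `min_r2`
#' and MAF of at least `min_maf`; MAF is computed from the mean dosage / 2,
#' folded.
#'
#' @param dosages sample x SNP matrix of continuous alternate-allele dosages
#'   in \[0, 2\].
#' @param quality per-SNP dosage R^2 in \[0, 1\].
#' @param min_r2,min_maf retention thresholds (SNPs strictly below either
#'   are removed).
#' @return list with the filtered `dosages`, `quality`, and a logical
#'   `kept` vector over the input SNPs.
#' @export
filter_dosage_panel <- function(dosages, quality, min_r2 = 0.3,
                                min_maf = 0.01) {
  if (length(quality) != ncol(dosages))
    pgx_stop("one quality value per SNP required", "pgx_data_error")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    pgx_stop("dosages must lie in [0, 2]", "pgx_domain_error")
  f <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  kept <- quality >= min_r2 & maf >= min_maf
  list(dosages = dosages[, kept, drop = FALSE], quality = quality[kept],
       kept = kept)
}

#' Imputation concordance: average squared allele-count difference
#'
#' `(1/n) * sum((d_i - g_i)^2)` over paired non-missing entries; a smaller
#' value indicates greater concordance between imputed dosages and observed
#' genotypes.  When the ref/alt orientation of the two sources is unknown
#' (`orientation = "unknown"`), the dosages are folded to the orientation
#' minimizing the metric, with a warning.
#'
#' @param dosages per-sample dosages in \[0, 2\].
#' @param genotypes per-sample calls in \{0, 1, 2\}.
#' @param orientation `"same"` (default) or `"unknown"`.
#' @return average squared difference in \[0, 4\].
#' @export
imputation_concordance <- function(dosages, genotypes,
                                   orientation = c("same", "unknown")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(dosages) & !is.na(genotypes)
  if (!any(ok))
    pgx_stop("no overlapping non-missing pairs", "pgx_insufficient_data")
  d <- dosages[ok]; g <- genotypes[ok]
  asd <- mean((d - g)^2)
  if (orientation == "unknown") {
    flipped <- mean((2 - d - g)^2)
    if (flipped < asd) {
      warning("allele orientation folded to the minimizing orientation")
      asd <- flipped
    }
  }
  asd
}

#' Pairwise composite LD r-squared from unphased genotypes
#'
#' Squared Pearson correlation of the paired 0/1/2 allele-count vectors
#' (composite LD; no phasing required).
#'
#' @param g1,g2 genotype vectors in \{0, 1, 2, NA\}.
#' @return r^2 in \[0, 1\], or `NA` (with warning) when fewer than 2
#'   complete pairs remain or either SNP is monomorphic in the complete-case
#'   subset.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2 || sd(g1[ok]) == 0 || sd(g2[ok]) == 0) {
    warning("LD r^2 unavailable: monomorphic input or too few pairs")
    return(NA_real_)
  }
  cor(g1[ok], g2[ok])^2
}
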