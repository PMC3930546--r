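#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF: biallelic records only (multiallelic records are dropped and
#' counted, with a message); GT fields `0/0`, `0/1`, `1/1` (phased `|`
#' accepted) map to 0/1/2 alternate-allele counts, `./.` to missing.
#' Coordinates are kept 1-based as in the source.  TSV: first column
#' `sample_id`, remaining columns one SNP each (calls 0/1/2, empty or NA
#' missing); SNP annotation may be supplied separately.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return list with `calls` (sample x SNP integer matrix) and `snp_info`
#'   (data.frame `snp_id`, `chr`, `pos`, `ref`, `alt`; `NULL` for TSV
#'   input).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(read_genotypes_vcf(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  calls <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- as.character(dt[[1]])
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad))
    pgx_stop("dosage TSV contains calls outside {0, 1, 2, NA}",
             "pgx_parse_error")
  if (anyDuplicated(colnames(calls)))
    pgx_stop("duplicate SNP ids in dosage TSV", "pgx_parse_error")
  list(calls = calls, snp_info = NULL)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message(sprintf("dropping %d multiallelic record(s)", sum(multi)))
  keep <- !multi
  if (anyDuplicated(fix$ID[keep]))
    pgx_stop("duplicate rsid in VCF", "pgx_parse_error")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    bad <- !is.na(x) & x != "./." & is.na(out)
    if (any(bad))
      pgx_stop(sprintf("unparseable GT value(s): %s",
                       paste(unique(x[bad]), collapse = ", ")),
               "pgx_parse_error")
    out
  }
  calls <- t(matrix(code(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt)))
  dimnames(calls) <- list(colnames(gt), rownames(gt))
  snp_info <- data.frame(snp_id = fix$ID[keep], chr = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         stringsAsFactors = FALSE)
  list(calls = calls, snp_info = snp_info)
}

#' Write a genotype matrix as VCF
#'
#' Minimal VCFv4.2 writer (GT field only, one ALT per record, 1-based
#' coordinates), suitable for round-tripping simulated cohorts through
#' standard tools.
#'
#' @param calls sample x SNP matrix in \{0, 1, 2, NA\}.
#' @param snp_info data.frame with `snp_id`, `chr`, `pos`, `ref`, `alt`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, snp_info, path) {
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  body <- vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[as.character(g)])
    paste(c(snp_info$chr[j], snp_info$pos[j], snp_info$snp_id[j],
            snp_info$ref[j], snp_info$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write all cohort components to a directory
#'
#' Emits genotypes as VCF and sample x SNP TSV, expression as probeset x
#' sample TSV with an annotation sidecar, dose-response as long-format CSV,
#' covariates as TSV, and the ground-truth ledger as TSVs.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pgx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f, sep = "\t")
    data.table::fwrite(x, file.path(dir, f), sep = sep)
  write_vcf(cohort$genotypes$calls, cohort$genotypes$snp_info,
            file.path(dir, "genotypes.vcf"))
  gt <- data.frame(sample_id = rownames(cohort$genotypes$calls),
                   cohort$genotypes$calls, check.names = FALSE)
  fw(gt, "genotypes.tsv")
  fw(cohort$genotypes$snp_info, "snp_info.tsv")
  ex <- data.frame(probeset_id = rownames(cohort$expression),
                   cohort$expression, check.names = FALSE)
  fw(ex, "expression.tsv")
  fw(cohort$probe_info, "probe_info.tsv")
  fw(cohort$covariates, "covariates.tsv")
  fw(cohort$dose_response, "dose_response.csv", sep = ",")
  fw(cohort$truth$eqtl_map, "truth_eqtl.tsv")
  fw(cohort$truth$pgx_snps, "truth_pgx_snps.tsv")
  fw(cohort$truth$pgx_probesets, "truth_pgx_probesets.tsv")
  ic <- data.frame(sample_id = rownames(cohort$truth$true_log_ic50),
                   cohort$truth$true_log_ic50, check.names = FALSE)
  fw(ic, "truth_log_ic50.tsv")
  invisible(dir)
}

#' Read a probeset x sample expression TSV
#'
#' @param path TSV whose first column is `probeset_id`.
#' @return numeric matrix, probesets in rows.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Published LCL locus tables for gemcitabine and AraC
#'
#' The top SNP-locus summary tables from a published genome-wide study of
#' gemcitabine and AraC cytotoxicity in the Coriell Human Variation Panel
#' lymphoblastoid cell lines (174 samples, three populations), transcribed
#' from print: one row per locus with the seed SNP, its lowest partial
#' correlation and P-value, the nearest gene, position, MAF, region class
#' and member count.  Useful as a worked example for [common_loci()].
#'
#' @param drug `"gemcitabine"` or `"araC"`.
#' @return data.frame with columns `seed_snp`, `lowest_r`, `lowest_p`,
#'   `nearby_gene`, `chr`, `seed_pos`, `maf`, `region`, `n_members`,
#'   `window_start`, `window_end`.
#' @export
hvp_locus_table <- function(drug = c("gemcitabine", "araC")) {
  drug <- match.arg(drug)
  f <- system.file("extdata",
                   sprintf("hvp_loci_%s.tsv", tolower(drug)),
                   package = "pgxtriad", mustWork = TRUE)
  d <- read.delim(f, stringsAsFactors = FALSE)
  d$chr <- as.character(d$chr)
  d$window_start <- d$seed_pos - 1e5
  d$window_end <- d$seed_pos + 1e5
  d
}

#' Published PIGB triad table (gemcitabine)
#'
#' The printed integrated-analysis rows for the seven PIGB SNPs associated
#' with both gemcitabine IC50 (P < 1e-3) and PIGB expression (P < 1e-4) in
#' the Human Variation Panel LCLs: one row per (SNP, probeset) pair with
#' all three association legs.
#'
#' @return data.frame with SNP coordinates, probeset ids, and the three
#'   r/P pairs.
#' @export
hvp_pigb_triads <- function() {
  f <- system.file("extdata", "hvp_pigb_triads.tsv", package = "pgxtriad",
                   mustWork = TRUE)
  d <- read.delim(f, stringsAsFactors = FALSE)
  d$chr <- as.character(d$chr)
  d$probe_chr <- as.character(d$probe_chr)
  d
}

#' Split the published PIGB triad table into association-leg tables
#'
#' Reshapes [hvp_pigb_triads()] into the three per-leg tables expected by
#' [triad_analysis()], plus SNP and probeset annotations.
#'
#' @return list with `snp_assoc`, `snp_expr_assoc`, `expr_pheno_assoc`,
#'   `snp_info`, `probe_info`.
#' @export
hvp_pigb_triad_tables <- function() {
  d <- hvp_pigb_triads()
  snp <- unique(d[, c("snp_id", "r_snp_ic50", "p_snp_ic50")])
  list(
    snp_assoc = data.frame(snp_id = snp$snp_id, r = snp$r_snp_ic50,
                           p = snp$p_snp_ic50, stringsAsFactors = FALSE),
    snp_expr_assoc = data.frame(snp_id = d$snp_id,
                                probeset_id = d$probeset_id,
                                r = d$r_snp_expr, p = d$p_snp_expr,
                                stringsAsFactors = FALSE),
    expr_pheno_assoc = unique(data.frame(probeset_id = d$probeset_id,
                                         r = d$r_expr_ic50,
                                         p = d$p_expr_ic50,
                                         stringsAsFactors = FALSE)),
    snp_info = unique(data.frame(snp_id = d$snp_id, chr = d$chr,
                                 pos = d$pos, maf = d$maf,
                                 stringsAsFactors = FALSE)),
    probe_info = unique(data.frame(probeset_id = d$probeset_id,
                                   gene_symbol = d$gene_symbol,
                                   chr = d$probe_chr,
                                   stringsAsFactors = FALSE)))
}
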