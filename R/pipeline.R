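#' Analysis parameters for the integrated pipeline
#'
#' Collects every tunable threshold of the pipeline with its default:
#' QC (call rate 0.95, HWE exact P 0.001, MAF 0.05, sample call rate 0.95),
#' five stratification eigenvectors, locus aggregation (seed P < 1e-4,
#' member P < 1e-3, +/- 100 kb), triad thresholds (SNP-IC50 1e-3,
#' SNP-expression 1e-4, expression-IC50 1e-4), cis window +/- 200 kb, and
#' the drug-to-phenotype-transform map (log10 for gemcitabine-type
#' distributions, van der Waerden for AraC-type).
#'
#' @param call_rate,hwe_p,maf,sample_call_rate QC thresholds
#'   (see [apply_qc()]).
#' @param n_eigenvectors stratification components (see
#'   [compute_eigenvectors()]).
#' @param p_strong,p_weak,half_window locus rule (see [define_loci()]).
#' @param triad_thresholds list for [triad_analysis()].
#' @param cis_half_window cis window (see [classify_cis_trans()]).
#' @param drug_transforms named character, drug -> `"log10"`/`"vdw"`; drugs
#'   without an entry default to `"log10"`.
#' @param fit_model dose-response model (see [fit_logistic()]).
#' @param locus_restricted restrict triad candidates to locus members.
#' @return a named list of class `pgx_params`.
#' @export
pipeline_params <- function(call_rate = 0.95, hwe_p = 0.001, maf = 0.05,
                            sample_call_rate = 0.95, n_eigenvectors = 5,
                            p_strong = 1e-4, p_weak = 1e-3,
                            half_window = 1e5,
                            triad_thresholds = list(snp_ic50 = 1e-3,
                                                    snp_expr = 1e-4,
                                                    expr_pheno = 1e-4),
                            cis_half_window = 2e5,
                            drug_transforms = c(gemcitabine = "log10",
                                                araC = "vdw"),
                            fit_model = "auto",
                            locus_restricted = TRUE) {
  structure(list(call_rate = call_rate, hwe_p = hwe_p, maf = maf,
                 sample_call_rate = sample_call_rate,
                 n_eigenvectors = n_eigenvectors, p_strong = p_strong,
                 p_weak = p_weak, half_window = half_window,
                 triad_thresholds = triad_thresholds,
                 cis_half_window = cis_half_window,
                 drug_transforms = drug_transforms,
                 fit_model = fit_model,
                 locus_restricted = locus_restricted),
            class = "pgx_params")
}

#' Run configuration: input paths + parameters
#'
#' @param genotypes path to a VCF or dosage TSV.
#' @param expression path to a probeset x sample TSV.
#' @param probe_info path to the probeset annotation TSV
#'   (`probeset_id`, `gene_symbol`, `chr`, `start`, `end`).
#' @param dose_response path to the long-format curve CSV.
#' @param covariates path to the sample covariate TSV
#'   (`sample_id`, `population`, `sex`).
#' @param snp_info optional SNP annotation TSV (required with TSV
#'   genotypes).
#' @param out_dir output directory.
#' @param params a [pipeline_params()] list.
#' @param seed integer seed recorded with the run.
#' @return list of class `pgx_run_config`.
#' @export
run_config <- function(genotypes, expression, probe_info, dose_response,
                       covariates, snp_info = NULL, out_dir = "pgx_out",
                       params = pipeline_params(), seed = 1L) {
  structure(list(genotypes = genotypes, expression = expression,
                 probe_info = probe_info, dose_response = dose_response,
                 covariates = covariates, snp_info = snp_info,
                 out_dir = out_dir, params = params,
                 seed = as.integer(seed)),
            class = "pgx_run_config")
}

#' Serialize / deserialize a run configuration (YAML)
#'
#' Configurations round-trip losslessly through [write_run_config()] and
#' [read_run_config()].
#'
#' @param config a [run_config()].
#' @param path YAML file.
#' @return the path / the configuration.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$params$drug_transforms <- as.list(x$params$drug_transforms)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  prm <- x$params
  prm$drug_transforms <- unlist(prm$drug_transforms)
  x$params <- do.call(pipeline_params, prm)
  do.call(run_config, x[setdiff(names(x), "params")] |>
            c(list(params = x$params)))
}

#' Run the full integrated analysis pipeline
#'
#' Stages: IC50 fitting -> phenotype transform -> genotype QC ->
#' stratification eigenvectors -> SNP-phenotype scan per drug ->
#' locus aggregation -> SNP-expression and expression-phenotype scans ->
#' triad analysis.  Every stage logs its input/output counts; all outputs
#' are deterministic given the inputs and parameters, including row order.
#'
#' @param x a [run_config()] (inputs read from disk) or a
#'   [simulate_cohort()] object (in-memory).
#' @param out_dir output directory for stage TSVs and the run log; `NULL`
#'   (default for in-memory input) skips writing.
#' @param params a [pipeline_params()] list; taken from the config when `x`
#'   is a `pgx_run_config`.
#' @param quiet suppress per-stage messages.
#' @return a result bundle (list): `ic50`, `phenotypes`, `qc`,
#'   `eigenvectors`, `assoc` (per drug), `loci` (per drug), `snp_expr` (per
#'   drug), `expr_pheno` (per drug), `triads` (per drug), `summary`.
#' @export
run_pipeline <- function(x, out_dir = NULL, params = NULL, quiet = FALSE) {
  if (inherits(x, "pgx_run_config")) {
    if (is.null(params)) params <- x$params
    if (is.null(out_dir)) out_dir <- x$out_dir
    geno <- read_genotypes(x$genotypes)
    if (is.null(geno$snp_info)) {
      if (is.null(x$snp_info))
        pgx_stop("TSV genotypes need a snp_info annotation file",
                 "pgx_config_error")
      geno$snp_info <- read.delim(x$snp_info, stringsAsFactors = FALSE)
      geno$snp_info$chr <- as.character(geno$snp_info$chr)
    }
    expr <- read_expression(x$expression)
    probe_info <- read.delim(x$probe_info, stringsAsFactors = FALSE)
    probe_info$chr <- as.character(probe_info$chr)
    dr <- data.table::fread(x$dose_response, data.table = FALSE)
    covars <- read.delim(x$covariates, stringsAsFactors = FALSE)
    input <- list(genotypes = geno, expression = expr,
                  probe_info = probe_info, dose_response = dr,
                  covariates = covars)
  } else if (inherits(x, "pgx_cohort")) {
    if (is.null(params)) params <- pipeline_params()
    input <- x
  } else {
    pgx_stop("x must be a pgx_run_config or a pgx_cohort",
             "pgx_config_error")
  }

  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logf <- file.path(out_dir, "run.log")
    if (file.exists(logf)) file.remove(logf)
  }
  log <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    if (!quiet) message(line)
    if (!is.null(logf)) cat(line, "\n", sep = "", file = logf,
                            append = TRUE)
  }
  emit <- function(obj, name, sep = "\t") {
    if (!is.null(out_dir))
      data.table::fwrite(obj, file.path(out_dir, name), sep = sep)
  }

  drugs <- unique(input$dose_response$drug)

  # --- IC50 fitting and phenotype transforms ------------------------------
  ic50 <- fit_ic50_table(input$dose_response, model = params$fit_model)
  log("ic50", "%d curves fitted, %d converged", nrow(ic50),
      sum(ic50$converged))
  emit(ic50, "ic50.tsv")
  sample_ids <- input$covariates$sample_id
  phen <- lapply(drugs, function(d) {
    tr <- params$drug_transforms[[d]]
    if (is.null(tr) || is.na(tr)) tr <- "log10"
    v <- ic50$ic50[ic50$drug == d][match(sample_ids,
                                         ic50$sample_id[ic50$drug == d])]
    transform_phenotype(v, tr)
  })
  names(phen) <- drugs
  phenotypes <- data.frame(sample_id = sample_ids,
                           as.data.frame(phen, check.names = FALSE))
  emit(phenotypes, "phenotypes.tsv")

  # --- genotype & sample QC ----------------------------------------------
  qc <- apply_qc(input$genotypes$calls, input$genotypes$snp_info,
                 call_rate = params$call_rate, hwe_p = params$hwe_p,
                 maf = params$maf,
                 sample_call_rate = params$sample_call_rate)
  log("qc", "samples %d -> %d, SNPs %d -> %d",
      qc$report$summary["samples_in"],
      qc$report$summary["samples_in"] - qc$report$summary["samples_removed"],
      qc$report$summary["snps_in"], qc$report$summary["snps_out"])
  emit(qc$report$snps, "qc_snps.tsv")
  emit(qc$report$samples, "qc_samples.tsv")
  if (qc$empty) {
    log("qc", "empty matrix after QC; downstream tables will be empty")
  }
  keep_samples <- rownames(qc$calls)
  covars <- input$covariates[match(keep_samples,
                                   input$covariates$sample_id), ,
                             drop = FALSE]
  expr <- input$expression[, match(keep_samples,
                                   colnames(input$expression)),
                           drop = FALSE]

  # --- stratification eigenvectors & designs ------------------------------
  ev <- if (qc$empty) NULL else
    compute_eigenvectors(qc$calls,
                         min(params$n_eigenvectors,
                             nrow(qc$calls), ncol(qc$calls)))
  if (!is.null(ev)) {
    log("pca", "%d eigenvector(s) computed over %d SNPs", ncol(ev),
        ncol(qc$calls))
    emit(data.frame(sample_id = rownames(ev), ev, check.names = FALSE),
         "eigenvectors.tsv")
  }
  design_snp <- build_design(covars, eigenvectors = ev)
  design_expr <- build_design(covars, include_eigenvectors = FALSE)

  snp_pos <- qc$snp_info
  genes <- input$probe_info
  names(genes)[names(genes) == "start"] <- "start"
  res <- list(ic50 = ic50, phenotypes = phenotypes, qc = qc,
              eigenvectors = ev, assoc = list(), loci = list(),
              snp_expr = list(), expr_pheno = list(), triads = list())
  summary_rows <- list()

  for (d in drugs) {
    y <- phen[[d]][match(keep_samples, sample_ids)]

    assoc <- if (qc$empty)
      data.frame(predictor_id = character(0), n = integer(0),
                 k = integer(0), r = numeric(0), t = numeric(0),
                 p = numeric(0), q = numeric(0)) else
      suppressMessages(association_scan(qc$calls, y, design_snp,
                                        response_id = d))
    log("gwas", "%s: %d SNPs scanned, %d with P < %g", d, nrow(assoc),
        sum(assoc$p < params$p_weak, na.rm = TRUE), params$p_weak)
    emit(assoc, sprintf("assoc_%s.tsv", d))
    res$assoc[[d]] <- assoc

    loci <- define_loci(assoc, snp_pos, p_strong = params$p_strong,
                        p_weak = params$p_weak,
                        half_window = params$half_window)
    loci$loci <- annotate_nearest_gene(loci, genes)
    log("loci", "%s: %d locus/loci, %d member SNPs", d, nrow(loci$loci),
        nrow(loci$members))
    emit(loci$loci, sprintf("loci_%s.tsv", d))
    emit(loci$members, sprintf("locus_members_%s.tsv", d))
    res$loci[[d]] <- loci

    cand <- assoc$predictor_id[!is.na(assoc$p) &
                                 assoc$p < params$triad_thresholds$snp_ic50]
    if (params$locus_restricted)
      cand <- intersect(cand, loci$members$snp_id)
    se <- if (length(cand) == 0)
      data.frame(snp_id = character(0), probeset_id = character(0),
                 r = numeric(0), p = numeric(0)) else {
      cc <- qc$calls[, cand, drop = FALSE]
      do.call(rbind, lapply(rownames(expr), function(pb) {
        sc <- suppressMessages(
          association_scan(cc, expr[pb, ], design_snp,
                           response_id = pb))
        data.frame(snp_id = sc$predictor_id, probeset_id = pb,
                   r = sc$r, p = sc$p, stringsAsFactors = FALSE)
      }))
    }
    log("eqtl", "%s: %d candidate SNP(s) x %d probesets tested", d,
        length(cand), nrow(expr))
    emit(se, sprintf("snp_expr_%s.tsv", d))
    res$snp_expr[[d]] <- se

    ep0 <- suppressMessages(
      association_scan(t(expr), y, design_expr, response_id = d))
    ep <- data.frame(probeset_id = ep0$predictor_id, r = ep0$r, p = ep0$p,
                     stringsAsFactors = FALSE)
    log("expr-pheno", "%s: %d probesets tested", d, nrow(ep))
    emit(ep, sprintf("expr_pheno_%s.tsv", d))
    res$expr_pheno[[d]] <- ep

    sa <- data.frame(snp_id = assoc$predictor_id, r = assoc$r, p = assoc$p,
                     stringsAsFactors = FALSE)
    si <- snp_pos
    if (!is.null(si)) si$maf <- qc$report$snps$maf[
      match(si$snp_id, qc$report$snps$snp_id)]
    triads <- triad_analysis(sa, se, ep, snp_info = si,
                             probe_info = genes,
                             loci = if (params$locus_restricted)
                               res$loci[[d]] else NULL,
                             thresholds = params$triad_thresholds,
                             cis_half_window = params$cis_half_window)
    s <- attr(triads, "summary")
    log("triads", "%s: %d pair(s), %d SNP(s), %d gene(s), %d cis / %d trans",
        d, s["n_pairs"], s["n_snps"], s["n_genes"], s["n_cis"],
        s["n_trans"])
    emit(as.data.frame(triads), sprintf("triads_%s.tsv", d))
    res$triads[[d]] <- triads

    summary_rows[[d]] <- data.frame(
      drug = d, snps_scanned = nrow(assoc),
      snps_p_weak = sum(assoc$p < params$p_weak, na.rm = TRUE),
      snps_p_strong = sum(assoc$p < params$p_strong, na.rm = TRUE),
      n_loci = nrow(loci$loci), n_locus_snps = nrow(loci$members),
      n_triad_pairs = s[["n_pairs"]], n_triad_snps = s[["n_snps"]],
      n_triad_genes = s[["n_genes"]], n_cis = s[["n_cis"]],
      n_trans = s[["n_trans"]], stringsAsFactors = FALSE)
  }
  res$summary <- do.call(rbind, summary_rows)
  rownames(res$summary) <- NULL
  emit(res$summary, "summary.tsv")
  log("done", "pipeline complete (%d drug(s))", length(drugs))
  res
}
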