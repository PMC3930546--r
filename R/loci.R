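#' Aggregate association signals into SNP loci
#'
#' A SNP locus is a +/- `half_window` region around a seed SNP that contains
#' either at least 2 SNPs with P < `p_strong`, or 1 SNP with P < `p_strong`
#' plus at least 3 additional SNPs with P < `p_weak`.  Loci are formed
#' greedily: the unassigned SNP with the smallest P among those below
#' `p_strong` seeds a window on its chromosome; all unassigned SNPs below
#' `p_weak` inside the closed window become members if the qualification
#' predicate holds, otherwise the seed is retired as a seed (it may still
#' join a later locus as a member).  Every SNP belongs to at most one locus,
#' so locus counts are well-defined and independent of input row order.
#'
#' @param assoc association table with columns `predictor_id`, `p` and
#'   optionally `r` (e.g. from [association_scan()]).
#' @param snp_info SNP annotation with `snp_id`, `chr`, `pos` (1-based).
#' @param p_strong,p_weak P-value thresholds (`p_strong <= p_weak`).
#' @param half_window half-width of the closed locus window in base pairs.
#' @return an object of class `locus_set`: list with `loci` (one row per
#'   locus: `locus_id`, `seed_snp`, `chr`, `seed_pos`, `window_start`,
#'   `window_end`, `lowest_r`, `lowest_p`, `n_members`, `n_strong`) and
#'   `members` (`locus_id`, `snp_id`, `p`), both sorted by seed P.
#' @export
define_loci <- function(assoc, snp_info, p_strong = 1e-4, p_weak = 1e-3,
                        half_window = 1e5) {
  if (p_strong > p_weak)
    pgx_stop("p_strong must be <= p_weak", "pgx_config_error")
  d <- merge(assoc, snp_info[, c("snp_id", "chr", "pos")],
             by.x = "predictor_id", by.y = "snp_id", sort = FALSE)
  d <- d[!is.na(d$p), , drop = FALSE]
  d <- d[order(d$p, d$chr, d$pos), , drop = FALSE]  # deterministic
  assigned <- rep(FALSE, nrow(d))
  retired <- rep(FALSE, nrow(d))
  has_r <- "r" %in% names(d)
  loci <- list(); members <- list()
  repeat {
    cand <- which(!assigned & !retired & d$p < p_strong)
    if (length(cand) == 0) break
    seed <- cand[1]
    inwin <- which(!assigned & d$chr == d$chr[seed] &
                     abs(d$pos - d$pos[seed]) <= half_window &
                     d$p < p_weak)
    n_strong <- sum(d$p[inwin] < p_strong)
    qualifies <- n_strong >= 2 ||
      (n_strong >= 1 && length(inwin) - n_strong >= 3)
    if (!qualifies) {
      retired[seed] <- TRUE
      next
    }
    id <- length(loci) + 1L
    loci[[id]] <- data.frame(
      locus_id = id, seed_snp = d$predictor_id[seed],
      chr = d$chr[seed], seed_pos = d$pos[seed],
      window_start = d$pos[seed] - half_window,
      window_end = d$pos[seed] + half_window,
      lowest_r = if (has_r) d$r[seed] else NA_real_,
      lowest_p = d$p[seed],
      n_members = length(inwin), n_strong = n_strong,
      stringsAsFactors = FALSE)
    members[[id]] <- data.frame(locus_id = id,
                                snp_id = d$predictor_id[inwin],
                                p = d$p[inwin], stringsAsFactors = FALSE)
    assigned[inwin] <- TRUE
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(locus_id = integer(0), seed_snp = character(0),
               chr = character(0), seed_pos = integer(0),
               window_start = numeric(0), window_end = numeric(0),
               lowest_r = numeric(0), lowest_p = numeric(0),
               n_members = integer(0), n_strong = integer(0))
  members <- if (length(members)) do.call(rbind, members) else
    data.frame(locus_id = integer(0), snp_id = character(0),
               p = numeric(0))
  rownames(loci) <- rownames(members) <- NULL
  structure(list(loci = loci, members = members,
                 p_strong = p_strong, p_weak = p_weak,
                 half_window = half_window),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("%d SNP locus/loci (%d member SNPs); window +/- %g bp, P < %g seed / %g member\n",
              nrow(x$loci), nrow(x$members), x$half_window, x$p_strong,
              x$p_weak))
  if (nrow(x$loci)) print(utils::head(x$loci, 10))
  invisible(x)
}

#' Re-validate a locus set against its qualification predicate
#'
#' Independent post-hoc checker: verifies that every emitted locus has its
#' seed as the minimum-P member, all members inside the closed window and
#' below `p_weak`, the qualification predicate true, and member sets of
#' distinct loci disjoint.
#'
#' @param locus_set a [define_loci()] result.
#' @param assoc,snp_info the inputs it was built from.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_loci <- function(locus_set, assoc, snp_info) {
  l <- locus_set$loci; mem <- locus_set$members
  if (anyDuplicated(mem$snp_id))
    pgx_stop("a SNP belongs to more than one locus", "pgx_validation_error")
  pm <- assoc$p[match(mem$snp_id, assoc$predictor_id)]
  if (any(abs(pm - mem$p) > 1e-12, na.rm = TRUE))
    pgx_stop("member P-values disagree with the association table",
             "pgx_validation_error")
  for (i in seq_len(nrow(l))) {
    mi <- mem[mem$locus_id == l$locus_id[i], ]
    pos <- snp_info$pos[match(mi$snp_id, snp_info$snp_id)]
    chr <- snp_info$chr[match(mi$snp_id, snp_info$snp_id)]
    if (any(chr != l$chr[i]) ||
        any(pos < l$window_start[i] | pos > l$window_end[i]))
      pgx_stop("member outside the locus window", "pgx_validation_error")
    if (any(mi$p >= locus_set$p_weak))
      pgx_stop("member above the weak threshold", "pgx_validation_error")
    if (min(mi$p) < l$lowest_p[i] - 1e-15)
      pgx_stop("seed is not the minimum-P member", "pgx_validation_error")
    ns <- sum(mi$p < locus_set$p_strong)
    if (!(ns >= 2 || (ns >= 1 && nrow(mi) - ns >= 3)))
      pgx_stop("locus fails the qualification predicate",
               "pgx_validation_error")
  }
  invisible(TRUE)
}

#' Annotate loci with their nearest gene
#'
#' For each locus seed, the nearest gene by minimal distance from the seed
#' position to the gene interval (0 if inside).  Ties are broken by the
#' lexicographically smaller symbol (and logged).  The region class is
#' `"within"` when the seed lies inside the interval, else `"upstream"` /
#' `"downstream"` relative to the gene (strand-aware when a `strand` column
#' is present; plus-strand convention otherwise).
#'
#' @param locus_set a [define_loci()] result (or its `loci` data.frame).
#' @param genes gene annotation with `gene_symbol`, `chr`, `start`, `end`
#'   and optionally `strand`.
#' @return the `loci` data.frame with added `nearby_gene`, `gene_distance`,
#'   `region` columns (`NA` + `unannotated = TRUE` attribute rowwise when no
#'   gene shares the chromosome).
#' @export
annotate_nearest_gene <- function(locus_set, genes) {
  loci <- if (inherits(locus_set, "locus_set")) locus_set$loci else locus_set
  stopifnot(all(c("gene_symbol", "chr", "start", "end") %in% names(genes)))
  strand <- if ("strand" %in% names(genes)) genes$strand else
    rep("+", nrow(genes))
  loci$nearby_gene <- rep(NA_character_, nrow(loci))
  loci$gene_distance <- rep(NA_real_, nrow(loci))
  loci$region <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    g <- genes[genes$chr == loci$chr[i], , drop = FALSE]
    st <- strand[genes$chr == loci$chr[i]]
    if (nrow(g) == 0) next
    pos <- loci$seed_pos[i]
    dd <- ifelse(pos < g$start, g$start - pos,
                 ifelse(pos > g$end, pos - g$end, 0))
    best <- which(dd == min(dd))
    if (length(best) > 1) {
      best <- best[order(g$gene_symbol[best])]
      message(sprintf("locus %s: nearest-gene tie, choosing %s",
                      loci$seed_snp[i], g$gene_symbol[best[1]]))
    }
    b <- best[1]
    loci$nearby_gene[i] <- g$gene_symbol[b]
    loci$gene_distance[i] <- dd[b]
    loci$region[i] <- if (dd[b] == 0) "within" else {
      before <- pos < g$start[b]
      if (identical(st[b], "-")) before <- !before
      if (before) "upstream" else "downstream"
    }
  }
  loci
}

#' Loci shared between two drugs
#'
#' Returns the gene symbols appearing as `nearby_gene` in both annotated
#' locus tables, plus pairs of loci whose windows overlap on the same
#' chromosome.
#'
#' @param loci_a,loci_b annotated locus data.frames (from
#'   [annotate_nearest_gene()], or any table with `nearby_gene` and
#'   optionally `chr`, `window_start`, `window_end`).
#' @return list with `shared_genes` (character) and `overlaps` (data.frame
#'   of overlapping locus pairs; empty when window columns are absent).
#' @export
common_loci <- function(loci_a, loci_b) {
  ga <- unique(na.omit(loci_a$nearby_gene))
  gb <- unique(na.omit(loci_b$nearby_gene))
  shared <- sort(intersect(ga, gb))
  overlaps <- data.frame(a = character(0), b = character(0),
                         chr = character(0))
  win <- c("chr", "window_start", "window_end")
  if (all(win %in% names(loci_a)) && all(win %in% names(loci_b))) {
    for (i in seq_len(nrow(loci_a))) for (j in seq_len(nrow(loci_b))) {
      if (loci_a$chr[i] == loci_b$chr[j] &&
          loci_a$window_start[i] <= loci_b$window_end[j] &&
          loci_b$window_start[j] <= loci_a$window_end[i]) {
        overlaps <- rbind(overlaps, data.frame(
          a = as.character(loci_a$seed_snp[i]),
          b = as.character(loci_b$seed_snp[j]),
          chr = as.character(loci_a$chr[i])))
      }
    }
  }
  list(shared_genes = shared, overlaps = overlaps)
}
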