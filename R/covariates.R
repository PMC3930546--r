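#' Genotype principal components for stratification adjustment
#'
#' Computes per-sample eigenvector loadings of the standardized genotype
#' matrix: each SNP is centered by `2 * f` and scaled by
#' `sqrt(2 * f * (1 - f))` with `f` the sample alternate-allele frequency
#' (the standard convention of the stratification-correction literature);
#' missing calls are mean-imputed (zero after centering) before the
#' decomposition.  Loadings are returned in decreasing-eigenvalue order with
#' the sign convention that each component's largest-magnitude loading is
#' positive.
#'
#' @param calls QC-passed sample x SNP matrix in \{0, 1, 2, NA\}.
#' @param n_components number of components (<= min(samples, SNPs)).
#' @return numeric matrix samples x `n_components` with columns `EV1..EVk`;
#'   attribute `"eigenvalues"` carries the corresponding eigenvalues.
#' @export
compute_eigenvectors <- function(calls, n_components = 5) {
  n_components <- as.integer(n_components)
  if (n_components < 0)
    pgx_stop("n_components must be >= 0", "pgx_config_error")
  out0 <- matrix(numeric(0), nrow = nrow(calls), ncol = 0,
                 dimnames = list(rownames(calls), NULL))
  if (n_components == 0) return(structure(out0, eigenvalues = numeric(0)))
  if (n_components > min(dim(calls)))
    pgx_stop("n_components exceeds min(samples, SNPs)", "pgx_config_error")
  f <- colMeans(calls, na.rm = TRUE) / 2
  colvar <- apply(calls, 2, function(g) var(g[!is.na(g)]))
  poly <- !is.na(f) & f > 0 & f < 1 & !is.na(colvar) & colvar > 0
  if (!any(poly))
    pgx_stop("genotype matrix is constant; no decomposition possible",
             "pgx_decomposition_error")
  x <- calls[, poly, drop = FALSE]
  f <- f[poly]
  x <- sweep(x, 2, 2 * f)
  x <- sweep(x, 2, sqrt(2 * f * (1 - f)), "/")
  x[is.na(x)] <- 0
  sv <- svd(x, nu = n_components, nv = 0)
  ev <- sv$u
  for (j in seq_len(ncol(ev))) {
    i <- which.max(abs(ev[, j]))
    if (ev[i, j] < 0) ev[, j] <- -ev[, j]
  }
  dimnames(ev) <- list(rownames(calls), paste0("EV", seq_len(ncol(ev))))
  structure(ev, eigenvalues = sv$d[seq_len(n_components)]^2)
}

#' Assemble the covariate-adjustment design matrix
#'
#' Builds the design used by the partial-correlation tests: intercept,
#' reference-coded population dummies, a sex indicator, and (when a SNP is
#' involved in the test) the stratification eigenvectors.  Aliased or
#' constant columns are dropped with a warning and the non-intercept column
#' count `k` -- the degrees-of-freedom correction of the Wald test -- is
#' adjusted accordingly.  With 3 populations, 2 sexes and 5 eigenvectors,
#' `k = 8`; without eigenvectors, `k = 3`.
#'
#' @param covariates data.frame with `sample_id`, `population`, `sex`.
#' @param eigenvectors optional matrix from [compute_eigenvectors()] (rows
#'   matched to `covariates$sample_id` by rowname when present).
#' @param include_eigenvectors whether to append the eigenvector columns.
#' @return an object of class `pgx_design`: list with `X` (numeric matrix
#'   including intercept, rownames = sample ids) and `k` (non-intercept
#'   column count).
#' @export
build_design <- function(covariates, eigenvectors = NULL,
                         include_eigenvectors = !is.null(eigenvectors)) {
  need <- c("sample_id", "population", "sex")
  if (!all(need %in% names(covariates)))
    pgx_stop("covariates must have sample_id, population, sex",
             "pgx_data_error")
  if (anyNA(covariates$population) || anyNA(covariates$sex))
    pgx_stop("population and sex must be non-missing", "pgx_data_error")
  n <- nrow(covariates)
  X <- matrix(1, nrow = n, ncol = 1,
              dimnames = list(covariates$sample_id, "(Intercept)"))
  pop <- factor(covariates$population)
  if (nlevels(pop) > 1) {
    P <- model.matrix(~pop)[, -1, drop = FALSE]
    colnames(P) <- paste0("population", levels(pop)[-1])
    X <- cbind(X, P)
  } else {
    warning("single-population cohort: population dummies dropped")
  }
  sex <- factor(covariates$sex)
  if (nlevels(sex) > 1) {
    X <- cbind(X, sex = as.numeric(sex == levels(sex)[2]))
  } else {
    warning("single-sex cohort: sex column dropped")
  }
  if (include_eigenvectors && !is.null(eigenvectors) &&
      ncol(eigenvectors) > 0) {
    ev <- eigenvectors
    if (!is.null(rownames(ev)))
      ev <- ev[match(covariates$sample_id, rownames(ev)), , drop = FALSE]
    if (anyNA(ev))
      pgx_stop("eigenvectors missing for some samples", "pgx_data_error")
    X <- cbind(X, ev)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    warning(sprintf("dropping aliased design column(s): %s",
                    paste(drop, collapse = ", ")))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  structure(list(X = X, k = ncol(X) - 1L), class = "pgx_design")
}

#' @export
print.pgx_design <- function(x, ...) {
  cat(sprintf("Adjustment design: %d samples, k = %d (%s)\n",
              nrow(x$X), x$k,
              paste(setdiff(colnames(x$X), "(Intercept)"), collapse = ", ")))
  invisible(x)
}
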