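#' Covariate-adjusted partial Pearson correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection onto the adjustment design (with intercept), restricted to
#' complete cases of `x`, `y` and all design columns.  Genotype predictors
#' enter as the 0/1/2 alternate-allele count (additive coding).
#'
#' @param x,y numeric per-sample vectors (missing values allowed).
#' @param design a [build_design()] object, a numeric design matrix
#'   (including intercept), or `NULL` for an intercept-only adjustment (plain
#'   Pearson correlation).
#' @return list with `r` (partial correlation; `NA` when a residual is
#'   numerically zero, i.e. the variable is collinear with the design), `n`
#'   (complete-case count) and `k` (non-intercept covariate count).
#' @export
partial_pearson <- function(x, y, design = NULL) {
  Z <- design_matrix_of(design, length(x))
  k <- attr(Z, "k")
  cc <- !is.na(x) & !is.na(y) & complete.cases(Z)
  n <- sum(cc)
  if (n <= k + 2)
    pgx_stop(sprintf("need n > k + 2 complete cases (n=%d, k=%d)", n, k),
             "pgx_insufficient_data")
  Zc <- Z[cc, , drop = FALSE]
  res <- stats::lm.fit(Zc, cbind(x[cc], y[cc]))$residuals
  rx <- res[, 1]; ry <- res[, 2]
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  tol_x <- 1e-10 * max(sd(x[cc]), 1) * sqrt(n)
  tol_y <- 1e-10 * max(sd(y[cc]), 1) * sqrt(n)
  if (sx <= tol_x || sy <= tol_y)
    return(list(r = NA_real_, n = n, k = k))
  list(r = sum(rx * ry) / (sx * sy), n = n, k = k)
}

# normalize a design argument to a numeric matrix with attribute k
design_matrix_of <- function(design, n) {
  if (is.null(design)) {
    Z <- matrix(1, nrow = n, ncol = 1)
    attr(Z, "k") <- 0L
    return(Z)
  }
  if (inherits(design, "pgx_design")) {
    Z <- design$X
    attr(Z, "k") <- design$k
    return(Z)
  }
  if (is.matrix(design)) {
    Z <- design
    if (!any(apply(Z, 2, function(col) all(col == col[1] & col[1] != 0))))
      Z <- cbind(1, Z)
    attr(Z, "k") <- ncol(Z) - 1L
    return(Z)
  }
  pgx_stop("design must be NULL, a matrix, or a pgx_design",
           "pgx_data_error")
}

#' Wald test of a partial correlation
#'
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` referred to a Student-t
#' distribution with `df = n - 2 - k` (the standard partial-correlation
#' degrees of freedom); the two-sided tail probability is returned.  With
#' `k = 0` this is the classical correlation t-test.
#'
#' @param r partial correlation.
#' @param n complete-case sample count.
#' @param k non-intercept covariate count.
#' @return list with `t`, `p`, `df`.
#' @export
wald_pvalue <- function(r, n, k = 0) {
  df <- n - 2 - k
  if (df < 1) pgx_stop("need n - 2 - k >= 1", "pgx_insufficient_data")
  if (is.na(r)) return(list(t = NA_real_, p = NA_real_, df = df))
  if (abs(r) >= 1) {
    warning("|r| = 1: P reported as the smallest representable value")
    return(list(t = sign(r) * Inf, p = .Machine$double.xmin, df = df))
  }
  t <- r * sqrt(df / (1 - r^2))
  list(t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE), df = df)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by the smoother method (a natural-spline
#' fit of `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over
#' `lambda = 0.05, ..., 0.95`, evaluated at `lambda = 0.95`), then computes
#' `q(p_i) = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`.  With
#' `pi0 = 1` (forced, or the fallback for fewer than 100 tests) the result
#' equals Benjamini-Hochberg adjusted p-values.  Output is monotone
#' non-decreasing in p and invariant to input order.
#'
#' @param p p-values in (0, 1\].
#' @param lambda tuning grid for the pi0 smoother.
#' @param pi0 optional forced null proportion in (0, 1\].
#' @return list with `q` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (anyNA(p) || any(p <= 0 | p > 1))
    pgx_stop("p-values must lie in (0, 1]", "pgx_domain_error")
  m <- length(p)
  if (m < 1) pgx_stop("need at least one p-value", "pgx_domain_error")
  if (is.null(pi0)) {
    if (m < 100) {
      message("fewer than 100 tests: using conservative pi0 = 1")
      pi0 <- 1
    } else {
      pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- lm(pl ~ splines::ns(lambda, df = 3))
      pi0 <- unname(predict(fit, data.frame(lambda = max(lambda))))
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(1, cummin(q))
  out <- numeric(m)
  out[o] <- q
  list(q = out, pi0 = pi0)
}

#' Genome-wide partial-correlation association scan
#'
#' Runs [partial_pearson()] + [wald_pvalue()] for every predictor column
#' against one response, with q-values computed once over the whole scan.
#' Columns without missing values share one residualization of the design
#' and are processed by matrix algebra; columns with missingness are handled
#' per-predictor with their own complete-case set.  Per-predictor failures
#' (collinearity, too few complete cases) yield `NA` statistics and are
#' excluded from the q-value computation, never aborting the scan.
#'
#' @param predictors numeric sample x predictor matrix (genotype dosages or
#'   expression), column names as predictor ids.
#' @param response numeric per-sample vector (transformed IC50 phenotype or
#'   one probeset's expression).
#' @param design adjustment design as in [partial_pearson()].
#' @param response_id label recorded in the output.
#' @param sort_by_p sort the result by ascending P.
#' @return data.frame with columns `predictor_id`, `response_id`, `n`, `k`,
#'   `r`, `t`, `p`, `q`.
#' @export
association_scan <- function(predictors, response, design = NULL,
                             response_id = "response", sort_by_p = FALSE) {
  if (is.null(dim(predictors)))
    predictors <- matrix(predictors, ncol = 1)
  m <- ncol(predictors)
  ids <- colnames(predictors)
  if (is.null(ids)) ids <- sprintf("p%05d", seq_len(m))
  if (m == 0) {
    return(data.frame(predictor_id = character(0),
                      response_id = character(0), n = integer(0),
                      k = integer(0), r = numeric(0), t = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  if (nrow(predictors) != length(response))
    pgx_stop("predictors and response have inconsistent dimensions",
             "pgx_data_error")
  Z <- design_matrix_of(design, length(response))
  k <- attr(Z, "k")

  r <- rep(NA_real_, m); n <- rep(NA_integer_, m)
  base_cc <- !is.na(response) & complete.cases(Z)
  full <- which(colSums(is.na(predictors)) == 0)
  if (length(full) > 0) {
    Zc <- Z[base_cc, , drop = FALSE]
    Q <- qr.Q(qr(Zc))
    Xc <- predictors[base_cc, full, drop = FALSE]
    RX <- Xc - Q %*% crossprod(Q, Xc)
    ry <- response[base_cc] - Q %*% crossprod(Q, response[base_cc])
    ry <- as.numeric(ry)
    sx <- sqrt(colSums(RX^2)); sy <- sqrt(sum(ry^2))
    rr <- as.numeric(crossprod(RX, ry)) / (sx * sy)
    tol <- 1e-10 * sqrt(sum(base_cc))
    rr[sx <= tol * pmax(apply(Xc, 2, sd), 1)] <- NA_real_
    if (sy <= tol * max(sd(response[base_cc]), 1)) rr[] <- NA_real_
    r[full] <- rr
    n[full] <- sum(base_cc)
  }
  partial <- setdiff(seq_len(m), full)
  for (j in partial) {
    pp <- tryCatch(partial_pearson(predictors[, j], response, design),
                   pgx_error = function(e) NULL)
    if (is.null(pp)) next
    r[j] <- pp$r; n[j] <- pp$n
  }

  df <- n - 2L - k
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  q <- rep(NA_real_, m)
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- storey_qvalues(p[ok])$q
  out <- data.frame(predictor_id = ids, response_id = response_id,
                    n = n, k = k, r = r, t = t, p = p, q = q,
                    stringsAsFactors = FALSE)
  if (sort_by_p) out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
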